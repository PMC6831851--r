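# Synthetic CF-MS study generator. Plants a complex catalog, rewires a
# fraction of complexes between two cell states, and emits noisy
# protein x fraction peptide-count matrices (SEC and IEC, in replicate)
# plus phosphosite tables, with ground truth recorded for every stage.

#' Simulate a ground-truth complex catalog
#'
#' Draws `n_complexes` disjoint member sets over a universe of named proteins,
#' plus `n_background` monomeric background proteins. Each protein receives a
#' molecular-mass proxy (log-normal, kDa scale) and an integer abundance
#' multiplier; both drive the elution-profile generator. Both cell states
#' start with identical complex membership (see [apply_rewiring()]).
#'
#' @param n_complexes Number of complexes to plant (>= 1).
#' @param size_range Integer vector `c(min, max)` of complex sizes; minimum
#'   size is 2.
#' @param n_background Number of monomeric background proteins.
#' @param seed Integer seed; identical seeds give identical truth objects.
#' @param states Labels of the two cell states being compared.
#' @param noise Noise parameters: `peak_width` (Gaussian s.d. in fractions),
#'   `peak_height` (expected peptide counts at the apex, before the per-protein
#'   abundance multiplier), `dropout` (probability that a protein is lost in a
#'   given replicate), `monomer_prob` (probability that a complex member also
#'   elutes as a free monomer), `count_model` (`"poisson"` or `"exact"` for
#'   noise-free integer profiles).
#' @return A `sim_truth` object.
#' @export
simulate_catalog <- function(n_complexes,
                             size_range = c(2L, 10L),
                             n_background = 0L,
                             seed = 1L,
                             states = c("ECSC", "DNLC"),
                             noise = list()) {
  if (n_complexes < 1) stop("n_complexes must be >= 1")
  size_range <- as.integer(round(size_range))
  if (length(size_range) != 2 || size_range[1] < 2 ||
      size_range[2] < size_range[1]) {
    stop("invalid size distribution: sizes must be >= 2")
  }
  if (length(states) != 2 || anyDuplicated(states)) {
    stop("exactly two distinct state labels are required")
  }
  default_noise <- list(peak_width = 2, peak_height = 15, dropout = 0.1,
                        monomer_prob = 0.1, count_model = "poisson")
  noise <- utils::modifyList(default_noise, noise)

  withr::with_seed(seed, {
    sizes <- if (size_range[1] == size_range[2]) {
      rep(size_range[1], n_complexes)
    } else {
      sample(seq(size_range[1], size_range[2]), n_complexes, replace = TRUE)
    }
    n_members <- sum(sizes)
    n_prot <- n_members + n_background
    universe <- sprintf("PROT%04d", seq_len(n_prot))
    member_ids <- split(universe[seq_len(n_members)],
                        rep(seq_len(n_complexes), sizes))
    complexes <- lapply(member_ids, identity)
    names(complexes) <- sprintf("CPX%03d", seq_len(n_complexes))
    mass <- stats::setNames(rlnorm(n_prot, meanlog = log(60), sdlog = 0.6),
                            universe)
    amplitude <- stats::setNames(sample(1:5, n_prot, replace = TRUE), universe)
  })

  structure(list(
    states = states,
    complexes_per_state = stats::setNames(list(complexes, complexes), states),
    rewired_pairs = data.frame(protein_a = character(),
                               protein_b = character(),
                               present_in = character(),
                               stringsAsFactors = FALSE),
    rewired_complexes = character(0),
    protein_universe = universe,
    background = if (n_background > 0) universe[(n_members + 1):n_prot]
                 else character(0),
    mass = mass,
    amplitude = amplitude,
    noise = noise,
    seed = as.integer(seed)
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated CF-MS ground truth\n")
  cat(sprintf("  states: %s\n", paste(x$states, collapse = " vs ")))
  cat(sprintf("  complexes: %d (%d rewired), background proteins: %d\n",
              length(x$complexes_per_state[[1]]),
              length(x$rewired_complexes), length(x$background)))
  cat(sprintf("  universe: %d proteins, rewired pairs: %d\n",
              length(x$protein_universe), nrow(x$rewired_pairs)))
  invisible(x)
}

#' Rewire a fraction of planted complexes between the two states
#'
#' Alters the membership of the selected complexes in the second state by
#' swapping one member for an unused background protein (complexes of size > 2
#' may instead lose a member). `rewired_pairs` records every co-complex pair
#' present in exactly one state, together with the state in which it occurs.
#'
#' @param truth A `sim_truth` from [simulate_catalog()].
#' @param fraction_rewired Proportion of complexes to alter, in `[0, 1]`.
#' @param seed Integer seed controlling which complexes/members are altered.
#' @return The updated `sim_truth`.
#' @export
apply_rewiring <- function(truth, fraction_rewired, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (fraction_rewired < 0 || fraction_rewired > 1) {
    stop("fraction_rewired must be in [0, 1]")
  }
  cpx_a <- truth$complexes_per_state[[1]]
  cpx_b <- cpx_a
  n_rw <- round(fraction_rewired * length(cpx_a))
  rewired_names <- character(0)
  if (n_rw > 0) {
    in_complex <- unique(unlist(cpx_a))
    free_pool <- setdiff(truth$background, in_complex)
    withr::with_seed(seed, {
      chosen <- sort(sample(seq_along(cpx_a), n_rw))
      for (ci in chosen) {
        members <- cpx_b[[ci]]
        victim <- sample(members, 1)
        # swap for an unused background protein; if the pool is exhausted and
        # the complex can afford it, drop the member instead
        if (length(free_pool) > 0) {
          incoming <- sample(free_pool, 1)
          free_pool <- setdiff(free_pool, incoming)
          cpx_b[[ci]] <- c(setdiff(members, victim), incoming)
        } else if (length(members) > 2) {
          cpx_b[[ci]] <- setdiff(members, victim)
        } else {
          stop("cannot rewire a heterodimer without background proteins")
        }
      }
    })
    rewired_names <- names(cpx_a)[chosen]
  }
  pairs_a <- cocomplex_pairs(cpx_a)
  pairs_b <- cocomplex_pairs(cpx_b)
  key_a <- pair_id(pairs_a$protein_a, pairs_a$protein_b)
  key_b <- pair_id(pairs_b$protein_a, pairs_b$protein_b)
  only_a <- pairs_a[!(key_a %in% key_b), , drop = FALSE]
  only_b <- pairs_b[!(key_b %in% key_a), , drop = FALSE]
  rw <- rbind(
    if (nrow(only_a)) cbind(only_a, present_in = truth$states[1]),
    if (nrow(only_b)) cbind(only_b, present_in = truth$states[2])
  )
  if (is.null(rw)) {
    rw <- data.frame(protein_a = character(), protein_b = character(),
                     present_in = character(), stringsAsFactors = FALSE)
  }
  rownames(rw) <- NULL
  truth$complexes_per_state[[2]] <- cpx_b
  truth$rewired_pairs <- rw
  truth$rewired_complexes <- rewired_names
  truth
}

# map a vector of ranks/percentiles onto usable fraction positions,
# leaving a margin so peaks are not truncated at the column edges
fraction_margin <- function(n_fractions, peak_width) {
  ceiling(2 * peak_width)
}

#' Simulate one fractionation experiment
#'
#' Generates a protein x fraction matrix of distinct-peptide counts for one
#' (state, technique, replicate). Each complex present in the state elutes as
#' a shared Gaussian peak: in SEC the apex order follows decreasing summed
#' member mass (large assemblies elute first), in IEC apexes are uniform
#' random. Members share the complex apex; monomeric proteins get independent
#' peaks. Counts are Poisson draws around the peak intensity (or exact
#' integers under `count_model = "exact"`), and whole-protein dropout is
#' applied per replicate. Apex positions and monomer assignments depend only
#' on (truth, state, technique), so replicates share the underlying signal.
#'
#' @param truth A `sim_truth`.
#' @param state One of `truth$states`.
#' @param technique `"SEC"` or `"IEC"`.
#' @param replicate Replicate identifier (integer or label).
#' @param n_fractions Number of fractions (>= 10 and wide enough for the
#'   configured peak width).
#' @param seed Integer seed for the replicate-level noise (counts, dropout).
#' @return A `fraction_experiment` (see [read_experiment()] for the type).
#' @export
simulate_experiment <- function(truth, state, technique = c("SEC", "IEC"),
                                replicate = 1L, n_fractions = 80L,
                                seed = truth$seed + 100L) {
  stopifnot(inherits(truth, "sim_truth"))
  technique <- match.arg(technique)
  if (!state %in% truth$states) stop("unknown state label: ", state)
  pw <- truth$noise$peak_width
  margin <- fraction_margin(n_fractions, pw)
  if (n_fractions < 10 || n_fractions <= 2 * margin + 2) {
    stop("n_fractions too small for the configured peak width")
  }
  complexes <- truth$complexes_per_state[[state]]
  universe <- truth$protein_universe
  n_prot <- length(universe)
  in_complex <- unique(unlist(complexes))
  span <- c(margin + 1L, n_fractions - margin)

  # technique-level randomness, shared by both states and all replicates:
  # a protein's (or assembly's) chromatographic behavior is a property of
  # its biochemistry, not of the cell state, so apex positions and monomer
  # propensities must agree across states -- only the planted membership
  # differences distinguish the states. Apexes are keyed to complex names
  # using the first state's membership so rewired complexes keep their
  # elution position.
  cond_seed <- (truth$seed * 131L + label_hash(technique)) %% 2147483647L
  cond <- withr::with_seed(cond_seed, {
    ref_cpx <- truth$complexes_per_state[[1]]
    n_cpx <- length(ref_cpx)
    cpx_mass <- vapply(ref_cpx, function(m) sum(truth$mass[m]), numeric(1))
    if (technique == "SEC") {
      # heaviest assemblies elute first; evenly spread by mass rank
      ord <- rank(-cpx_mass, ties.method = "first")
      grid <- round(seq(span[1], span[2], length.out = max(n_cpx, 2)))
      cpx_apex <- grid[ord]
      pct <- rank(-truth$mass, ties.method = "first") / n_prot
      mono_apex <- span[1] + floor(pct * (span[2] - span[1])) +
        sample(-2:2, n_prot, replace = TRUE)
      mono_apex <- pmin(pmax(mono_apex, span[1]), span[2])
    } else {
      cpx_apex <- sample(seq(span[1], span[2]), n_cpx, replace = TRUE)
      mono_apex <- sample(seq(span[1], span[2]), n_prot, replace = TRUE)
    }
    names(cpx_apex) <- names(ref_cpx)
    mono_propensity <- stats::setNames(runif(n_prot), universe)
    list(cpx_apex = cpx_apex,
         mono_apex = stats::setNames(mono_apex, universe),
         mono_propensity = mono_propensity)
  })

  fr <- seq_len(n_fractions)
  kernel <- function(apex) exp(-(fr - apex)^2 / (2 * pw^2))
  lambda <- matrix(0, n_prot, n_fractions, dimnames = list(universe, NULL))
  exact <- matrix(0L, n_prot, n_fractions, dimnames = list(universe, NULL))
  ph <- truth$noise$peak_height
  for (ci in names(complexes)) {
    shape <- kernel(cond$cpx_apex[[ci]])
    int_kernel <- as.integer(round(ph * shape))
    for (m in complexes[[ci]]) {
      lambda[m, ] <- lambda[m, ] + truth$amplitude[m] * ph * shape
      exact[m, ] <- exact[m, ] + truth$amplitude[m] * int_kernel
    }
  }
  extra_mono <- in_complex[cond$mono_propensity[in_complex] <
                             truth$noise$monomer_prob]
  monomers <- c(setdiff(universe, in_complex), extra_mono)
  for (m in monomers) {
    shape <- kernel(cond$mono_apex[m])
    lambda[m, ] <- lambda[m, ] + truth$amplitude[m] * ph * shape
    exact[m, ] <- exact[m, ] + truth$amplitude[m] * as.integer(round(ph * shape))
  }

  counts <- withr::with_seed(seed, {
    out <- if (identical(truth$noise$count_model, "exact")) {
      exact
    } else {
      matrix(rpois(length(lambda), lambda), n_prot, n_fractions,
             dimnames = dimnames(lambda))
    }
    drop <- runif(n_prot) < truth$noise$dropout
    out[drop, ] <- 0L
    out
  })
  storage.mode(counts) <- "integer"
  colnames(counts) <- sprintf("F%03d", fr)

  new_fraction_experiment(counts, state = state, technique = technique,
                          replicate = replicate)
}

#' Simulate a full two-state, two-technique CF-MS study
#'
#' Convenience wrapper reproducing the default study design: two cell states,
#' SEC and IEC separations, duplicate replicates per combination.
#'
#' @inheritParams simulate_catalog
#' @param fraction_rewired Proportion of complexes rewired between states.
#' @param techniques Named integer vector mapping technique label to its
#'   number of fractions per replicate.
#' @param n_replicates Replicates per (state, technique).
#' @return List with the `truth` object and a list of `fraction_experiment`s.
#' @export
simulate_study <- function(n_complexes = 50L, size_range = c(2L, 10L),
                           n_background = 200L, fraction_rewired = 0.2,
                           states = c("ECSC", "DNLC"),
                           techniques = c(SEC = 80L, IEC = 95L),
                           n_replicates = 2L, seed = 1L, noise = list()) {
  truth <- simulate_catalog(n_complexes, size_range, n_background,
                            seed = seed, states = states, noise = noise)
  truth <- apply_rewiring(truth, fraction_rewired, seed = seed + 1L)
  experiments <- list()
  i <- 0L
  for (st in states) {
    for (tech in names(techniques)) {
      for (rep_i in seq_len(n_replicates)) {
        i <- i + 1L
        experiments[[i]] <- simulate_experiment(
          truth, state = st, technique = tech, replicate = rep_i,
          n_fractions = techniques[[tech]], seed = seed + 1000L + i)
      }
    }
  }
  list(truth = truth, experiments = experiments)
}

#' Simulate a phosphosite table with known filter outcomes
#'
#' Generates phosphosite records (protein, position, residue, Ascore,
#' per-state replicate detections, known-site flag) together with the
#' ground-truth retention label under the canonical filter (Ascore >= 13 and
#' detection in >= 2 of 3 replicates, or presence in an external site
#' catalog).
#'
#' @param truth A `sim_truth` (supplies protein identifiers and state labels).
#' @param n_sites Number of sites to generate (>= 0).
#' @param seed Integer seed.
#' @param residue_mix Named probabilities for S/T/Y residues. The default
#'   follows the residue composition typical of mitochondrial
#'   phosphoproteomes (about 65/22/13).
#' @param prop_confident Proportion of sites drawn with a confidently
#'   localized Ascore (>= 13).
#' @param known_rate Probability that a site is flagged as previously
#'   catalogued.
#' @param detect_prob Per-replicate detection probability for a site truly
#'   present in a state (a site absent from a state is detected at rate 0.05).
#' @return Data frame of phosphosite records with `truth_retained_<state>`
#'   columns.
#' @export
simulate_phosphosites <- function(truth, n_sites, seed = truth$seed + 2L,
                                  residue_mix = c(S = 0.65, T = 0.22, Y = 0.13),
                                  prop_confident = 0.7, known_rate = 0.2,
                                  detect_prob = 0.8) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_sites < 0) stop("n_sites must be >= 0")
  states <- truth$states
  det_cols <- as.vector(outer(states, 1:3, function(s, r)
    paste0(s, "_rep", r)))
  if (n_sites == 0) {
    out <- data.frame(protein = character(), position = integer(),
                      residue = character(), ascore = numeric(),
                      known_site = logical(), stringsAsFactors = FALSE)
    for (cn in det_cols) out[[cn]] <- logical(0)
    for (st in states) out[[paste0("truth_retained_", st)]] <- logical(0)
    return(out)
  }
  withr::with_seed(seed, {
    residue <- sample(names(residue_mix), n_sites, replace = TRUE,
                      prob = residue_mix)
    confident <- runif(n_sites) < prop_confident
    ascore <- ifelse(confident, runif(n_sites, 13, 60), runif(n_sites, 0, 13))
    known <- runif(n_sites) < known_rate
    # presence pattern: both states, or specific to either state
    pattern <- sample(c("both", states), n_sites, replace = TRUE,
                      prob = c(0.4, 0.3, 0.3))
    out <- data.frame(
      protein = sample(truth$protein_universe, n_sites, replace = TRUE),
      position = sample.int(600L, n_sites, replace = TRUE),
      residue = residue, ascore = round(ascore, 2), known_site = known,
      stringsAsFactors = FALSE)
    for (st in states) {
      present <- pattern %in% c("both", st)
      for (r in 1:3) {
        p <- ifelse(present, detect_prob, 0.05)
        out[[paste0(st, "_rep", r)]] <- runif(n_sites) < p
      }
    }
  })
  for (st in states) {
    n_det <- rowSums(out[paste0(st, "_rep", 1:3)])
    out[[paste0("truth_retained_", st)]] <-
      out$ascore >= 13 & (n_det >= 2 | out$known_site)
  }
  out
}

#' Extract the planted catalog of one state as a reference catalog
#'
#' @param truth A `sim_truth`.
#' @param state State label (defaults to the first state).
#' @return A `complex_catalog` usable wherever a curated reference (e.g. a
#'   CORUM-like table) is expected.
#' @export
truth_catalog <- function(truth, state = truth$states[1]) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!state %in% truth$states) stop("unknown state label: ", state)
  new_complex_catalog(truth$complexes_per_state[[state]])
}
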