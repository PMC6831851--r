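# Co-elution similarity scoring. Three complementary measures per
# separation technique: Pearson correlation (global shape), weighted
# cross-correlation (shift-tolerant cosine), and co-apex score (fraction of
# experiments in which two proteins peak in the same fraction).

#' Filter unreliable detections from an experiment
#'
#' Zeroes fraction cells supported by fewer than `min_distinct_peptides`
#' distinct peptides (the classical >= 2-peptide rule for reliable co-elution
#' calls), then removes proteins detected in fewer than
#' `min_fractions_detected` fractions: a single-fraction profile carries no
#' co-elution information.
#'
#' @param exp A `fraction_experiment`.
#' @param min_distinct_peptides Minimum distinct-peptide count per cell
#'   (default 2).
#' @param min_fractions_detected Minimum number of nonzero fractions a
#'   protein must retain (default 2).
#' @return The filtered `fraction_experiment`.
#' @export
filter_proteins <- function(exp, min_distinct_peptides = 2L,
                            min_fractions_detected = 2L) {
  stopifnot(inherits(exp, "fraction_experiment"))
  counts <- exp$counts
  counts[counts < min_distinct_peptides] <- 0L
  keep <- rowSums(counts > 0) >= min_fractions_detected
  exp$counts <- counts[keep, , drop = FALSE]
  exp
}

#' Pearson correlation of two elution profiles
#'
#' Standard product-moment correlation over all fractions. Profiles with zero
#' variance have no defined correlation and yield `NA` (the pair is skipped,
#' not scored 0).
#'
#' @param profile_a,profile_b Equal-length non-negative count vectors.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pcc <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) {
    stop("profiles must have equal length")
  }
  if (sd(profile_a) == 0 || sd(profile_b) == 0) return(NA_real_)
  cor(profile_a, profile_b)
}

#' Weighted cross-correlation of two elution profiles
#'
#' Maximum over integer shifts `s` with `|s| <= max_shift` of
#' `w(s) * ncc(s)`, where `ncc(s)` is the cosine similarity of the
#' overlapping segments after shifting one profile by `s` fractions and
#' `w(s) = 1 - |s| / (max_shift + 1)` down-weights larger offsets. Negative
#' values are floored at 0 (counts are non-negative, so this only matters for
#' degenerate overlaps). All-zero profiles yield `NA`.
#'
#' @param profile_a,profile_b Equal-length non-negative count vectors.
#' @param max_shift Maximum absolute shift considered (default 2).
#' @return Score in `[0, 1]`, or `NA` if undefined.
#' @export
wcc <- function(profile_a, profile_b, max_shift = 2L) {
  n <- length(profile_a)
  if (length(profile_b) != n) stop("profiles must have equal length")
  if (max_shift < 0 || max_shift >= n) stop("max_shift must be in [0, n)")
  if (all(profile_a == 0) || all(profile_b == 0)) return(NA_real_)
  best <- NA_real_
  for (s in seq(-max_shift, max_shift)) {
    ia <- seq(max(1, 1 + s), min(n, n + s))   # a[i] aligned to b[i - s]
    ib <- ia - s
    na2 <- sum(profile_a[ia]^2)
    nb2 <- sum(profile_b[ib]^2)
    if (na2 == 0 || nb2 == 0) next
    ncc <- sum(profile_a[ia] * profile_b[ib]) / sqrt(na2 * nb2)
    cand <- (1 - abs(s) / (max_shift + 1)) * ncc
    if (is.na(best) || cand > best) best <- cand
  }
  if (is.na(best)) return(NA_real_)
  max(best, 0)
}

# apex fraction per protein: index of the maximum count, earliest on ties
apex_fractions <- function(counts) {
  apply(counts, 1, which.max)
}

#' Co-apex score for a protein pair
#'
#' Fraction of experiments in which both proteins attain their maximum count
#' in the same fraction, among experiments in which both are detected
#' (post-filter). Apex ties resolve to the earliest fraction. A pair never
#' co-detected has no defined score (`NA`).
#'
#' @param pair Character vector of two protein ids.
#' @param experiments List of (already filtered) `fraction_experiment`s.
#' @return Score in `[0, 1]`, or `NA` if the pair is never co-detected.
#' @export
coapex <- function(pair, experiments) {
  stopifnot(length(pair) == 2)
  hits <- 0L
  n_co <- 0L
  for (exp in experiments) {
    counts <- exp$counts
    if (!all(pair %in% rownames(counts))) next
    a <- counts[pair[1], ]
    b <- counts[pair[2], ]
    if (all(a == 0) || all(b == 0)) next
    n_co <- n_co + 1L
    if (which.max(a) == which.max(b)) hits <- hits + 1L
  }
  if (n_co == 0) return(NA_real_)
  hits / n_co
}

# vectorized all-pairs wcc over the rows of X (proteins x fractions);
# returns a symmetric matrix of max_s w(s) * ncc(s)
wcc_matrix <- function(X, max_shift) {
  n <- ncol(X)
  np <- nrow(X)
  best <- matrix(NA_real_, np, np)
  for (s in 0:max_shift) {
    ia <- seq(1 + s, n)
    ib <- seq(1, n - s)
    A <- X[, ia, drop = FALSE]
    B <- X[, ib, drop = FALSE]
    cross <- A %*% t(B)
    na2 <- rowSums(A^2)
    nb2 <- rowSums(B^2)
    denom <- sqrt(outer(na2, nb2))
    ncc <- cross / denom
    ncc[!is.finite(ncc)] <- NA_real_
    cand <- (1 - s / (max_shift + 1)) * ncc
    best <- pmax(best, cand, t(cand), na.rm = TRUE)
  }
  pmax(best, 0)
}

#' Score all protein pairs of one cell state
#'
#' For each separation technique, a pair is scored only if both proteins
#' survive [filter_proteins()] in *both* replicates of that technique
#' (co-detection in duplicate experiments). PCC and WCC are computed on
#' replicate-concatenated profiles by default (replicates contribute extra
#' fractions) or on replicate-averaged profiles; the co-apex score is
#' computed across the technique's replicate experiments.
#'
#' @param experiments List of `fraction_experiment`s from a single state,
#'   covering one or more techniques with their replicates.
#' @param min_distinct_peptides,min_fractions_detected Passed to
#'   [filter_proteins()].
#' @param max_shift Passed to [wcc()].
#' @param replicate_mode `"concatenate"` (default) or `"average"`.
#' @return Data frame with columns `protein_a`, `protein_b`, `technique`,
#'   `pcc`, `wcc`, `coapex` (one row per pair per technique; undefined
#'   metrics are `NA`), with the state label in attribute `"state"`.
#' @export
score_elution_pairs <- function(experiments, min_distinct_peptides = 2L,
                                min_fractions_detected = 2L, max_shift = 2L,
                                replicate_mode = c("concatenate", "average")) {
  replicate_mode <- match.arg(replicate_mode)
  if (length(experiments) == 0) stop("state with no experiments")
  states <- unique(vapply(experiments, `[[`, character(1), "state"))
  if (length(states) != 1) {
    stop("score_elution_pairs expects experiments from a single state")
  }
  techniques <- vapply(experiments, `[[`, character(1), "technique")
  out <- list()
  for (tech in unique(techniques)) {
    reps <- experiments[techniques == tech]
    filtered <- lapply(reps, filter_proteins,
                       min_distinct_peptides = min_distinct_peptides,
                       min_fractions_detected = min_fractions_detected)
    shared <- Reduce(intersect, lapply(filtered, function(e) rownames(e$counts)))
    shared <- sort(shared)
    if (length(shared) < 2) next
    mats <- lapply(filtered, function(e) e$counts[shared, , drop = FALSE])
    X <- if (replicate_mode == "concatenate") {
      do.call(cbind, mats)
    } else {
      Reduce(`+`, mats) / length(mats)
    }
    pcc_m <- suppressWarnings(cor(t(X)))
    wcc_m <- wcc_matrix(X, max_shift)
    apexes <- lapply(mats, apex_fractions)
    co_hit <- Reduce(`+`, lapply(apexes, function(a) outer(a, a, `==`)))
    coapex_m <- co_hit / length(mats)
    idx <- which(upper.tri(pcc_m), arr.ind = TRUE)
    out[[tech]] <- data.frame(
      protein_a = shared[idx[, 1]],
      protein_b = shared[idx[, 2]],
      technique = tech,
      pcc = pcc_m[idx],
      wcc = wcc_m[idx],
      coapex = coapex_m[idx],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    stop("no technique retained >= 2 proteins after filtering")
  }
  res <- do.call(rbind, out)
  res <- res[!(is.na(res$pcc) & is.na(res$wcc) & is.na(res$coapex)), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "state") <- states
  res
}

#' Score all protein pairs, grouped by cell state
#'
#' @param experiments List of `fraction_experiment`s covering one or more
#'   states.
#' @param ... Passed to [score_elution_pairs()].
#' @return Named list (one element per state) of pair-score data frames.
#' @export
score_all_pairs <- function(experiments, ...) {
  states <- vapply(experiments, `[[`, character(1), "state")
  lapply(split(experiments, states)[unique(states)],
         score_elution_pairs, ...)
}
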