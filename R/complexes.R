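# Complex discovery on a weighted interaction network (sigma-LLS edge
# weights): Markov clustering, ClusterONE-style greedy cohesiveness growth,
# and a core-attachment method; predictions are matched to a reference
# catalog with the overlap score omega = |A \cap B|^2 / (|A| |B|).
# Ties everywhere break by lexicographic node order, so all three
# algorithms are deterministic.

# weighted symmetric adjacency matrix, nodes sorted lexicographically
network_adjacency <- function(network, weight_col = "sigma_lls") {
  edges <- if (inherits(network, "static_network")) network$edges else network
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b") %in% names(edges)))
  if (nrow(edges) == 0) stop("network has no edges")
  w <- if (weight_col %in% names(edges)) edges[[weight_col]] else
    rep(1, nrow(edges))
  if (any(w <= 0)) stop("edge weights must be positive")
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  ia <- match(edges$protein_a, nodes)
  ib <- match(edges$protein_b, nodes)
  A[cbind(ia, ib)] <- w
  A[cbind(ib, ia)] <- w
  A
}

new_predicted_complexes <- function(members, algorithm, score) {
  members <- lapply(members, function(m) sort(unique(m)))
  structure(list(members = members, algorithm = algorithm,
                 score = score), class = "predicted_complexes")
}

#' @export
print.predicted_complexes <- function(x, ...) {
  sizes <- vapply(x$members, length, integer(1))
  cat(sprintf("%d complexes predicted by %s (sizes %s)\n",
              length(x$members), x$algorithm,
              if (length(sizes)) paste(range(sizes), collapse = "-") else "-"))
  invisible(x)
}

#' Markov clustering of a weighted network
#'
#' Classical MCL on the column-stochastic transition matrix of the weighted
#' graph (self-loops added): alternate expansion (matrix power), inflation
#' (elementwise power followed by column renormalization) and pruning of
#' entries below `prune`, until the matrix is stable. Clusters are the
#' connected components of the non-zero structure of the limit matrix;
#' singletons are discarded (a complex needs >= 2 members).
#'
#' @param network A `static_network` or edge data frame with positive
#'   weights in `sigma_lls`.
#' @param inflation Inflation exponent (default 2.0).
#' @param expansion Expansion power (default 2).
#' @param max_iter Iteration cap; non-convergence raises an error carrying
#'   the residual trace.
#' @param tol Convergence tolerance on the max absolute change.
#' @param prune Entries below this value are zeroed each iteration.
#' @return A `predicted_complexes` (scores are mean internal edge weights).
#' @export
mcl_cluster <- function(network, inflation = 2.0, expansion = 2L,
                        max_iter = 100L, tol = 1e-6, prune = 1e-5) {
  if (inflation <= 1) stop("inflation must be > 1")
  A <- network_adjacency(network)
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    E <- M
    for (p in seq_len(expansion - 1)) E <- E %*% M
    E <- E^inflation
    E[E < prune] <- 0
    E <- sweep(E, 2, colSums(E), "/")
    delta <- max(abs(E - M))
    trace <- c(trace, delta)
    M <- E
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("MCL did not converge after ", max_iter,
         " iterations; residual trace tail: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  }
  S <- (M > prune) | t(M > prune)
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  nodes <- rownames(A)
  members <- split(nodes, comp$membership)
  members <- members[vapply(members, length, integer(1)) >= 2]
  members <- unname(members[order(vapply(members, min, character(1)))])
  score <- vapply(members, function(m) {
    sub <- A[m, m]
    diag(sub) <- 0
    mean(sub[upper.tri(sub)][sub[upper.tri(sub)] > 0])
  }, numeric(1))
  new_predicted_complexes(members, "mcl", score)
}

# cohesiveness f(V) = w_in / (w_in + w_bound + penalty)
cohesiveness <- function(A, members, penalty) {
  idx <- members
  sub <- A[idx, idx, drop = FALSE]
  w_in <- sum(sub[upper.tri(sub)])
  w_bound <- sum(A[idx, -idx, drop = FALSE])
  w_in / (w_in + w_bound + penalty)
}

#' Greedy cohesiveness growth (ClusterONE-style)
#'
#' Grows candidate complexes from seeds in decreasing weighted-degree order,
#' maximizing the cohesiveness `f(V) = w_in / (w_in + w_bound + penalty)`
#' where `w_in` is the total internal edge weight and `w_bound` the total
#' boundary weight. Each step adds the boundary vertex (or removes the
#' member) giving the largest improvement, until no step improves `f`.
#' Grown sets with pairwise overlap score `omega >= overlap_merge` are
#' merged; sets smaller than `min_size` are dropped.
#'
#' @param network A `static_network` or edge data frame.
#' @param penalty Non-negative penalty modeling unobserved boundary weight
#'   (default 2).
#' @param overlap_merge Omega threshold above which grown sets merge
#'   (default 0.8).
#' @param min_size Minimum complex size (default 2).
#' @return A `predicted_complexes` (scores are cohesiveness values).
#' @export
cohesiveness_grow <- function(network, penalty = 2, overlap_merge = 0.8,
                              min_size = 2L) {
  if (penalty < 0) stop("penalty must be >= 0")
  A <- network_adjacency(network)
  nodes <- rownames(A)
  n <- length(nodes)
  wdeg <- rowSums(A)
  seed_order <- order(-wdeg, nodes)
  covered <- rep(FALSE, n)
  grown <- list()
  for (s in seed_order) {
    if (covered[s]) next
    V <- s
    f <- cohesiveness(A, V, penalty)
    repeat {
      nb <- which(colSums(A[V, , drop = FALSE] > 0) > 0)
      nb <- setdiff(nb, V)
      best_f <- f
      best_set <- NULL
      for (cand in nb) {
        f2 <- cohesiveness(A, c(V, cand), penalty)
        if (f2 > best_f + 1e-12) {
          best_f <- f2
          best_set <- c(V, cand)
        }
      }
      if (length(V) > 2) {
        for (cand in setdiff(V, s)) {
          f2 <- cohesiveness(A, setdiff(V, cand), penalty)
          if (f2 > best_f + 1e-12) {
            best_f <- f2
            best_set <- setdiff(V, cand)
          }
        }
      }
      if (is.null(best_set)) break
      V <- best_set
      f <- best_f
    }
    grown[[length(grown) + 1]] <- sort(V)
    covered[V] <- TRUE
  }
  # merge highly overlapping grown sets (transitively)
  merged <- lapply(grown, function(ix) nodes[ix])
  repeat {
    did_merge <- FALSE
    i <- 1
    while (i < length(merged)) {
      j <- i + 1
      while (j <= length(merged)) {
        if (omega(merged[[i]], merged[[j]]) >= overlap_merge) {
          merged[[i]] <- sort(union(merged[[i]], merged[[j]]))
          merged[[j]] <- NULL
          did_merge <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    if (!did_merge) break
  }
  merged <- merged[vapply(merged, length, integer(1)) >= min_size]
  merged <- unique(merged)
  merged <- merged[order(vapply(merged, min, character(1)))]
  score <- vapply(merged, function(m)
    cohesiveness(A, match(m, nodes), penalty), numeric(1))
  new_predicted_complexes(merged, "cohesiveness", score)
}

#' Core-attachment complex detection
#'
#' Cores are grown greedily from the highest-weight unused edges: neighbors
#' are added while the induced (unweighted) subgraph density stays at or
#' above `core_density`. Attachment proteins are outside nodes connected to
#' at least `attach_ratio` of a core's members; a complex is the core plus
#' its attachments.
#'
#' @param network A `static_network` or edge data frame.
#' @param core_density Minimum core density in (0, 1] (default 0.6).
#' @param attach_ratio Minimum fraction of core members an attachment must
#'   touch, in (0, 1] (default 0.5).
#' @return A `predicted_complexes` (scores are core densities).
#' @export
core_attach <- function(network, core_density = 0.6, attach_ratio = 0.5) {
  if (core_density <= 0 || core_density > 1) {
    stop("core_density must be in (0, 1]")
  }
  if (attach_ratio <= 0 || attach_ratio > 1) {
    stop("attach_ratio must be in (0, 1]")
  }
  A <- network_adjacency(network)
  B <- A > 0
  nodes <- rownames(A)
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  ord <- order(-A[ut], nodes[ut[, 1]], nodes[ut[, 2]])
  ut <- ut[ord, , drop = FALSE]
  used <- rep(FALSE, length(nodes))
  members <- list()
  score <- numeric(0)
  density_of <- function(ix) {
    k <- length(ix)
    sum(B[ix, ix]) / 2 / choose(k, 2)
  }
  for (e in seq_len(nrow(ut))) {
    u <- ut[e, 1]
    v <- ut[e, 2]
    if (used[u] || used[v]) next
    core <- c(u, v)
    repeat {
      cand <- which(colSums(B[core, , drop = FALSE]) > 0 & !used)
      cand <- setdiff(cand, core)
      if (length(cand) == 0) break
      dens <- vapply(cand, function(c0) density_of(c(core, c0)), numeric(1))
      keep <- dens >= core_density
      if (!any(keep)) break
      pick <- cand[keep][order(-dens[keep], nodes[cand[keep]])][1]
      core <- c(core, pick)
    }
    used[core] <- TRUE
    outside <- setdiff(seq_along(nodes), core)
    frac <- colSums(B[core, outside, drop = FALSE]) / length(core)
    attach <- outside[frac >= attach_ratio]
    members[[length(members) + 1]] <- sort(nodes[c(core, attach)])
    score <- c(score, density_of(core))
  }
  new_predicted_complexes(members, "core_attach", score)
}

#' Overlap score between two member sets
#'
#' `omega(A, B) = |A intersect B|^2 / (|A| * |B|)`, the standard statistic
#' for matching predicted complexes against a reference catalog; 0.25 is the
#' conventional recovery cutoff.
#'
#' @param a,b Non-empty character vectors.
#' @return Value in `[0, 1]`.
#' @export
omega <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0) stop("omega of an empty set")
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Match predictions to a reference catalog and select the best algorithm
#'
#' Each prediction is matched to its maximum-omega reference complex and
#' counted as recovered when `omega >= omega_cutoff`. Each algorithm then
#' receives an upper-tail hypergeometric p-value for its recovered count
#' against the pooled predictions of all algorithms (draws = the algorithm's
#' predictions, successes = recovered predictions overall); the best
#' algorithm is the one with the smallest p (ties: higher recovery rate,
#' then alphabetical order), which makes the selection deterministic.
#'
#' @param predictions Named list of `predicted_complexes` (or of plain
#'   member-set lists), one per algorithm.
#' @param catalog A `complex_catalog`.
#' @param omega_cutoff Recovery cutoff on omega (default 0.25).
#' @return List with `matches` (per-prediction data frame), `p_by_algorithm`
#'   and `best_algorithm`.
#' @export
match_and_select <- function(predictions, catalog, omega_cutoff = 0.25) {
  stopifnot(inherits(catalog, "complex_catalog"))
  if (length(predictions) == 0) stop("no algorithm predictions supplied")
  if (is.null(names(predictions))) {
    names(predictions) <- vapply(predictions, function(p)
      if (inherits(p, "predicted_complexes")) p$algorithm else "algorithm",
      character(1))
  }
  rows <- list()
  for (alg in names(predictions)) {
    p <- predictions[[alg]]
    sets <- if (inherits(p, "predicted_complexes")) p$members else p
    for (i in seq_along(sets)) {
      om <- vapply(catalog$complexes, omega, numeric(1), b = sets[[i]])
      best <- order(-om, names(catalog$complexes))[1]
      rows[[length(rows) + 1]] <- data.frame(
        algorithm = alg, prediction = i, size = length(sets[[i]]),
        best_ref = names(catalog$complexes)[best], omega = om[best],
        recovered = om[best] >= omega_cutoff, stringsAsFactors = FALSE)
    }
  }
  matches <- do.call(rbind, rows)
  if (is.null(matches)) stop("no predicted complexes to match")
  N <- nrow(matches)
  K <- sum(matches$recovered)
  p_by_alg <- vapply(names(predictions), function(alg) {
    n <- sum(matches$algorithm == alg)
    k <- sum(matches$algorithm == alg & matches$recovered)
    if (n == 0) return(1)
    hypergeom_p(k, K, n, N)
  }, numeric(1))
  rate <- vapply(names(predictions), function(alg) {
    n <- sum(matches$algorithm == alg)
    if (n == 0) return(0)
    sum(matches$algorithm == alg & matches$recovered) / n
  }, numeric(1))
  best <- names(predictions)[order(p_by_alg, -rate, names(predictions))][1]
  list(matches = matches, p_by_algorithm = p_by_alg, best_algorithm = best)
}

#' Catalog-side recovery rate of predicted complexes
#'
#' Fraction of reference complexes matched by at least one prediction with
#' `omega >= omega_cutoff`.
#'
#' @param predictions A `predicted_complexes` or list of member sets.
#' @param catalog A `complex_catalog`.
#' @param omega_cutoff Recovery cutoff (default 0.25).
#' @return Proportion in `[0, 1]`.
#' @export
complex_recall <- function(predictions, catalog, omega_cutoff = 0.25) {
  sets <- if (inherits(predictions, "predicted_complexes"))
    predictions$members else predictions
  if (length(sets) == 0) return(0)
  hit <- vapply(catalog$complexes, function(ref) {
    any(vapply(sets, function(s) omega(ref, s) >= omega_cutoff, logical(1)))
  }, logical(1))
  mean(hit)
}

#' Correlation of interaction profiles for a protein pair
#'
#' Pearson correlation of the two proteins' edge-weight vectors over all
#' other network nodes (the mutual edge and self entries are excluded;
#' absent edges count as weight 0). Subunits of the same complex tend to
#' share interaction partners and hence correlate positively.
#'
#' @param network A `static_network` or edge data frame.
#' @param pair Character vector of two protein ids, both present in the
#'   network.
#' @return Correlation in `[-1, 1]`, or `NA` when either profile has zero
#'   variance (e.g. a protein connected to nothing but its partner).
#' @export
interaction_profile_correlation <- function(network, pair) {
  stopifnot(length(pair) == 2)
  A <- network_adjacency(network)
  if (!all(pair %in% rownames(A))) stop("both proteins must be in the network")
  keep <- setdiff(rownames(A), pair)
  va <- A[pair[1], keep]
  vb <- A[pair[2], keep]
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  cor(va, vb)
}

#' One-sided rank-sum test: within-complex vs between-complex correlations
#'
#' Wilcoxon rank-sum p-value for the alternative that within-complex
#' interaction-profile correlations exceed between-complex ones.
#'
#' @param r_within,r_between Non-empty numeric samples.
#' @return The one-sided p-value.
#' @export
within_between_test <- function(r_within, r_between) {
  r_within <- r_within[!is.na(r_within)]
  r_between <- r_between[!is.na(r_between)]
  if (length(r_within) == 0 || length(r_between) == 0) {
    stop("both samples must be non-empty")
  }
  suppressWarnings(
    wilcox.test(r_within, r_between, alternative = "greater")$p.value)
}
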