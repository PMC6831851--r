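# Over-representation statistics: upper-tail hypergeometric tests with
# Benjamini-Hochberg FDR control, plus marker-based class assignment.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' population of `N` containing `K` successes. This is the one-sided
#' over-representation p-value used throughout the package.
#'
#' @param k Observed overlap count.
#' @param K Number of successes in the population (e.g. term size).
#' @param n Number of draws (e.g. query size).
#' @param N Population size (background).
#' @return The p-value in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_p(5, 5, 5, 10)  # 1 / choose(10, 5)
hypergeom_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    stop("inconsistent hypergeometric counts")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH procedure with monotonicity enforcement; the result preserves
#' the input order.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return q-values of the same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Annotation enrichment of a query set
#'
#' One upper-tail hypergeometric test per annotation term with non-empty
#' overlap (terms with `k = 0` are skipped), BH-corrected across the tested
#' terms. Annotation sets are harmonized to the background before testing.
#'
#' @param query Character vector of proteins/genes, a subset of `background`.
#' @param sets Named list of annotation term -> member vectors.
#' @param background Character vector defining the tested universe.
#' @return Data frame with one row per tested term: `term`, `k`, `K`, `n`,
#'   `N`, `p`, `q`, sorted by `q` then `p`.
#' @export
annotate_enrichment <- function(query, sets, background) {
  background <- unique(background)
  if (length(background) == 0) stop("background must be non-empty")
  query <- unique(query)
  if (!all(query %in% background)) {
    stop("query must be a subset of the background")
  }
  sets <- lapply(sets, function(s) intersect(unique(s), background))
  rows <- list()
  for (term in names(sets)) {
    K <- length(sets[[term]])
    k <- length(intersect(query, sets[[term]]))
    if (k == 0) next
    rows[[term]] <- data.frame(
      term = term, k = k, K = K, n = length(query), N = length(background),
      p = hypergeom_p(k, K, length(query), length(background)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker-based class assignment
#'
#' Assigns each entity (e.g. a single-cell cluster) the marker-set label
#' with the smallest upper-tail hypergeometric p-value for the overlap
#' between the entity's detected features and the marker set, provided that
#' p-value reaches the requested confidence (`p <= 1 - confidence`);
#' otherwise the entity is left unassigned (`NA`).
#'
#' @param entity_features Named list: entity -> character vector of detected
#'   genes/proteins.
#' @param marker_sets Named list: label -> marker gene vector.
#' @param background Character vector of all assayable features.
#' @param confidence Assignment confidence (default 0.95, i.e. p <= 0.05).
#' @return Data frame with `entity`, `label` (NA when unassigned) and `p`.
#' @export
marker_assignment <- function(entity_features, marker_sets, background,
                              confidence = 0.95) {
  if (length(marker_sets) == 0) stop("marker sets must be non-empty")
  background <- unique(background)
  if (length(background) == 0) stop("background must be non-empty")
  marker_sets <- lapply(marker_sets, function(s)
    intersect(unique(s), background))
  rows <- lapply(names(entity_features), function(ent) {
    feats <- intersect(unique(entity_features[[ent]]), background)
    p_all <- vapply(marker_sets, function(mk) {
      k <- length(intersect(feats, mk))
      hypergeom_p(k, length(mk), length(feats), length(background))
    }, numeric(1))
    best <- order(p_all, names(marker_sets))[1]
    assigned <- p_all[best] <= 1 - confidence
    data.frame(entity = ent,
               label = if (assigned) names(marker_sets)[best]
                       else NA_character_,
               p = p_all[best], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
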