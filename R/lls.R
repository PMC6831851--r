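# Naive-Bayes integration of raw co-elution scores into a single
# log-likelihood score (LLS) per pair. Each (technique, metric) evidence
# source is binned (equal-frequency bins over the reference pairs); a bin's
# LLS is the log ratio of its positive:negative odds to the prior odds.
# A pair's summed score over all available evidence is its edge weight
# (the sigma-LLS of the static networks).

#' Derive positive and negative reference pairs from a complex catalog
#'
#' Positives are pairs co-occurring in at least one catalog complex;
#' negatives are pairs of catalog proteins that never share a complex.
#' Both sets are restricted to the scored protein universe.
#'
#' @param catalog A `complex_catalog`.
#' @param scored_universe Character vector of proteins that were scored.
#' @return List with data frames `positives` and `negatives`.
#' @export
derive_reference_pairs <- function(catalog, scored_universe) {
  stopifnot(inherits(catalog, "complex_catalog"))
  prot <- sort(intersect(catalog$universe, scored_universe))
  if (length(prot) < 2) {
    stop("fewer than 2 catalog proteins are present in the scored universe")
  }
  pos <- cocomplex_pairs(catalog$complexes)
  pos <- pos[pos$protein_a %in% scored_universe &
               pos$protein_b %in% scored_universe, , drop = FALSE]
  all_m <- t(combn(prot, 2))
  all_df <- data.frame(protein_a = all_m[, 1], protein_b = all_m[, 2],
                       stringsAsFactors = FALSE)
  pos_key <- pair_id(pos$protein_a, pos$protein_b)
  neg <- all_df[!(pair_id(all_df$protein_a, all_df$protein_b) %in% pos_key), ,
                drop = FALSE]
  rownames(pos) <- rownames(neg) <- NULL
  list(positives = pos, negatives = neg)
}

METRICS <- c("pcc", "wcc", "coapex")

# weighted pool-adjacent-violators: smallest monotone non-decreasing fit
pava <- function(y, w) {
  n <- length(y)
  if (n <= 1) return(y)
  val <- y
  wt <- w
  len <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]
    wt[m] <- w[i]
    len[m] <- 1L
    while (m > 1 && val[m - 1] > val[m]) {
      val[m - 1] <- (wt[m - 1] * val[m - 1] + wt[m] * val[m]) /
        (wt[m - 1] + wt[m])
      wt[m - 1] <- wt[m - 1] + wt[m]
      len[m - 1] <- len[m - 1] + len[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], len[seq_len(m)])
}

#' Fit a binned log-likelihood model for each evidence source
#'
#' For every (technique, metric) present in `scores`, the raw scores of the
#' labeled reference pairs are cut into `n_bins` equal-frequency bins and
#' each bin `b` receives
#' `LLS(b) = ln[((pos_b + c) / (neg_b + c)) / (pos_total / neg_total)]`,
#' where `c` is the pseudocount keeping every bin finite. Only reference
#' pairs are used for fitting. Bin edges are extended to cover the whole
#' real line so any future score falls in a bin. With `monotone = TRUE`
#' (the default) the bin table is monotonized by weighted isotonic
#' regression: greater co-elution similarity cannot imply lower co-complex
#' odds, so adjacent violator bins are pooled, which de-noises the per-bin
#' estimates.
#'
#' @param scores Pair-score data frame from [score_elution_pairs()].
#' @param positives,negatives Reference pair data frames (see
#'   [derive_reference_pairs()]).
#' @param n_bins Number of equal-frequency bins per evidence source
#'   (default 10; collapses automatically when scores tie heavily).
#' @param pseudocount Smoothing constant added to each bin's class counts
#'   (default 1).
#' @param monotone Enforce a non-decreasing LLS across score bins
#'   (default `TRUE`).
#' @return An `lls_model`.
#' @export
fit_lls <- function(scores, positives, negatives, n_bins = 10L,
                    pseudocount = 1, monotone = TRUE) {
  if (nrow(positives) == 0 || nrow(negatives) == 0) {
    stop("need >= 1 positive and >= 1 negative reference pair")
  }
  key <- pair_id(scores$protein_a, scores$protein_b)
  lab <- rep(NA_character_, nrow(scores))
  lab[key %in% pair_id(positives$protein_a, positives$protein_b)] <- "pos"
  lab[key %in% pair_id(negatives$protein_a, negatives$protein_b)] <- "neg"
  tables <- list()
  for (tech in unique(scores$technique)) {
    for (metric in METRICS) {
      sel <- scores$technique == tech & !is.na(lab) & !is.na(scores[[metric]])
      if (!any(sel)) next
      x <- scores[[metric]][sel]
      y <- lab[sel]
      pos_tot <- sum(y == "pos")
      neg_tot <- sum(y == "neg")
      if (pos_tot == 0 || neg_tot == 0) next
      # equal-frequency with respect to the positive reference scores:
      # positives are rare among reference pairs, so pooled quantiles would
      # collapse nearly all of them into one bin and destroy resolution in
      # the score range where co-complex evidence actually lives
      breaks <- unique(quantile(x[y == "pos"],
                                probs = seq(0, 1, length.out = n_bins + 1),
                                names = FALSE, type = 7))
      breaks[1] <- -Inf
      breaks[length(breaks)] <- Inf
      if (length(breaks) < 2) breaks <- c(-Inf, Inf)
      bin <- findInterval(x, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
      nb <- length(breaks) - 1
      pos_b <- tabulate(bin[y == "pos"], nbins = nb)
      neg_b <- tabulate(bin[y == "neg"], nbins = nb)
      lls <- log(((pos_b + pseudocount) / (neg_b + pseudocount)) /
                   (pos_tot / neg_tot))
      if (monotone) lls <- pava(lls, pos_b + neg_b + 2 * pseudocount)
      tables[[paste(tech, metric, sep = ".")]] <- list(
        technique = tech, metric = metric, breaks = breaks, lls = lls,
        pos = pos_b, neg = neg_b)
    }
  }
  if (length(tables) == 0) stop("no evidence source had labeled scores")
  pos_tot <- sum(!is.na(lab) & lab == "pos")
  neg_tot <- sum(!is.na(lab) & lab == "neg")
  structure(list(tables = tables, prior_odds = pos_tot / neg_tot,
                 pseudocount = pseudocount, n_bins = n_bins),
            class = "lls_model")
}

#' @export
print.lls_model <- function(x, ...) {
  cat(sprintf("LLS model: %d evidence sources, prior odds %.4g\n",
              length(x$tables), x$prior_odds))
  for (nm in names(x$tables)) {
    t <- x$tables[[nm]]
    cat(sprintf("  %-12s %d bins, LLS range [%.2f, %.2f]\n", nm,
                length(t$lls), min(t$lls), max(t$lls)))
  }
  invisible(x)
}

#' Sum per-evidence LLS values into a single score per pair
#'
#' Each pair's score is the sum, over every available (technique, metric)
#' evidence, of the LLS of the bin its raw score falls into; missing
#' evidence contributes 0.
#'
#' @param model An `lls_model`.
#' @param scores Pair-score data frame (same layout as used for fitting).
#' @return Data frame with `protein_a`, `protein_b`, `sigma_lls`, carrying
#'   over the `"state"` attribute of `scores`.
#' @export
sum_lls <- function(model, scores) {
  stopifnot(inherits(model, "lls_model"))
  contrib <- numeric(nrow(scores))
  for (tab in model$tables) {
    sel <- scores$technique == tab$technique & !is.na(scores[[tab$metric]])
    if (!any(sel)) next
    bin <- findInterval(scores[[tab$metric]][sel], tab$breaks,
                        rightmost.closed = TRUE, all.inside = TRUE)
    contrib[sel] <- contrib[sel] + tab$lls[bin]
  }
  key <- pair_id(scores$protein_a, scores$protein_b)
  sums <- rowsum(contrib, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(protein_a = scores$protein_a[first],
                    protein_b = scores$protein_b[first],
                    sigma_lls = as.numeric(sums[match(key[first],
                                                      rownames(sums))]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "state") <- attr(scores, "state")
  out
}

#' Youden-optimal threshold on a score, with optional prevalence weighting
#'
#' Maximizes the generalized Youden index `J = se + r * sp - 1` with
#' `r = (1 - prev) / (cost * prev)`. With `prevalence = 0.5` and unit cost
#' this is the classic equal-weight Youden point; passing the empirical
#' prevalence of the labeled pairs yields the cost-sensitive form, which is
#' the appropriate reading of a "stringent" cutoff when reference negatives
#' vastly outnumber positives (an unweighted optimum would admit large
#' numbers of false edges purely because specificity is cheap).
#'
#' @param roc A `pROC::roc` object.
#' @param prevalence Assumed positive prevalence (default 0.5 = classic).
#' @param cost Relative cost of a false negative vs a false positive.
#' @return The threshold value.
#' @keywords internal
youden_threshold <- function(roc, prevalence = 0.5, cost = 1) {
  best <- pROC::coords(roc, "best", best.method = "youden",
                       best.weights = c(cost, prevalence),
                       transpose = FALSE)
  as.numeric(best$threshold[1])
}

# label sigma-lls pairs against reference sets: "pos"/"neg"/NA
label_pairs <- function(sigma, positives, negatives) {
  key <- pair_id(sigma$protein_a, sigma$protein_b)
  lab <- rep(NA_character_, nrow(sigma))
  lab[key %in% pair_id(positives$protein_a, positives$protein_b)] <- "pos"
  lab[key %in% pair_id(negatives$protein_a, negatives$protein_b)] <- "neg"
  lab
}

roc_auc <- function(labels, score) {
  r <- pROC::roc(response = labels, predictor = score,
                 levels = c("neg", "pos"), direction = "<", quiet = TRUE)
  r
}

#' Threshold summed LLS scores into a static network
#'
#' Builds the ROC of the summed score against labeled reference pairs,
#' reports the AUC, and retains every scored pair with `sigma_lls` strictly
#' above the threshold. The threshold is `fixed` when supplied (the
#' conventional stringent cutoff is 1.45, i.e. associations with
#' sigma-LLS <= 1.45 are eliminated); with `fixed = NULL` the point
#' maximizing Youden's J on the ROC is used. Because reference negatives
#' typically outnumber positives by one to two orders of magnitude, the
#' Youden index is prevalence-weighted by default (see
#' [youden_threshold()]); `weighted = FALSE` gives the classic equal-weight
#' form.
#'
#' @param sigma Data frame from [sum_lls()].
#' @param positives,negatives Reference pair data frames.
#' @param fixed Fixed threshold, or `NULL` to choose by Youden's J
#'   (default 1.45).
#' @param weighted Use the prevalence-weighted Youden index when choosing
#'   the threshold automatically (default `TRUE`).
#' @param state Optional state label (defaults to the `"state"` attribute).
#' @return A `static_network`: list with `state`, `edges` (pairs with
#'   `sigma_lls`), `threshold` and `auc`.
#' @export
choose_threshold <- function(sigma, positives, negatives, fixed = 1.45,
                             weighted = TRUE,
                             state = attr(sigma, "state")) {
  lab <- label_pairs(sigma, positives, negatives)
  if (length(unique(lab[!is.na(lab)])) < 2) {
    stop("degenerate labels: need both positive and negative scored pairs")
  }
  r <- roc_auc(factor(lab[!is.na(lab)], levels = c("neg", "pos")),
               sigma$sigma_lls[!is.na(lab)])
  auc <- as.numeric(r$auc)
  threshold <- if (!is.null(fixed)) {
    as.numeric(fixed)
  } else if (weighted) {
    prev <- sum(lab == "pos", na.rm = TRUE) / sum(!is.na(lab))
    youden_threshold(r, prevalence = prev)
  } else {
    youden_threshold(r)
  }
  edges <- sigma[sigma$sigma_lls > threshold, , drop = FALSE]
  edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(state = if (is.null(state)) NA_character_ else state,
                 edges = edges, threshold = threshold, auc = auc),
            class = "static_network")
}

#' @export
print.static_network <- function(x, ...) {
  cat(sprintf(
    "Static network (%s): %d edges, sigma-LLS > %.3f, reference AUC %.3f\n",
    x$state, nrow(x$edges), x$threshold, x$auc))
  invisible(x)
}

#' Complex-level k-fold cross-validation of the LLS pipeline
#'
#' Folds are split at the complex level: all co-complex pairs of a complex
#' share a fold, so no within-complex pair appears in both training and test
#' sets. For each fold the LLS model is refit on the training complexes only
#' and the AUC is measured on the held-out complexes' pairs (held-out
#' negatives are pairs of held-out-complex proteins that never share a
#' complex in the full catalog).
#'
#' @param catalog A `complex_catalog`.
#' @param scores Pair-score data frame for one state.
#' @param k Number of folds (>= 2, <= number of complexes; default 5).
#' @param seed Integer seed for the fold assignment.
#' @param n_bins,pseudocount Passed to [fit_lls()].
#' @return Numeric vector of per-fold AUCs.
#' @export
crossvalidate <- function(catalog, scores, k = 5L, seed = 1L, n_bins = 10L,
                          pseudocount = 1) {
  stopifnot(inherits(catalog, "complex_catalog"))
  n_cpx <- length(catalog$complexes)
  if (k < 2) stop("k must be >= 2")
  if (k > n_cpx) stop("k exceeds the number of complexes")
  scored_universe <- unique(c(scores$protein_a, scores$protein_b))
  full_pos_key <- with(cocomplex_pairs(catalog$complexes),
                       pair_id(protein_a, protein_b))
  fold <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n_cpx)))
  aucs <- numeric(k)
  for (i in seq_len(k)) {
    train_cat <- new_complex_catalog(catalog$complexes[fold != i])
    test_cpx <- catalog$complexes[fold == i]
    refs <- derive_reference_pairs(train_cat, scored_universe)
    model <- fit_lls(scores, refs$positives, refs$negatives,
                     n_bins = n_bins, pseudocount = pseudocount)
    sigma <- sum_lls(model, scores)
    test_prot <- sort(intersect(unique(unlist(test_cpx)), scored_universe))
    if (length(test_prot) < 2) stop("held-out fold has < 2 scored proteins")
    test_pos <- cocomplex_pairs(test_cpx)
    test_pos <- test_pos[test_pos$protein_a %in% scored_universe &
                           test_pos$protein_b %in% scored_universe, ,
                         drop = FALSE]
    all_m <- t(combn(test_prot, 2))
    all_key <- pair_id(all_m[, 1], all_m[, 2])
    neg_key <- all_key[!(all_key %in% full_pos_key)]
    key <- pair_id(sigma$protein_a, sigma$protein_b)
    lab <- rep(NA_character_, nrow(sigma))
    lab[key %in% pair_id(test_pos$protein_a, test_pos$protein_b)] <- "pos"
    lab[key %in% neg_key] <- "neg"
    if (length(unique(lab[!is.na(lab)])) < 2) {
      stop("held-out fold lacks scored pairs of both classes")
    }
    r <- roc_auc(factor(lab[!is.na(lab)], levels = c("neg", "pos")),
                 sigma$sigma_lls[!is.na(lab)])
    aucs[i] <- as.numeric(r$auc)
  }
  aucs
}

#' Co-complex enrichment in a score percentile of the network
#'
#' Tests whether edges in the top (or bottom) `percentile` of sigma-LLS
#' scores are enriched for membership in the same reference complex,
#' relative to all scored edges covered by the catalog (both proteins in the
#' catalog universe). The p-value is the upper-tail hypergeometric
#' probability (see [hypergeom_p()]).
#'
#' @param network A `static_network`, or a data frame of pairs with
#'   `sigma_lls`.
#' @param catalog A `complex_catalog`.
#' @param percentile Proportion of edges in the tested tail, in (0, 1)
#'   (default 0.20).
#' @param side `"top"` (highest scores, default) or `"bottom"`.
#' @return List with counts `k`, `K`, `n`, `N` and the p-value `p`.
#' @export
percentile_cocomplex_enrichment <- function(network, catalog,
                                            percentile = 0.20,
                                            side = c("top", "bottom")) {
  side <- match.arg(side)
  edges <- if (inherits(network, "static_network")) network$edges else network
  if (nrow(edges) == 0) stop("network is empty")
  if (percentile <= 0 || percentile >= 1) {
    stop("percentile must be in (0, 1)")
  }
  covered <- edges[edges$protein_a %in% catalog$universe &
                     edges$protein_b %in% catalog$universe, , drop = FALSE]
  if (nrow(covered) == 0) stop("no network edge is covered by the catalog")
  pos_key <- with(cocomplex_pairs(catalog$complexes),
                  pair_id(protein_a, protein_b))
  is_cocomplex <- pair_id(covered$protein_a, covered$protein_b) %in% pos_key
  n_tail <- max(1L, ceiling(percentile * nrow(covered)))
  ord <- order(covered$sigma_lls,
               decreasing = (side == "top"))
  tail_idx <- ord[seq_len(n_tail)]
  k <- sum(is_cocomplex[tail_idx])
  K <- sum(is_cocomplex)
  n <- n_tail
  N <- nrow(covered)
  list(k = k, K = K, n = n, N = N, p = hypergeom_p(k, K, n, N))
}

#' One-step state network inference
#'
#' Convenience wrapper chaining [derive_reference_pairs()], [fit_lls()],
#' [sum_lls()] and [choose_threshold()] for one state's pair scores.
#'
#' @param scores Pair-score data frame from [score_elution_pairs()].
#' @param catalog A `complex_catalog` used as the reference.
#' @param fixed Threshold passed to [choose_threshold()] (`NULL` = Youden).
#' @param weighted Passed to [choose_threshold()].
#' @param n_bins,pseudocount Passed to [fit_lls()].
#' @return List with `network` (a `static_network`), `sigma` (all scored
#'   pairs with their summed LLS), `model` and `refs`.
#' @export
build_state_network <- function(scores, catalog, fixed = NULL,
                                weighted = TRUE, n_bins = 10L,
                                pseudocount = 1) {
  scored_universe <- unique(c(scores$protein_a, scores$protein_b))
  refs <- derive_reference_pairs(catalog, scored_universe)
  model <- fit_lls(scores, refs$positives, refs$negatives, n_bins = n_bins,
                   pseudocount = pseudocount)
  sigma <- sum_lls(model, scores)
  network <- choose_threshold(sigma, refs$positives, refs$negatives,
                              fixed = fixed, weighted = weighted)
  list(network = network, sigma = sigma, model = model, refs = refs)
}
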