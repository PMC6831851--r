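# Differential (DF) network: fold change of the summed LLS between two
# cell states, z-score of the log2 fold change over all DF edges,
# significance at |z| >= 1.96 (two-sided p <= 0.05), and rewiring labels
# for significant edges with fold change >= 2 (or <= 1/2).

#' Compute per-pair fold changes of sigma-LLS between two states
#'
#' The fold change is `sigma_lls_b / sigma_lls_a` (in the study design this
#' is the differentiated state relative to the stem state). A pair scored in
#' only one state uses the `floor` value for the missing state, so that
#' state-specific pairs still enter the DF network; scores below the floor
#' (including non-positive sigma-LLS values, which a log-likelihood sum can
#' produce) are raised to it so that every fold change is positive.
#'
#' @param scores_a,scores_b Data frames of pairs with `sigma_lls` for the
#'   reference state (`a`) and the contrasted state (`b`) — typically the
#'   edge tables of the two static networks.
#' @param floor Positive pseudo-score for missing/low values. Default: the
#'   smallest positive `sigma_lls` observed across both states.
#' @param states Length-2 character vector naming states `a` and `b`.
#' @return Data frame of `differential_edges`: `protein_a`, `protein_b`,
#'   `sigma_lls_a`, `sigma_lls_b` (NA when unscored), `fc`, `log2fc`; the
#'   state names are kept in attribute `"states"`.
#' @export
compute_fold_changes <- function(scores_a, scores_b, floor = NULL,
                                 states = c(attr(scores_a, "state"),
                                            attr(scores_b, "state"))) {
  if (inherits(scores_a, "static_network")) {
    states[1] <- scores_a$state
    scores_a <- scores_a$edges
  }
  if (inherits(scores_b, "static_network")) {
    states[2] <- scores_b$state
    scores_b <- scores_b$edges
  }
  if (nrow(scores_a) + nrow(scores_b) == 0) {
    stop("need >= 1 scored pair in at least one state")
  }
  if (is.null(floor)) {
    pool <- c(scores_a$sigma_lls, scores_b$sigma_lls)
    pool <- pool[pool > 0]
    if (length(pool) == 0) stop("no positive sigma-LLS to derive a floor from")
    floor <- min(pool)
  }
  if (floor <= 0) stop("floor must be positive")
  key_a <- pair_id(scores_a$protein_a, scores_a$protein_b)
  key_b <- pair_id(scores_b$protein_a, scores_b$protein_b)
  all_key <- union(key_a, key_b)
  parts <- strsplit(all_key, PAIR_SEP, fixed = TRUE)
  out <- data.frame(
    protein_a = vapply(parts, `[[`, character(1), 1),
    protein_b = vapply(parts, `[[`, character(1), 2),
    sigma_lls_a = scores_a$sigma_lls[match(all_key, key_a)],
    sigma_lls_b = scores_b$sigma_lls[match(all_key, key_b)],
    stringsAsFactors = FALSE)
  va <- pmax(ifelse(is.na(out$sigma_lls_a), floor, out$sigma_lls_a), floor)
  vb <- pmax(ifelse(is.na(out$sigma_lls_b), floor, out$sigma_lls_b), floor)
  out$fc <- vb / va
  out$log2fc <- log2(out$fc)
  # floored edges carry a coverage/floor artifact in their fold change and
  # are excluded from the null when z-scoring
  out$floored <- is.na(out$sigma_lls_a) | is.na(out$sigma_lls_b) |
    out$sigma_lls_a < floor | out$sigma_lls_b < floor
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  if (any(is.na(states)) || length(states) != 2) states <- c("a", "b")
  attr(out, "states") <- stats::setNames(states, c("a", "b"))
  attr(out, "floor") <- floor
  out
}

#' Build the differential network from two state analyses
#'
#' The DF edge universe is every pair retained in at least one state's
#' static network; per-state values are taken from the *full* scored
#' sigma-LLS tables, so a pair that passed the threshold in one state
#' contributes its actual (possibly sub-threshold) score in the other state
#' rather than the floor. Fold changes are computed by
#' [compute_fold_changes()], then z-scored and classified.
#'
#' @param res_a,res_b Results of [build_state_network()] for the reference
#'   and contrasted state (or lists with `network` and `sigma`).
#' @param floor,z_threshold,fc_cutoff Passed to the respective steps.
#' @return Annotated differential edge table (see [classify_rewired()]).
#' @export
build_differential_network <- function(res_a, res_b, floor = NULL,
                                       z_threshold = 1.96, fc_cutoff = 2.0) {
  sig_a <- res_a$sigma
  sig_b <- res_b$sigma
  attr(sig_a, "state") <- res_a$network$state
  attr(sig_b, "state") <- res_b$network$state
  df <- compute_fold_changes(sig_a, sig_b, floor = floor)
  states <- attr(df, "states")
  used_floor <- attr(df, "floor")
  keep_key <- union(
    pair_id(res_a$network$edges$protein_a, res_a$network$edges$protein_b),
    pair_id(res_b$network$edges$protein_a, res_b$network$edges$protein_b))
  df <- df[pair_id(df$protein_a, df$protein_b) %in% keep_key, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "states") <- states
  attr(df, "floor") <- used_floor
  df <- zscore_edges(df, z_threshold = z_threshold)
  classify_rewired(df, fc_cutoff = fc_cutoff)
}

#' Z-score differential edges
#'
#' Standardizes `log2fc` against the empirical mean and standard deviation
#' of the null distribution of the scored data and flags edges with
#' `|z| >= z_threshold` as significant. The default threshold 1.96 is the
#' two-sided normal critical value at p = 0.05 (two standard deviations).
#'
#' By default the null moments are estimated from the un-floored edges
#' (both states observed above the floor): fold changes involving the floor
#' are bounded by `log2(max score / floor)`, so including them in the null
#' inflates the standard deviation towards (or beyond) that bound and the
#' gate can become unsatisfiable by construction. `null = "all"` uses the
#' moments of every DF edge instead.
#'
#' @param edges Data frame from [compute_fold_changes()].
#' @param z_threshold Absolute z cutoff (default 1.96).
#' @param null Population used for the null moments: `"unfloored"`
#'   (default) or `"all"`.
#' @return `edges` with added columns `z` and `significant`.
#' @export
zscore_edges <- function(edges, z_threshold = 1.96,
                         null = c("unfloored", "all")) {
  null <- match.arg(null)
  lfc <- edges$log2fc
  if (sum(is.finite(lfc)) < 2) stop("need >= 2 edges with finite log2fc")
  ref <- if (null == "unfloored" && !is.null(edges$floored) &&
               sum(!edges$floored) >= 2) {
    lfc[!edges$floored]
  } else {
    lfc
  }
  s <- sd(ref)
  if (s == 0) stop("zero standard deviation of log2fc")
  edges$z <- (lfc - mean(ref)) / s
  edges$significant <- abs(edges$z) >= z_threshold
  attr(edges, "z_threshold") <- z_threshold
  edges
}

#' Classify significant differential edges as rewired
#'
#' Among significant edges (significance gates rewiring), a fold change
#' `>= fc_cutoff` is labeled specific to state `b` and `<= 1/fc_cutoff`
#' specific to state `a`; everything else is `"none"`.
#'
#' @param edges Data frame from [zscore_edges()].
#' @param fc_cutoff Fold-change cutoff (> 1; default 2.0).
#' @return `edges` with an added `rewired_label` column taking values
#'   `"none"`, `"<state_b>_specific"` or `"<state_a>_specific"`.
#' @export
classify_rewired <- function(edges, fc_cutoff = 2.0) {
  if (is.null(edges$significant)) {
    stop("run zscore_edges() before classify_rewired()")
  }
  if (fc_cutoff <= 1) stop("fc_cutoff must be > 1")
  states <- attr(edges, "states")
  if (is.null(states)) states <- c(a = "a", b = "b")
  lab_b <- paste0(states[["b"]], "_specific")
  lab_a <- paste0(states[["a"]], "_specific")
  label <- rep("none", nrow(edges))
  label[edges$significant & edges$fc >= fc_cutoff] <- lab_b
  label[edges$significant & edges$fc <= 1 / fc_cutoff] <- lab_a
  edges$rewired_label <- label
  attr(edges, "fc_cutoff") <- fc_cutoff
  edges
}
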