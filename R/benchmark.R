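# End-to-end recovery benchmark on the default synthetic study: plants a
# catalog, rewires a fraction of complexes, simulates SEC/IEC duplicates
# for both states, runs scoring -> LLS integration -> thresholding ->
# differential analysis -> complex discovery, and measures recovery of the
# planted structure.

#' Run the full pipeline on a simulated study and measure recovery
#'
#' The default arguments reproduce the package's reference study design:
#' 50 planted complexes (sizes 2-10), 200 monomeric background proteins,
#' 20% of complexes rewired between the two states, two separation
#' techniques (SEC 80 fractions, IEC 95) in duplicate per state, default
#' count noise. All randomness derives from `seed`.
#'
#' Reported metrics:
#' * `auc` - per-state ROC AUC of the summed LLS against the planted
#'   reference pairs;
#' * `cv_aucs` - complex-level 5-fold cross-validated AUCs (first state);
#' * `pair_recall` / `pair_fdr` - pooled over states at the chosen
#'   thresholds: recall of planted co-complex pairs among the scored
#'   reference pairs (the ROC population) and the false discovery rate of
#'   network edges against planted negatives;
#' * `rewired_recall` - fraction of planted rewired pairs receiving the
#'   correct state-specific label in the differential network;
#' * `rewired_rank_p` - one-sided rank-sum p that planted rewired pairs
#'   have larger |log2 fold change| than planted stable co-complex pairs;
#' * `complex_recall` - per-algorithm fraction of planted complexes
#'   recovered at omega >= 0.25 from the second state's network;
#' * `best_algorithm` - winner of [match_and_select()];
#' * `enrichment_p` - top-percentile co-complex enrichment p (first state).
#'
#' @param seed Integer seed driving the whole study.
#' @param n_complexes,size_range,n_background,fraction_rewired,techniques
#'   Study design, as in [simulate_study()].
#' @param k Cross-validation folds (default 5).
#' @param omega_cutoff Complex recovery cutoff (default 0.25).
#' @return A list of metrics (see details), plus the `truth`, the per-state
#'   `networks`, the differential table `df_edges`, the clustering
#'   `predictions` and the `catalogs` used.
#' @export
run_simulation_benchmark <- function(seed = 1L, n_complexes = 50L,
                                     size_range = c(2L, 10L),
                                     n_background = 200L,
                                     fraction_rewired = 0.2,
                                     techniques = c(SEC = 80L, IEC = 95L),
                                     k = 5L, omega_cutoff = 0.25) {
  sim <- simulate_study(n_complexes = n_complexes, size_range = size_range,
                        n_background = n_background,
                        fraction_rewired = fraction_rewired,
                        techniques = techniques, seed = seed)
  truth <- sim$truth
  states <- truth$states
  scores <- score_all_pairs(sim$experiments)

  res <- list()
  tp <- fp <- pos_scored <- 0
  for (st in states) {
    r <- build_state_network(scores[[st]], truth_catalog(truth, st),
                             fixed = NULL)
    res[[st]] <- r
    lab_net <- label_pairs(r$network$edges, r$refs$positives,
                           r$refs$negatives)
    lab_all <- label_pairs(r$sigma, r$refs$positives, r$refs$negatives)
    tp <- tp + sum(lab_net == "pos", na.rm = TRUE)
    fp <- fp + sum(lab_net == "neg", na.rm = TRUE)
    pos_scored <- pos_scored + sum(lab_all == "pos", na.rm = TRUE)
  }

  cv_aucs <- crossvalidate(truth_catalog(truth, states[1]),
                           scores[[states[1]]], k = k, seed = seed)
  enr <- percentile_cocomplex_enrichment(res[[states[1]]]$network,
                                         truth_catalog(truth, states[1]))

  df <- build_differential_network(res[[states[1]]], res[[states[2]]])
  rw <- truth$rewired_pairs
  dfk <- pair_id(df$protein_a, df$protein_b)
  rwk <- pair_id(rw$protein_a, rw$protein_b)
  correct <- logical(nrow(rw))
  for (i in seq_len(nrow(rw))) {
    j <- match(rwk[i], dfk)
    if (is.na(j)) next
    correct[i] <- df$rewired_label[j] ==
      paste0(rw$present_in[i], "_specific")
  }
  stable <- cocomplex_pairs(truth$complexes_per_state[[1]])
  stable_k <- setdiff(pair_id(stable$protein_a, stable$protein_b), rwk)
  is_rw <- dfk %in% rwk
  is_stable <- dfk %in% stable_k
  rank_p <- if (any(is_rw) && any(is_stable)) {
    suppressWarnings(wilcox.test(abs(df$log2fc[is_rw]),
                                 abs(df$log2fc[is_stable]),
                                 alternative = "greater")$p.value)
  } else NA_real_

  net2 <- res[[states[2]]]$network
  cat2 <- truth_catalog(truth, states[2])
  predictions <- list(mcl = mcl_cluster(net2),
                      cohesiveness = cohesiveness_grow(net2),
                      core_attach = core_attach(net2))
  recs <- vapply(predictions, complex_recall, numeric(1), catalog = cat2,
                 omega_cutoff = omega_cutoff)
  ms <- match_and_select(predictions, cat2, omega_cutoff = omega_cutoff)

  list(
    auc = vapply(res, function(r) r$network$auc, numeric(1)),
    cv_aucs = cv_aucs,
    thresholds = vapply(res, function(r) r$network$threshold, numeric(1)),
    n_edges = vapply(res, function(r) nrow(r$network$edges), integer(1)),
    pair_recall = tp / pos_scored,
    pair_fdr = fp / (fp + tp),
    enrichment_p = enr$p,
    rewired_recall = mean(correct),
    rewired_rank_p = rank_p,
    complex_recall = recs,
    best_algorithm = ms$best_algorithm,
    match_p = ms$p_by_algorithm,
    truth = truth,
    networks = lapply(res, `[[`, "network"),
    df_edges = df,
    predictions = predictions,
    catalogs = stats::setNames(
      lapply(states, function(st) truth_catalog(truth, st)), states)
  )
}
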