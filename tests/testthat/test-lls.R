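test_that("derive_reference_pairs enumerates co-complex and cross-complex pairs", {
  cat1 <- complex_catalog(list(c1 = c("A", "B", "C"), c2 = c("C", "D")))
  refs <- derive_reference_pairs(cat1, c("A", "B", "C", "D", "X"))
  expect_identical(paste(refs$positives$protein_a, refs$positives$protein_b),
                   c("A B", "A C", "B C", "C D"))
  expect_identical(paste(refs$negatives$protein_a, refs$negatives$protein_b),
                   c("A D", "B D"))

  # a protein absent from the scored universe contributes no pairs
  refs2 <- derive_reference_pairs(cat1, c("A", "B", "C"))
  expect_false("D" %in% c(refs2$positives$protein_a,
                          refs2$positives$protein_b,
                          refs2$negatives$protein_a,
                          refs2$negatives$protein_b))

  expect_error(derive_reference_pairs(cat1, c("A", "Z")),
               "fewer than 2")

  # a single complex yields zero negatives; training then fails
  cat_one <- complex_catalog(list(c1 = c("A", "B")))
  refs3 <- derive_reference_pairs(cat_one, c("A", "B"))
  expect_identical(nrow(refs3$negatives), 0L)
  sc <- data.frame(protein_a = "A", protein_b = "B", technique = "SEC",
                   pcc = 0.9, wcc = 0.9, coapex = 1)
  expect_error(fit_lls(sc, refs3$positives, refs3$negatives), "negative")
})

make_scores <- function(pos_scores, neg_scores) {
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  pos_names <- sprintf("POS%03d", seq_len(n_pos))
  neg_names <- sprintf("NEG%03d", seq_len(n_neg))
  scores <- data.frame(
    protein_a = paste0(c(pos_names, neg_names), "a"),
    protein_b = paste0(c(pos_names, neg_names), "b"),
    technique = "SEC",
    pcc = c(pos_scores, neg_scores), wcc = NA_real_, coapex = NA_real_,
    stringsAsFactors = FALSE)
  positives <- scores[seq_len(n_pos), c("protein_a", "protein_b")]
  negatives <- scores[n_pos + seq_len(n_neg), c("protein_a", "protein_b")]
  list(scores = scores, positives = positives, negatives = negatives)
}

test_that("fit_lls reproduces hand-computed log-odds", {
  # totals 10 pos / 90 neg; top bin holds 5 pos and 5 neg -> ln 9
  d <- make_scores(c(rep(0.5, 5), rep(0.9, 5)),
                   c(rep(0.1, 85), rep(0.9, 5)))
  model <- fit_lls(d$scores, d$positives, d$negatives, n_bins = 2)
  tab <- model$tables[["SEC.pcc"]]
  expect_identical(tab$pos, c(5L, 5L))
  expect_identical(tab$neg, c(85L, 5L))
  expect_equal(tab$lls[2], log(9))

  # bin with pos/neg ratio equal to the prior ratio has LLS = 0
  d0 <- make_scores(c(rep(0.2, 4), rep(0.8, 4)),
                    c(rep(0.2, 4), rep(0.8, 4)))
  m0 <- fit_lls(d0$scores, d0$positives, d0$negatives, n_bins = 2,
                pseudocount = 0)
  expect_equal(m0$tables[["SEC.pcc"]]$lls, c(0, 0))

  # a bin with 0 negatives stays finite under the pseudocount
  d1 <- make_scores(c(0.8, 0.8, 0.8, 0.9, 0.9, 0.9), rep(0.1, 6))
  m1 <- fit_lls(d1$scores, d1$positives, d1$negatives, n_bins = 2)
  expect_true(all(is.finite(m1$tables[["SEC.pcc"]]$lls)))
  expect_gt(max(m1$tables[["SEC.pcc"]]$lls), 0)

  # all scores identical -> a single bin defined by the counts
  d2 <- make_scores(rep(0.5, 3), rep(0.5, 7))
  m2 <- fit_lls(d2$scores, d2$positives, d2$negatives, n_bins = 5,
                pseudocount = 0)
  expect_length(m2$tables[["SEC.pcc"]]$lls, 1)
  expect_equal(m2$tables[["SEC.pcc"]]$lls, 0)  # (3/7)/(3/7)

  # oracle: <= 20 labeled pairs, 2 bins, exact hand log-odds
  pos_scores <- c(0.95, 0.9, 0.85, 0.8, 0.45, 0.4)
  neg_scores <- c(0.7, 0.35, 0.3, 0.25, 0.2, 0.15, 0.1, 0.05)
  d3 <- make_scores(pos_scores, neg_scores)
  m3 <- fit_lls(d3$scores, d3$positives, d3$negatives, n_bins = 2,
                monotone = FALSE)
  split_at <- median(pos_scores)  # positive-quantile bin edge
  hi_pos <- sum(pos_scores >= split_at)
  lo_pos <- sum(pos_scores < split_at)
  hi_neg <- sum(neg_scores >= split_at)
  lo_neg <- sum(neg_scores < split_at)
  prior <- length(pos_scores) / length(neg_scores)
  expect_equal(m3$tables[["SEC.pcc"]]$lls,
               c(log(((lo_pos + 1) / (lo_neg + 1)) / prior),
                 log(((hi_pos + 1) / (hi_neg + 1)) / prior)))
})

test_that("shuffled labels calibrate to near-zero LLS in every bin", {
  set.seed(9)
  x <- runif(5000)
  lab <- sample(rep(c(TRUE, FALSE), c(500, 4500)))
  d <- make_scores(x[lab], x[!lab])
  m <- fit_lls(d$scores, d$positives, d$negatives, n_bins = 5,
               monotone = FALSE)
  expect_lt(max(abs(m$tables[["SEC.pcc"]]$lls)), 0.5)
})

test_that("sum_lls is additive over available evidence and ignores missing metrics", {
  d <- make_scores(c(rep(0.9, 5), rep(0.5, 5)), c(rep(0.1, 20), rep(0.9, 2)))
  # give some pairs (both classes) a second evidence source
  d$scores$wcc[c(1:3, 15:20)] <- c(rep(0.8, 3), rep(0.2, 6))
  model <- fit_lls(d$scores, d$positives, d$negatives, n_bins = 2)
  sigma <- sum_lls(model, d$scores)
  # manual lookup per pair
  manual <- vapply(seq_len(nrow(d$scores)), function(i) {
    tot <- 0
    for (tab in model$tables) {
      v <- d$scores[[tab$metric]][i]
      if (is.na(v)) next
      b <- findInterval(v, tab$breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
      tot <- tot + tab$lls[b]
    }
    tot
  }, numeric(1))
  key_order <- match(paste(sigma$protein_a, sigma$protein_b),
                     paste(d$scores$protein_a, d$scores$protein_b))
  expect_equal(sigma$sigma_lls, manual[key_order])

  # a pair whose every evidence lands in LLS = 0 bins sums to 0
  d0 <- make_scores(c(0.2, 0.8, 0.2, 0.8), c(0.2, 0.8, 0.2, 0.8))
  m0 <- fit_lls(d0$scores, d0$positives, d0$negatives, n_bins = 2,
                pseudocount = 0)
  s0 <- sum_lls(m0, d0$scores)
  expect_true(all(s0$sigma_lls == 0))
})

test_that("choose_threshold reports AUC and applies threshold semantics", {
  d <- make_scores(rep(0.9, 10), rep(0.1, 30))
  sigma <- data.frame(d$scores[c("protein_a", "protein_b")],
                      sigma_lls = c(seq(5, 10, length.out = 10),
                                    seq(-5, 1.4, length.out = 30)))

  net <- choose_threshold(sigma, d$positives, d$negatives, fixed = NULL)
  expect_equal(net$auc, 1.0)  # perfectly separated
  expect_identical(nrow(net$edges), 10L)

  # fixed threshold: no edge with sigma_lls <= cutoff is retained
  net145 <- choose_threshold(sigma, d$positives, d$negatives, fixed = 1.45)
  expect_true(all(net145$edges$sigma_lls > 1.45))
  expect_identical(net145$threshold, 1.45)
  expect_identical(nrow(net145$edges), 10L)

  # degenerate labels error
  expect_error(choose_threshold(sigma, d$positives,
                                d$positives[0, ], fixed = NULL),
               "degenerate")
})

test_that("random scores give AUC near 0.5", {
  set.seed(33)
  d <- make_scores(runif(400), runif(4000))
  model <- fit_lls(d$scores, d$positives, d$negatives, n_bins = 5,
                   monotone = FALSE)
  sigma <- sum_lls(model, d$scores)
  net <- choose_threshold(sigma, d$positives, d$negatives, fixed = 0)
  expect_equal(net$auc, 0.5, tolerance = 0.06)
})

test_that("crossvalidate splits at the complex level and is deterministic", {
  sim <- small_study()
  scores <- score_elution_pairs(
    Filter(function(e) e$state == "ECSC", sim$experiments))
  cat1 <- truth_catalog(sim$truth, "ECSC")

  aucs <- crossvalidate(cat1, scores, k = 4, seed = 2)
  aucs2 <- crossvalidate(cat1, scores, k = 4, seed = 2)
  expect_identical(aucs, aucs2)
  expect_length(aucs, 4)
  expect_true(all(aucs > 0.5))

  expect_error(crossvalidate(cat1, scores, k = 1), "k must be >= 2")
  expect_error(crossvalidate(cat1, scores, k = 99), "exceeds")
})

test_that("percentile co-complex enrichment behaves on toy networks", {
  cat1 <- complex_catalog(list(c1 = c("A", "B"), c2 = c("C", "D")))
  # both co-complex edges on top, cross-complex edges below
  edges <- edge_df(c("A", "C", "A", "B", "A", "B"),
                   c("B", "D", "C", "D", "D", "C"),
                   w = c(10, 9, 2, 1, 0.5, 0.4))
  res <- percentile_cocomplex_enrichment(edges, cat1, percentile = 1 / 3)
  expect_equal(c(res$k, res$K, res$n, res$N), c(2, 2, 2, 6))
  # exact enumeration: both successes drawn in 2 of 6 -> 1 / C(6,2)
  expect_equal(res$p, 1 / choose(6, 2))

  # tested tail equal to the whole covered set -> p = 1
  res_all <- percentile_cocomplex_enrichment(edges, cat1, percentile = 0.999)
  expect_equal(res_all$p, 1.0)

  expect_error(percentile_cocomplex_enrichment(edges, cat1, percentile = 0),
               "percentile")
  cat_far <- complex_catalog(list(z = c("QQ", "ZZ")))
  expect_error(percentile_cocomplex_enrichment(edges, cat_far),
               "covered")
  expect_error(percentile_cocomplex_enrichment(edges[0, ], cat1), "empty")
})
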