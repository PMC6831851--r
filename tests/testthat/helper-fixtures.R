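# Small in-code fixtures shared across test files.

# a fraction_experiment from a plain matrix (rownames optional)
toy_experiment <- function(counts, state = "ECSC", technique = "SEC",
                           replicate = 1L, proteins = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(proteins)) rownames(counts) <- proteins
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("P", seq_len(nrow(counts)))
  }
  fraction_experiment(counts, state = state, technique = technique,
                      replicate = replicate)
}

# weighted edge data frame for a clique over `nodes`
clique_edges <- function(nodes, weight = 1) {
  pr <- t(combn(sort(nodes), 2))
  data.frame(protein_a = pr[, 1], protein_b = pr[, 2], sigma_lls = weight,
             stringsAsFactors = FALSE)
}

edge_df <- function(a, b, w = 1) {
  cp <- canonical_pairs(a, b)
  data.frame(cp, sigma_lls = w, stringsAsFactors = FALSE)
}

# brute-force wcc by direct enumeration over all shifts (independent oracle)
wcc_bruteforce <- function(a, b, max_shift) {
  n <- length(a)
  vals <- c()
  for (s in seq(-max_shift, max_shift)) {
    ia <- seq(max(1, 1 + s), min(n, n + s))
    ib <- ia - s
    na2 <- sum(a[ia]^2)
    nb2 <- sum(b[ib]^2)
    if (na2 == 0 || nb2 == 0) next
    vals <- c(vals, (1 - abs(s) / (max_shift + 1)) *
                sum(a[ia] * b[ib]) / sqrt(na2 * nb2))
  }
  if (length(vals) == 0) return(NA_real_)
  max(max(vals), 0)
}

# brute-force upper-tail hypergeometric by enumerating all C(N, n) draws
hypergeom_bruteforce <- function(k, K, n, N) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- combn(N, n)
  mean(apply(draws, 2, function(ix) sum(pop[ix]) >= k))
}

# a small study used by several slower tests (cached per test run)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(n_complexes = 12L, size_range = c(2L, 6L),
                               n_background = 40L, fraction_rewired = 0.25,
                               techniques = c(SEC = 40L, IEC = 45L),
                               seed = 42L)
    }
    cache
  }
})
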