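test_that("omega matches direct arithmetic and is symmetric", {
  expect_equal(omega(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(omega(c("a", "b"), c("x", "y")), 0.0)
  expect_equal(omega(c("a", "b", "c"), c("b", "c", "d")), 4 / 9)
  expect_equal(omega(c("a", "b", "c"), c("b", "c", "d")),
               omega(c("b", "c", "d"), c("a", "b", "c")))
  expect_error(omega(character(0), "a"), "empty")
})

test_that("MCL recovers components of disjoint cliques (component oracle)", {
  # two disjoint triangles -> exactly 2 clusters
  tri <- rbind(clique_edges(c("a1", "a2", "a3")),
               clique_edges(c("b1", "b2", "b3")))
  res <- mcl_cluster(tri)
  expect_length(res$members, 2)
  expect_setequal(vapply(res$members, paste, character(1), collapse = "+"),
                  c("a1+a2+a3", "b1+b2+b3"))

  # single edge -> one heterodimer cluster
  res1 <- mcl_cluster(edge_df("x", "y"))
  expect_identical(res1$members, list(c("x", "y")))

  # disjoint cliques of mixed sizes vs igraph components oracle
  g <- rbind(clique_edges(paste0("c", 1:4)),
             clique_edges(paste0("d", 1:5), weight = 2),
             clique_edges(c("e1", "e2")))
  res2 <- mcl_cluster(g)
  ig <- igraph::graph_from_data_frame(g[, 1:2], directed = FALSE)
  comp <- igraph::components(ig)
  oracle <- unname(split(names(comp$membership), comp$membership))
  oracle <- lapply(oracle, sort)
  expect_setequal(vapply(res2$members, paste, character(1), collapse = "+"),
                  vapply(oracle, paste, character(1), collapse = "+"))
})

test_that("MCL splits a barbell of two K4s joined by a weak bridge", {
  k4a <- paste0("a", 1:4)
  k4b <- paste0("b", 1:4)
  barbell <- rbind(clique_edges(k4a), clique_edges(k4b),
                   edge_df("a1", "b1", w = 0.2))
  res <- mcl_cluster(barbell, inflation = 2.0)
  expect_length(res$members, 2)
  # oracle: connected components after removing the bridge
  expect_setequal(vapply(res$members, paste, character(1), collapse = "+"),
                  c(paste(k4a, collapse = "+"), paste(k4b, collapse = "+")))
  expect_error(mcl_cluster(barbell, max_iter = 1), "converge")
})

test_that("cohesiveness objective matches hand computation", {
  # isolated clique: f = w_in / (w_in + penalty); penalty 0 -> 1
  k4 <- clique_edges(paste0("k", 1:4), weight = 2)
  A <- cofracnet:::network_adjacency(k4)
  expect_equal(cofracnet:::cohesiveness(A, 1:4, penalty = 0), 1.0)
  w_in <- 6 * 2
  expect_equal(cofracnet:::cohesiveness(A, 1:4, penalty = 3),
               w_in / (w_in + 3))

  # K3 plus one pendant edge: adding the pendant node changes f by a
  # hand-computable amount
  g <- rbind(clique_edges(c("k1", "k2", "k3"), weight = 1),
             edge_df("k3", "p", w = 0.5))
  A2 <- cofracnet:::network_adjacency(g)
  core <- match(c("k1", "k2", "k3"), rownames(A2))
  with_p <- match(c("k1", "k2", "k3", "p"), rownames(A2))
  expect_equal(cofracnet:::cohesiveness(A2, core, penalty = 1),
               3 / (3 + 0.5 + 1))            # boundary = pendant edge
  expect_equal(cofracnet:::cohesiveness(A2, with_p, penalty = 1),
               3.5 / (3.5 + 0 + 1))
})

test_that("cohesiveness_grow finds cliques and merges heavy overlaps", {
  two <- rbind(clique_edges(paste0("a", 1:4), weight = 3),
               clique_edges(paste0("b", 1:4), weight = 3),
               edge_df("a1", "b1", w = 0.1))
  res <- cohesiveness_grow(two, penalty = 1)
  expect_setequal(vapply(res$members, paste, character(1), collapse = "+"),
                  c("a1+a2+a3+a4", "b1+b2+b3+b4"))

  # predictions sharing >= 80% members merge into one
  big <- clique_edges(paste0("x", 1:5))
  res2 <- cohesiveness_grow(big, penalty = 0.5, overlap_merge = 0.8)
  expect_length(res2$members, 1)
  expect_error(cohesiveness_grow(two, penalty = -1), "penalty")
})

test_that("core_attach grows dense cores and attaches by neighbor ratio", {
  # K4 with core_density 1.0 is itself a core
  k4 <- clique_edges(paste0("k", 1:4), weight = 2)
  res <- core_attach(k4, core_density = 1.0, attach_ratio = 1.0)
  expect_identical(res$members, list(paste0("k", 1:4)))

  # node adjacent to 2 of 4 core members attaches at ratio 0.5 but not 1.0
  g <- rbind(k4, edge_df(c("n", "n"), c("k1", "k2"), w = 0.3))
  res05 <- core_attach(g, core_density = 1.0, attach_ratio = 0.5)
  expect_identical(res05$members[[1]], sort(c(paste0("k", 1:4), "n")))
  res10 <- core_attach(g, core_density = 1.0, attach_ratio = 1.0)
  expect_identical(res10$members[[1]], paste0("k", 1:4))

  expect_error(core_attach(k4, core_density = 0), "core_density")
  expect_error(core_attach(k4, attach_ratio = 1.5), "attach_ratio")
})

test_that("clustering algorithms are deterministic", {
  sim <- small_study()
  scores <- score_elution_pairs(
    Filter(function(e) e$state == "DNLC", sim$experiments))
  net <- build_state_network(scores, truth_catalog(sim$truth, "DNLC"),
                             fixed = NULL)$network
  for (fn in list(mcl_cluster, cohesiveness_grow, core_attach)) {
    r1 <- fn(net)
    r2 <- fn(net)
    expect_identical(r1$members, r2$members)
  }
})

test_that("match_and_select scores recovery and picks a deterministic winner", {
  cat1 <- complex_catalog(list(c1 = c("A", "B", "C"), c2 = c("D", "E"),
                               c3 = c("F", "G", "H", "I")))
  exact <- list(c("A", "B", "C"), c("D", "E"), c("F", "G", "H", "I"))
  shuffled <- list(c("A", "D", "F"), c("B", "G"), c("C", "E", "H"))
  res <- match_and_select(list(good = exact, bad = shuffled), cat1)
  expect_true(all(res$matches$recovered[res$matches$algorithm == "good"]))
  expect_identical(res$best_algorithm, "good")
  expect_true(all(res$matches$omega >= 0 & res$matches$omega <= 1))
  # omega at 0.24 is not recovered at the 0.25 cutoff
  m <- match_and_select(list(x = list(c("A", "Q", "R", "S"))), cat1,
                        omega_cutoff = 0.25)
  expect_equal(m$matches$omega, 1 / 12)  # |{A}|^2 / (4 * 3)
  expect_false(m$matches$recovered)
  expect_error(match_and_select(list(), cat1), "no algorithm")

  # catalog-side recall
  expect_equal(complex_recall(exact, cat1), 1.0)
  expect_lt(complex_recall(shuffled, cat1), 1.0)
})

test_that("interaction profile correlation uses neighborhoods minus the mutual edge", {
  # two proteins with identical neighborhoods -> r = 1
  g <- rbind(edge_df(c("u", "u", "u"), c("x", "y", "z"), w = c(1, 2, 3)),
             edge_df(c("v", "v", "v"), c("x", "y", "z"), w = c(1, 2, 3)),
             edge_df("u", "v", w = 9))
  expect_equal(interaction_profile_correlation(g, c("u", "v")), 1.0)

  # a protein connected to nothing but its partner is skipped (NA)
  g2 <- rbind(edge_df(c("u", "u"), c("x", "y"), w = c(1, 2)),
              edge_df("u", "v", w = 5))
  expect_true(is.na(interaction_profile_correlation(g2, c("u", "v"))))
  expect_error(interaction_profile_correlation(g2, c("u", "missing")),
               "network")
})

test_that("within-complex pairs share interaction partners on simulated networks", {
  sim <- small_study()
  scores <- score_elution_pairs(
    Filter(function(e) e$state == "ECSC", sim$experiments))
  cat1 <- truth_catalog(sim$truth, "ECSC")
  net <- build_state_network(scores, cat1, fixed = NULL)$network
  pos_key <- with(cocomplex_pairs(cat1), paste(protein_a, protein_b))
  edges <- net$edges
  ek <- paste(edges$protein_a, edges$protein_b)
  within_idx <- which(ek %in% pos_key)
  between_idx <- which(!(ek %in% pos_key))
  r_of <- function(idx) vapply(idx, function(i)
    interaction_profile_correlation(
      net, c(edges$protein_a[i], edges$protein_b[i])), numeric(1))
  r_within <- r_of(within_idx)
  r_between <- r_of(between_idx)
  expect_lt(within_between_test(r_within, r_between), 0.05)
})

test_that("within/between rank-sum test matches exact enumeration", {
  # identical samples: p about 0.5
  p_same <- within_between_test(1:5, 1:5)
  expect_equal(p_same, 0.5, tolerance = 0.1)

  # fully separated 5 vs 5: exact one-sided p = 1 / C(10, 5)
  w <- c(6, 7, 8, 9, 10)
  b <- c(1, 2, 3, 4, 5)
  expect_equal(within_between_test(w, b), 1 / choose(10, 5))

  # swapped samples give the complementary tail
  p_rev <- within_between_test(b, w)
  expect_gt(p_rev, 0.99)

  expect_error(within_between_test(numeric(0), 1:3), "non-empty")
})
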