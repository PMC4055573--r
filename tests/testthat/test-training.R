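# Parameter packing/sharing, the profile objective, and coordinate-ascent
# fitting.

test_that("pack/unpack is a bounded bijection with correct block counts", {
  m <- build_model(mouse_style_forest(), gene_bl_init = 0.01)
  v <- pack_parameters(m)
  m2 <- unpack_parameters(v, m)
  expect_equal(pack_parameters(m2), v, tolerance = 1e-12)

  # random in-bounds vector round-trips
  set.seed(2)
  lo <- attr(v, "lower"); hi <- attr(v, "upper")
  draw <- setNames(runif(length(v), lo, pmin(hi, lo + 1)), names(v))
  m3 <- unpack_parameters(draw, m)
  expect_equal(as.numeric(pack_parameters(m3)), as.numeric(draw),
               tolerance = 1e-9)

  # mouse-style model: 3 gene blocks (distinct unrooted 4-leaf topologies),
  # not 15, each with 5 free lengths
  pt <- param_table(m, "gene_bl")
  expect_equal(length(m$blocks), 3)
  expect_equal(nrow(pt), 3 * 5)
  # out-of-bounds clamps with a warning
  bad <- v; bad[["gamma"]] <- 2
  expect_warning(m4 <- unpack_parameters(bad, m), "clamped")
  expect_equal(m4$hmm$gamma, 1 - 1e-6)
})

test_that("moving a parental branch length reshapes the topology table", {
  m <- build_model(three_taxon_forest())
  P_before <- m$P
  v <- pack_parameters(m, "parental_bl")
  # shrink the class-1 internal branch: congruence probability must drop
  internal_edge <- which(m$forest$trees[[1]]$edge[, 2] ==
                           ape::getMRCA(m$forest$trees[[1]], c("A", "B")))
  nm <- paste0("pbl1_e", internal_edge)
  m2 <- unpack_parameters(setNames(0.1, nm), m)
  expect_false(isTRUE(all.equal(m2$P, P_before)))
  cong_idx <- which(m$states$class == 1 & m$states$congruent)
  topo <- m$states$topology[cong_idx]
  expect_lt(m2$P[1, topo], P_before[1, topo])
  expect_equal(sum(m2$P[1, ]), 1, tolerance = 1e-9)
  # and the independently computed table agrees
  tab <- topology_probability_table(m2$forest$trees[[1]],
                                    m2$forest$allele_map, m2$topologies)
  expect_equal(unname(m2$P[1, ]), tab$probability, tolerance = 1e-12)
})

test_that("profile objective is cached consistently and separable", {
  m <- build_model(three_taxon_forest(), hmm = hmm_params(0.1, 0.2, 0.2),
                   gene_bl_init = 0.03)
  set.seed(6)
  # model-generated data, so the gamma profile has a well-formed optimum
  aln <- simulate_from_model(recovery_model(0.1, 0.2, 0.2), 400)$alignment
  ll0 <- model_log_likelihood(m, aln)
  # evaluating at the current value reproduces the current log-likelihood
  expect_equal(profile_objective(m, aln, "gamma", m$hmm$gamma), ll0,
               tolerance = 1e-10)
  expect_equal(profile_objective(m, aln, "gbl1_e1",
                                 m$blocks[[1]]$tree$edge.length[
                                   m$blocks[[1]]$free_edges[1]]),
               ll0, tolerance = 1e-10)
  # moving a gene branch length leaves the transition matrix bit-identical
  m2 <- introscan:::apply_param(m, "gbl1_e1", 0.07)$model
  expect_identical(transition_matrix(m2), transition_matrix(m))
  # Brent attains (at least) the quality of a fine grid search on the
  # gamma profile
  env <- introscan:::make_objective_env(m, aln)
  grid <- seq(1e-4, 1 - 1e-4, length.out = 2000)
  gv <- vapply(grid, function(g) env$eval("gamma", g), 0)
  opt <- optimize(function(g) env$eval("gamma", g),
                  c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-7)
  expect_gte(opt$objective, max(gv) - 1e-6)
})

test_that("fitting improves monotonically and flags flat profiles", {
  truth <- recovery_model(gamma = 0.08, s1 = 0.15, s2 = 0.3)
  set.seed(10)
  sim <- simulate_from_model(truth, 1500)
  start <- build_model(truth$forest, truth$gtr, hmm_params(0.3, 0.4, 0.4))
  start <- init_gene_blocks(start, sim$alignment)
  ft <- fit_model(start, sim$alignment,
                  fit_config(tolerance = 1e-3, max_rounds = 3, restarts = 1,
                             free = "hmm", brent_rel_tol = 1e-3))
  expect_true(all(diff(ft$trace) > -1e-9))         # ascent property
  expect_gte(ft$log_likelihood, ft$trace[1])
  expect_false(ft$flat_profile)

  # all-missing alignment: every profile is flat and reported as such
  blank <- site_alignment(matrix("N", 3, 30,
                                 dimnames = list(c("a", "b", "c"), NULL)))
  expect_warning(
    ft0 <- fit_model(start, blank,
                     fit_config(max_rounds = 2, restarts = 1, free = "hmm",
                                brent_rel_tol = 1e-3)),
    "flat")
  expect_true(ft0$flat_profile)
  expect_equal(ft0$log_likelihood, 0)   # all-N columns emit log 1
})
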