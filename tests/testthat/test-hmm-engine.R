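# Model construction, transition structure, GTR emissions and the
# forward/backward/Viterbi machinery, all checked against independent
# oracles (dense R recursions, exhaustive path enumeration, brute-force
# marginalization).

test_that("state counts follow the class x topology construction", {
  m3 <- build_model(three_taxon_forest())
  expect_equal(n_states(m3), 7)
  m4 <- build_model(mouse_style_forest())
  expect_equal(n_states(m4), 31)
  expect_equal(m4$n_topologies, 15)
  # exactly one congruent state per class
  expect_equal(as.vector(tapply(m3$states$congruent, m3$states$class, sum)),
               c(1, 1))
  expect_equal(as.vector(tapply(m4$states$congruent, m4$states$class, sum)),
               c(1, 1))
  # degenerate single-class model: 1 + #topologies states, gamma forced 0
  t1 <- read_tree("((A:5,B:5):1,C:6);", "coalescent")
  f1 <- parental_forest(list(t1), c(a = "A", b = "B", c = "C"),
                        introgressed = integer(0))
  m1 <- build_model(f1, hmm = hmm_params(0.1, 0.2, 0.2))
  expect_equal(n_states(m1), 1 + 3)
  expect_equal(m1$hmm$gamma, 0)
  expect_true(all(rowSums(transition_matrix(m1)) - 1 < 1e-12))
})

test_that("transition matrix rows are stochastic and match the formulas", {
  # star parental trees give uniform topology probabilities; the worked
  # numbers below follow from the two-parameter switching construction
  t1 <- read_tree("((A:1,B:0):0,C:1);", "coalescent")
  t2 <- read_tree("(A:1,(B:1,C:0):0);", "coalescent")
  f <- parental_forest(list(t1, t2), c(a = "A", b = "B", c = "C"), 2L)
  m <- build_model(f, hmm = hmm_params(gamma = 0.1, s1 = 0.2, s2 = 0.2))
  Tm <- transition_matrix(m)
  expect_equal(dim(Tm), c(6, 6))
  expect_equal(unname(rowSums(Tm)), rep(1, 6), tolerance = 1e-12)
  offdiag_within <- Tm[1, 2]
  expect_equal(unname(offdiag_within), 0.9 * 0.2 * (1 / 3), tolerance = 1e-12)
  expect_equal(unname(Tm[1, 4]), 0.1 * (1 / 3), tolerance = 1e-12)
  expect_equal(unname(diag(Tm)), rep(0.78, 6), tolerance = 1e-12)

  # start distribution: normalized gene-tree probability over all states
  expect_equal(sum(m$pi0), 1, tolerance = 1e-12)
  expect_equal(m$pi0, rep(1 / 6, 6), tolerance = 1e-9)

  # gamma = 0: no cross-class transitions at all
  m0 <- build_model(f, hmm = hmm_params(gamma = 1e-12, s1 = 0.2, s2 = 0.2))
  m0$hmm$gamma <- 0
  Tm0 <- transition_matrix(m0)
  expect_equal(max(Tm0[1:3, 4:6]), 0)
  expect_equal(max(Tm0[4:6, 1:3]), 0)
})

test_that("transition rows are stochastic over random parameter draws", {
  set.seed(5)
  amap <- c(a = "A", b = "B", c = "C")
  worst <- 0
  for (i in 1:1000) {
    gamma <- runif(1, 1e-6, 1 - 1e-6)
    s1 <- runif(1, 1e-6, 1 - 1e-6)
    s2 <- runif(1, 1e-6, 1 - 1e-6)
    if (i <= 25) {   # rebuild topology tables for a subset of random trees
      tint <- runif(2, 0, 4)
      t1 <- read_tree(sprintf("((A:5,B:5):%g,C:%g);", tint[1], 5 + tint[1]),
                      "coalescent")
      t2 <- read_tree(sprintf("(A:%g,(B:5,C:5):%g);", 5 + tint[2], tint[2]),
                      "coalescent")
      m <- build_model(parental_forest(list(t1, t2), amap, 2L),
                       hmm = hmm_params(gamma, s1, s2))
    } else {
      m$hmm <- hmm_params(gamma, s1, s2)
    }
    Tm <- transition_matrix(m)
    worst <- max(worst, max(abs(rowSums(Tm) - 1)), -min(Tm))
  }
  expect_lt(worst, 1e-12)
})

test_that("pruning emissions match stationarity, ambiguity and brute force", {
  gtr <- gtr_params(c(0.1, 0.4, 0.2, 0.3), c(2, 1, 3, 0.5, 4, 1))
  # single-leaf tree: log pi_base
  leaf <- structure(list(edge = matrix(c(2L, 1L), 1), tip.label = "a",
                         edge.length = 0.3, Nnode = 1L), class = "phylo")
  expect_equal(emission_log_probability(leaf, gtr, c(a = "C")),
               log(gtr$freqs[["C"]]))
  # all-missing column marginalizes to 1
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.15):0.08);")
  expect_equal(emission_log_probability(tr, gtr, c(a = "N", b = "N",
                                                   c = "-", d = "?")), 0)
  expect_error(emission_log_probability(tr, gtr, c(a = "Z", b = "A",
                                                   c = "A", d = "A")),
               "non-IUPAC")
  # random columns against brute-force marginalization
  set.seed(11)
  for (i in 1:25) {
    col <- setNames(sample(c("A", "C", "G", "T"), 4, TRUE),
                    c("a", "b", "c", "d"))
    expect_equal(emission_log_probability(tr, gtr, col),
                 oracle_column_likelihood(tr, gtr, col), tolerance = 1e-12)
  }
  # 5-leaf tree with a multifurcating root (unrooted representation)
  tr5 <- ape::read.tree(text = "((a:0.1,b:0.2):0.07,c:0.3,(d:0.1,e:0.2):0.1);")
  col5 <- c(a = "A", b = "G", c = "T", d = "C", e = "A")
  ll <- emission_log_probability(tr5, gtr, col5)
  expect_true(is.finite(ll) && ll < 0)
  # GTR transition matrices are proper and stationary
  P <- gtr_pmat(gtr, 0.7)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  expect_equal(as.numeric(gtr$freqs %*% P), unname(gtr$freqs),
               tolerance = 1e-12)
  expect_equal(sum(-diag(gtr$Q) * gtr$freqs), 1, tolerance = 1e-12)
})

test_that("pruning likelihoods agree with an independent implementation", {
  set.seed(1)
  gtr <- gtr_params(c(0.1, 0.4, 0.2, 0.3), c(2, 1, 3, 0.5, 4, 1))
  for (i in 1:3) {
    tr <- ape::rtree(sample(3:5, 1))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
    codes <- matrix(sample(c("A", "C", "G", "T"), length(tr$tip.label) * 40,
                           TRUE),
                    length(tr$tip.label), 40,
                    dimnames = list(tr$tip.label, NULL))
    ll <- sum(tree_pattern_loglik(tr, gtr, introscan:::encode_bases(codes)))
    fit <- phangorn::pml(tr, phangorn::phyDat(codes),
                         bf = unname(gtr$freqs), Q = unname(gtr$rates))
    expect_equal(ll, as.numeric(stats::logLik(fit)), tolerance = 1e-10)
  }
})

test_that("forward/backward agree with each other and with path enumeration", {
  m <- build_model(three_taxon_forest(),
                   gtr_params(c(.3, .2, .3, .2), c(1.2, 2, .8, 1.1, 2.5, 1)),
                   hmm_params(0.1, 0.2, 0.3), gene_bl_init = 0.05)
  set.seed(3)
  for (rep in 1:4) {
    L <- sample(3:6, 1)
    aln <- site_alignment(matrix(sample(c("A", "C", "G", "T", "N"), 3 * L,
                                        TRUE, prob = c(rep(.23, 4), .08)),
                                 3, L, dimnames = list(c("a", "b", "c"), NULL)))
    dec <- forward_backward(m, aln)
    expect_equal(dec$log_likelihood, dec$log_likelihood_backward,
                 tolerance = 1e-8)
    expect_equal(unname(rowSums(dec$posterior)), rep(1, L), tolerance = 1e-8)
    em <- introscan:::prepare_emissions(m, aln)
    ex <- oracle_exhaustive_loglik(m$pi0, transition_matrix(m), em$logE,
                                   em$index)
    expect_equal(dec$log_likelihood, ex$loglik, tolerance = 1e-10)
    # dense R reference forward agrees with the structured C++ recursion
    expect_equal(oracle_forward(m$pi0, transition_matrix(m), em$logE,
                                em$index),
                 dec$log_likelihood, tolerance = 1e-10)
    # length-1 closed form
    a1 <- site_alignment(matrix(c("A", "C", "G"), 3, 1,
                                dimnames = list(c("a", "b", "c"), NULL)))
    em1 <- introscan:::prepare_emissions(m, a1)
    expect_equal(model_log_likelihood(m, a1),
                 log(sum(m$pi0 * exp(em1$logE[, 1]))), tolerance = 1e-10)
  }
})

test_that("viterbi matches exhaustive search and is reversal-stable", {
  m <- build_model(three_taxon_forest(), gtr_params(),
                   hmm_params(0.1, 0.25, 0.25), gene_bl_init = 0.04)
  set.seed(8)
  for (rep in 1:3) {
    L <- 5
    aln <- site_alignment(matrix(sample(c("A", "C", "G", "T"), 3 * L, TRUE),
                                 3, L, dimnames = list(c("a", "b", "c"), NULL)))
    vt <- viterbi_path(m, aln)
    em <- introscan:::prepare_emissions(m, aln)
    ex <- oracle_exhaustive_loglik(m$pi0, transition_matrix(m), em$logE,
                                   em$index)
    expect_equal(vt$log_joint, ex$max, tolerance = 1e-10)
    # with symmetric switching (s1 = s2) the path score is invariant under
    # reversing the sites
    rev_aln <- site_alignment(aln$codes[, L:1],
                              labels = c("a", "b", "c"))
    expect_equal(viterbi_path(m, rev_aln)$log_joint, vt$log_joint,
                 tolerance = 1e-9)
  }
})

test_that("introgression posterior is the flagged-class mass", {
  m <- build_model(mouse_style_forest(), hmm = hmm_params(0.05, 0.1, 0.2),
                   gene_bl_init = 0.01)
  set.seed(21)
  aln <- site_alignment(matrix(sample(c("A", "C", "G", "T"), 4 * 40, TRUE), 4,
                               40, dimnames = list(c("a1", "a2", "b1", "b2"),
                                                   NULL)))
  dec <- forward_backward(m, aln)
  tr <- dec$introgression_posterior
  expect_true(all(tr >= 0 & tr <= 1))
  # complement identity: 1 - non-introgressed mass
  non <- rowSums(dec$posterior[, !m$states$introgressed, drop = FALSE])
  expect_equal(tr, 1 - non, tolerance = 1e-10)
  # invariant to permuting states within a class (permute the dense
  # representation and recompute from the permuted matrices)
  perm <- c(sample(1:15), sample(16:30))
  logT <- log(transition_matrix(m))[perm, perm]
  em <- introscan:::prepare_emissions(m, aln)
  pi0p <- m$pi0[perm]
  logEp <- em$logE[perm, , drop = FALSE]
  # dense forward-backward in R on permuted matrices
  L <- 40; K <- 30
  alpha <- matrix(0, K, L); ca <- numeric(L)
  alpha[, 1] <- pi0p * exp(logEp[, em$index[1]])
  ca[1] <- sum(alpha[, 1]); alpha[, 1] <- alpha[, 1] / ca[1]
  for (t in 2:L) {
    alpha[, t] <- as.vector(alpha[, t - 1] %*% exp(logT)) *
      exp(logEp[, em$index[t]])
    ca[t] <- sum(alpha[, t]); alpha[, t] <- alpha[, t] / ca[t]
  }
  beta <- matrix(1, K, L)
  for (t in (L - 1):1) {
    beta[, t] <- as.vector(exp(logT) %*% (exp(logEp[, em$index[t + 1]]) *
                                            beta[, t + 1]))
    beta[, t] <- beta[, t] / sum(beta[, t])
  }
  post <- alpha * beta
  post <- sweep(post, 2, colSums(post), "/")
  track_perm <- colSums(post[m$states$introgressed[perm], ])
  expect_equal(track_perm, tr, tolerance = 1e-8)
})

test_that("restricted start distribution keeps unreachable states empty", {
  m <- build_model(mouse_style_forest(), hmm = hmm_params(0.3, 0.2, 0.2),
                   gene_bl_init = 0.01)
  m$hmm$gamma <- 0                      # freeze classes
  m$pi0[m$states$introgressed] <- 0     # start only in class 1
  m$pi0 <- m$pi0 / sum(m$pi0)
  set.seed(4)
  aln <- site_alignment(matrix(sample(c("A", "C", "G", "T"), 4 * 30, TRUE), 4,
                               30, dimnames = list(c("a1", "a2", "b1", "b2"),
                                                   NULL)))
  dec <- forward_backward(m, aln)
  expect_equal(max(dec$introgression_posterior), 0)
})
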