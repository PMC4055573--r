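# Region calling, scan summaries and annotation outputs.

test_that("region calling follows the threshold/merge/min-sites rules", {
  expect_equal(nrow(call_regions(rep(0, 50))), 0)
  r <- call_regions(c(0, 1, 1, 1, 0), threshold = 0.9, min_sites = 1)
  expect_equal(r$start, 1)
  expect_equal(r$end, 4)
  expect_equal(r$n_sites, 3)
  # merge across a one-site gap, then a distant run stays separate
  tr <- c(0.95, 0.95, 0.1, 0.95, 0, 0, 0, 0.95, 0.95)
  r2 <- call_regions(tr, threshold = 0.9, min_sites = 1, merge_gap = 1)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$start[1], 0)
  expect_equal(r2$end[1], 4)
  # min_sites drops short runs
  r3 <- call_regions(tr, threshold = 0.9, min_sites = 3, merge_gap = 1)
  expect_equal(nrow(r3), 1)
  expect_equal(r3$n_sites, 3)
  # genomic coordinates span first to last qualifying site
  r4 <- call_regions(c(0, 1, 1, 0), coordinates = c(100L, 200L, 350L, 500L),
                     min_sites = 1)
  expect_equal(r4$start, 199)
  expect_equal(r4$end, 350)
})

test_that("region site counts match a brute-force run-length oracle", {
  set.seed(30)
  for (i in 1:40) {
    tr <- runif(200)
    th <- runif(1, 0.3, 0.95)
    min_sites <- sample(1:4, 1)
    regs <- call_regions(tr, threshold = th, min_sites = min_sites)
    # brute force: qualifying runs of above-threshold sites
    above <- tr > th
    runs <- rle(above)
    lens <- runs$lengths[runs$values]
    expect_equal(sum(regs$n_sites), sum(lens[lens >= min_sites]))
    if (nrow(regs) > 1) {
      expect_true(all(regs$start < regs$end))
      expect_true(all(diff(regs$start) > 0))     # sorted, non-overlapping
      expect_true(all(regs$mean_posterior >= regs$min_posterior))
    }
    # idempotence under coordinate shift
    shift <- call_regions(tr, coordinates = seq_len(200) + 1000L,
                          threshold = th, min_sites = min_sites)
    expect_equal(shift$start - 1000L, regs$start)
    expect_equal(shift$end - 1000L, regs$end)
  }
})

test_that("posterior-rule percentage decreases in the threshold", {
  set.seed(31)
  tr <- runif(500)^2
  pct <- vapply(seq(0.05, 0.95, by = 0.1),
                function(th) 100 * mean(tr > th), 0)
  expect_true(all(diff(pct) <= 0))
})

test_that("summaries report both decision rules and the gamma identity", {
  m <- build_model(mouse_style_forest(), hmm = hmm_params(0.07, 0.1, 0.2),
                   gene_bl_init = 0.01)
  set.seed(32)
  aln <- site_alignment(matrix(sample(c("A", "C", "G", "T"), 4 * 50, TRUE),
                               4, 50,
                               dimnames = list(c("a1", "a2", "b1", "b2"),
                                               NULL)))
  dec <- forward_backward(m, aln)
  vit <- viterbi_path(m, aln)
  regs <- call_regions(dec$introgression_posterior)
  s <- summarize_scan(m, dec, vit, regs)
  # gamma read-back is an algebraic identity of the parameterization
  expect_equal(s$gamma_readback, m$hmm$gamma, tolerance = 1e-12)
  expect_true(s$percent_sites_posterior >= 0 &&
                s$percent_sites_posterior <= 100)
  expect_equal(sum(s$topology_posterior_mass), 1, tolerance = 1e-8)
  # no posterior mass in introgressed states -> 0% under both rules
  m0 <- m
  m0$hmm$gamma <- 0
  m0$pi0[m0$states$introgressed] <- 0
  m0$pi0 <- m0$pi0 / sum(m0$pi0)
  dec0 <- forward_backward(m0, aln)
  vit0 <- viterbi_path(m0, aln)
  s0 <- summarize_scan(m0, dec0, vit0, call_regions(dec0$introgression_posterior))
  expect_equal(s0$percent_sites_posterior, 0)
  expect_equal(s0$percent_sites_viterbi, 0)
})

test_that("missing-data stretches are masked, not interpolated", {
  codes <- matrix("A", 3, 60, dimnames = list(c("a", "b", "c"), NULL))
  codes[, 11:25] <- "N"
  codes[, 41:45] <- "-"
  aln <- site_alignment(codes)
  mask <- missing_data_mask(aln, min_length = 10)
  expect_equal(nrow(mask), 1)
  expect_equal(mask$start, 10)
  expect_equal(mask$end, 25)
  mask5 <- missing_data_mask(aln, min_length = 5)
  expect_equal(nrow(mask5), 2)
})
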