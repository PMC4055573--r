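# The isolation-with-migration generator: structured-coalescent behavior,
# truth-label soundness, segment structure, reproducibility and ms
# interoperability.

test_that("isolation forbids cross-population coalescence before the split", {
  cfg <- sim_config(m = 0, t_split_AB = 2, t_split_outgroup = 4)
  set.seed(14)
  for (i in 1:200) {
    g <- simulate_genealogy(cfg)
    cs <- introscan:::clade_sets(g$phylo)
    ntip <- length(g$phylo$tip.label)
    for (nd in (ntip + 1L):(ntip + g$phylo$Nnode)) {
      pops <- unique(substr(cs[[nd]], 1, 1))
      if (g$times[nd] < 2) expect_length(pops, 1)
      if (g$times[nd] < 4) expect_false("o" %in% pops && length(pops) > 1)
    }
  }
})

test_that("within-population pairs coalesce at rate one", {
  cfg <- sim_config(n_A = 2, n_B = 1, n_out = 1, m = 0)
  set.seed(15)
  tt <- replicate(3000, {
    g <- simulate_genealogy(cfg)
    cs <- introscan:::clade_sets(g$phylo)
    ntip <- length(g$phylo$tip.label)
    out <- NA_real_
    for (nd in (ntip + 1L):(ntip + g$phylo$Nnode))
      if (setequal(cs[[nd]], c("a1", "a2"))) out <- g$times[nd]
    out
  })
  # split is deep (30 units), so a1-a2 almost surely coalesce inside A
  expect_gt(mean(!is.na(tt)), 0.999)
  se <- sd(tt, na.rm = TRUE) / sqrt(sum(!is.na(tt)))
  expect_lt(abs(mean(tt, na.rm = TRUE) - 1), 3 * se)
})

test_that("strong migration makes early cross-population coalescence common", {
  cfg <- sim_config(m = 10, t_mig_start = 0, t_mig_end = 0.5)
  set.seed(16)
  frac <- mean(replicate(400, {
    g <- simulate_genealogy(cfg)
    cs <- introscan:::clade_sets(g$phylo)
    ntip <- length(g$phylo$tip.label)
    any(vapply((ntip + 1L):(ntip + g$phylo$Nnode), function(nd) {
      tips <- cs[[nd]]
      g$times[nd] < cfg$t_split_AB &&
        any(startsWith(tips, "a")) && any(startsWith(tips, "b"))
    }, TRUE))
  }))
  expect_gt(frac, 0.5)
})

test_that("migration lower-bound labels are sound and monotone in m", {
  set.seed(17)
  cfg0 <- sim_config(m = 0)
  labs0 <- replicate(2000, label_migration_lower_bound(
    simulate_genealogy(cfg0), cfg0))
  expect_equal(sum(labs0), 0)   # never true under isolation

  freqs <- vapply(c(0, 0.5, 5), function(m) {
    cfg <- sim_config(m = m)
    mean(replicate(600, label_migration_lower_bound(
      simulate_genealogy(cfg), cfg)))
  }, 0)
  expect_true(all(diff(freqs) > 0))

  # direct rule application on a hand-built genealogy: the (a1,b1) clade
  # closes inside the window
  cfg <- sim_config(m = 1, t_mig_start = 0.1, t_mig_end = 1)
  phy <- ape::read.tree(text = "(((a1:0.5,b1:0.5):30,(a2:1,b2:1):29.5):15,o1:45.5);")
  depth <- ape::node.depth.edgelength(phy)
  gen <- structure(list(phylo = phy,
                        times = max(depth[1:5]) - depth,
                        tip_pop = c(a1 = "A", b1 = "B", a2 = "A", b2 = "B",
                                    o1 = "O")), class = "genealogy")
  expect_true(label_migration_lower_bound(gen, cfg))
  # same clade but closing after the window end: not certified
  cfg_narrow <- sim_config(m = 1, t_mig_start = 0.1, t_mig_end = 0.4)
  expect_false(label_migration_lower_bound(gen, cfg_narrow))
})

test_that("replicates have the advertised segment and sequence structure", {
  # rho = 0: a single segment; theta = 0: constant alignment
  r0 <- simulate_replicate(sim_config(rho = 0, theta = 0, L = 500L, seed = 3))
  expect_equal(nrow(r0$segments), 1)
  expect_equal(r0$segments$start, 0)
  expect_equal(r0$segments$end, 500)
  expect_equal(length(unique(as.vector(r0$alignment$codes))), 1)

  # segment counts are Poisson with mean 1 + rho * L
  set.seed(18)
  counts <- replicate(150, nrow(simulate_replicate(
    sim_config(rho = 2e-3, L = 5000L))$segments))
  expected <- 1 + 2e-3 * 5000
  se <- sqrt(2e-3 * 5000 / 150)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # truth track is constant within segments and matches the labels
  r <- simulate_replicate(sim_config(m = 5, L = 20000L, seed = 19))
  for (k in seq_len(nrow(r$segments))) {
    sites <- (r$segments$start[k] + 1):r$segments$end[k]
    expect_equal(unique(r$truth[sites]), r$segments$label[k])
  }
  expect_equal(r$alignment$L, 20000L)

  # same seed, same bits
  r2 <- simulate_replicate(sim_config(m = 5, L = 20000L, seed = 19))
  expect_identical(r$alignment$codes, r2$alignment$codes)
  expect_identical(r$segments, r2$segments)
})

test_that("ms-format export parses back to identical segments", {
  r <- simulate_replicate(sim_config(m = 1, L = 10000L, seed = 23))
  lines <- export_ms_segments(r)
  back <- read_ms_output(lines)
  expect_equal(back$length, r$segments$end - r$segments$start)
  expect_identical(back$newick, r$segments$newick)
  expect_equal(sum(back$length), 10000)
  # single-line read-off
  one <- read_ms_output("[100](a:1,b:1);")
  expect_equal(one$length, 100)
  # malformed lines name the line number
  expect_error(read_ms_output(c("[10](a:1,b:1);", "[x](a:1);")), "line 2")
  expect_error(read_ms_output("no trees here"), "no ms tree lines")
})

test_that("model-sampled alignments reflect the sampled state path", {
  truth <- recovery_model(gamma = 0.1, s1 = 0.2, s2 = 0.3)
  set.seed(24)
  sim <- simulate_from_model(truth, 800)
  expect_equal(sim$alignment$L, 800)
  expect_equal(length(sim$path), 800)
  expect_true(all(sim$path >= 1 & sim$path <= nrow(truth$states)))
  # state-path transition frequencies are plausible under the chain:
  # class switches should be rare with gamma = 0.1
  switches <- mean(truth$states$class[sim$path[-1]] !=
                     truth$states$class[sim$path[-800]])
  expect_lt(abs(switches - 0.1), 0.05)
})
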