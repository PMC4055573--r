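# Rooted trees, topology enumeration, congruence, and multispecies
# coalescent topology probabilities.

test_that("newick parsing validates structure and round-trips", {
  tr <- read_tree("((A:1,B:1):1,C:2);", "coalescent")
  expect_s3_class(tr, "phylo")
  expect_identical(tree_units(tr), "coalescent")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  # internal branch read off directly
  ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(tr$edge.length[tr$edge[, 2] == ab], 1)

  expect_error(read_tree("(A:1,B:1,C:1);"), "non-binary")
  expect_error(read_tree("((A:1,B:1):1,C:2)"), "character")
  expect_error(read_tree("((A:1,B:1):1,C:2));"), "character 18")
  expect_error(read_tree("((A:1,A:1):1,C:2);"), "duplicate")

  # random-tree round trip: reparse is isomorphic (canonical form equal)
  set.seed(1)
  for (i in 1:100) {
    topo <- ape::rtree(sample(3:9, 1))
    s <- write_tree(topo)
    back <- read_tree(s, "substitutions")
    expect_identical(canonical_newick(back), canonical_newick(topo))
  }
})

test_that("rooted topology enumeration matches (2n-3)!! in canonical order", {
  for (n in 3:6) {
    topos <- enumerate_topologies(paste0("x", 1:n))
    expect_length(topos, n_rooted_topologies(n))
    canon <- vapply(topos, function(x) attr(x, "canonical"), "")
    expect_identical(canon, sort(canon))       # deterministic order
    expect_false(anyDuplicated(canon) > 0)     # all distinct
  }
  expect_length(enumerate_topologies(c("a", "b", "c")), 3)
  expect_length(enumerate_topologies(c("a", "b", "c", "d")), 15)
  expect_length(enumerate_topologies(letters[1:5]), 105)
  expect_error(enumerate_topologies("a"), "size error")
  expect_error(enumerate_topologies(letters[1:9]), "size error")
})

test_that("congruence requires species monophyly and matching topology", {
  parental <- read_tree("(D:1,S:1);", "coalescent")
  amap <- c(d1 = "D", d2 = "D", s1 = "S", s2 = "S")
  g_ok <- ape::read.tree(text = "((d1,d2),(s1,s2));")
  g_bad <- ape::read.tree(text = "((d1,s1),(d2,s2));")
  expect_true(is_congruent(g_ok, parental, amap))
  expect_false(is_congruent(g_bad, parental, amap))
  expect_error(is_congruent(g_ok, parental, amap[-1]), "unmapped")

  # over all 15 four-allele topologies, congruent == both species
  # monophyletic (brute-force cross-check via clade inspection)
  topos <- enumerate_topologies(names(amap))
  cong <- vapply(topos, is_congruent, TRUE, parental = parental,
                 allele_map = amap)
  mono <- vapply(topos, function(g) {
    cs <- introscan:::clade_sets(g)
    any(vapply(cs, function(x) setequal(x, c("d1", "d2")), TRUE)) &&
      any(vapply(cs, function(x) setequal(x, c("s1", "s2")), TRUE))
  }, TRUE)
  expect_identical(cong, mono)
  expect_equal(sum(cong), 1)

  # invariant under relabeling alleles within a species
  amap_swap <- c(d1 = "D", d2 = "D", s1 = "S", s2 = "S")[c(2, 1, 4, 3)]
  names(amap_swap) <- c("d1", "d2", "s1", "s2")
  expect_identical(
    vapply(topos, is_congruent, TRUE, parental = parental,
           allele_map = amap_swap), cong)
})

test_that("lineage-count probabilities follow Tavare's closed forms", {
  t <- 0.7
  expect_equal(coalescent_gij(2, 2, t), exp(-t), tolerance = 1e-12)
  expect_equal(coalescent_gij(2, 1, t), 1 - exp(-t), tolerance = 1e-12)
  expect_equal(coalescent_gij(3, 3, t), exp(-3 * t), tolerance = 1e-12)
  expect_equal(coalescent_gij(3, 1, Inf), 1)
  expect_equal(coalescent_gij(4, 4, 0), 1)
  expect_equal(coalescent_gij(4, 2, 0), 0)
  for (i in 2:6) {
    probs <- vapply(1:i, coalescent_gij, 0, i = i, t = 0.4)
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
})

test_that("three-taxon topology probabilities match the ILS closed form", {
  amap <- c(a = "A", b = "B", c = "C")
  for (t in c(0.25, 1, 2.5)) {
    sp <- read_tree(sprintf("((A:5,B:5):%g,C:%g);", t, 5 + t), "coalescent")
    tab <- topology_probability_table(sp, amap)
    cong <- tab$probability[tab$topology == "((a,b),c);"]
    incong <- tab$probability[tab$topology != "((a,b),c);"]
    expect_equal(cong, 1 - (2 / 3) * exp(-t), tolerance = 1e-9)
    expect_equal(incong, rep(exp(-t) / 3, 2), tolerance = 1e-9)
    expect_equal(sum(tab$probability), 1, tolerance = 1e-9)
  }
  # frozen value at t = 1 and monotone decay of incongruence
  sp1 <- read_tree("((A:5,B:5):1,C:6);", "coalescent")
  tab1 <- topology_probability_table(sp1, amap)
  expect_equal(tab1$probability[2], 0.1226265, tolerance = 1e-6)
  inc <- vapply(c(0.5, 1, 2, 4), function(t) {
    sp <- read_tree(sprintf("((A:5,B:5):%g,C:%g);", t, 5 + t), "coalescent")
    gene_tree_topology_probability(
      ape::read.tree(text = "((a,c),b);"), sp, amap)
  }, 0)
  expect_true(all(diff(inc) < 0))
})

test_that("star species tree gives exchangeable (uniform) topologies", {
  sp <- read_tree("((A:1,B:0):0,C:1);", "coalescent")  # zero internal branch
  tab <- topology_probability_table(sp, c(a = "A", b = "B", c = "C"))
  expect_equal(tab$probability, rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("topology probabilities sum to 1 and match Monte-Carlo draws", {
  amap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  topos <- enumerate_topologies(names(amap))
  set.seed(99)
  for (depth in c(0.6, 2.1)) {
    sp <- read_tree(sprintf("(A:%g,B:%g);", depth, depth), "coalescent")
    tab <- topology_probability_table(sp, amap, topos)
    expect_equal(sum(tab$probability), 1, tolerance = 1e-9)
    ndraw <- 12000
    freq <- oracle_mc_topology_freq(sp, amap, ndraw, topos)
    se <- sqrt(pmax(tab$probability * (1 - tab$probability), 1e-12) / ndraw)
    expect_true(all(abs(freq - tab$probability) <= 3 * se + 4e-3))
  }
  expect_error(
    gene_tree_topology_probability(
      topos[[1]], read_tree("(A:1,B:1);", "substitutions"), amap),
    "unit error")
})
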