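# Independent oracles used across the suite. These deliberately avoid the
# package's own fast paths: dense matrix recursions in plain R, exhaustive
# path enumeration, brute-force pruning, and Monte-Carlo coalescent
# frequencies.

# Dense scaled forward in plain R (reference implementation).
oracle_forward <- function(pi0, Tm, logE, pidx) {
  L <- length(pidx)
  a <- pi0 * exp(logE[, pidx[1]])
  ll <- log(sum(a)); a <- a / sum(a)
  if (L > 1) for (t in 2:L) {
    a <- as.vector(a %*% Tm) * exp(logE[, pidx[t]])
    ll <- ll + log(sum(a)); a <- a / sum(a)
  }
  ll
}

# Exhaustive log-likelihood: sum over all state paths.
oracle_exhaustive_loglik <- function(pi0, Tm, logE, pidx) {
  K <- length(pi0); L <- length(pidx)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  lp <- apply(paths, 1, function(p) {
    v <- log(pi0[p[1]]) + logE[p[1], pidx[1]]
    if (L > 1) for (t in 2:L) v <- v + log(Tm[p[t - 1], p[t]]) + logE[p[t], pidx[t]]
    v
  })
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))), max = max(lp))
}

# Brute-force column likelihood: marginalize internal node states directly.
oracle_column_likelihood <- function(tree, gtr, column) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- introscan:::node_children(tree)
  elen <- numeric(nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  obs <- match(toupper(column[tree$tip.label]), c("A", "C", "G", "T"))
  internal <- (ntip + 1L):nnode
  combos <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    st <- integer(nnode)
    st[seq_len(ntip)] <- obs
    st[internal] <- combos[r, ]
    pr <- gtr$freqs[st[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      pr <- pr * gtr_pmat(gtr, elen[ch])[st[par], st[ch]]
    }
    tot <- tot + pr
  }
  log(unname(tot))
}

# Monte-Carlo gene-tree topology frequencies on a two-population species
# tree via the package-independent event simulation below.
oracle_mc_topology_freq <- function(species_tree, allele_map, ndraw,
                                    topologies) {
  canon <- vapply(topologies, function(x)
    attr(x, "canonical") %||% canonical_newick(x), "")
  counts <- setNames(numeric(length(canon)), canon)
  depth <- ape::node.depth.edgelength(species_tree)
  ntip <- length(species_tree$tip.label)
  times <- max(depth[seq_len(ntip)]) - depth
  for (i in seq_len(ndraw)) {
    g <- oracle_draw_msc(species_tree, allele_map, times)
    counts[canonical_newick(g)] <- counts[canonical_newick(g)] + 1
  }
  counts / ndraw
}

# Draw one genealogy under the multispecies coalescent on an arbitrary
# rooted species tree (independent of the package's simulator internals:
# merges species in node-time order and coalesces exchangeable lineages).
oracle_draw_msc <- function(species_tree, allele_map, times) {
  ntip <- length(species_tree$tip.label)
  cs <- introscan:::clade_sets(species_tree)
  events <- order(times[(ntip + 1L):(ntip + species_tree$Nnode)]) + ntip
  frag <- as.list(names(allele_map))
  pop <- unname(allele_map[names(allele_map)])
  t <- 0
  coalesce_until <- function(tmax) {
    repeat {
      sizes <- table(pop)
      rate <- sum(choose(sizes, 2))
      if (rate == 0) { t <<- tmax; return(invisible()) }
      dt <- rexp(1, rate)
      if (t + dt > tmax) { t <<- tmax; return(invisible()) }
      t <<- t + dt
      p <- sample(names(sizes), 1, prob = choose(sizes, 2))
      pair <- sample(which(pop == p), 2)
      frag[[pair[1]]] <<- list(frag[[pair[1]]], frag[[pair[2]]])
      frag <<- frag[-pair[2]]; pop <<- pop[-pair[2]]
    }
  }
  for (ev in events) {
    coalesce_until(times[ev])
    merged <- species_tree$tip.label[species_tree$tip.label %in% cs[[ev]]]
    pop[pop %in% merged] <- paste(sort(merged), collapse = "+")
  }
  coalesce_until(Inf)
  nest_to_phylo <- function(x) {
    s <- nest_str(x)
    ape::read.tree(text = paste0(s, ";"))
  }
  nest_str <- function(x) {
    if (!is.list(x)) return(x)
    paste0("(", nest_str(x[[1]]), ",", nest_str(x[[2]]), ")")
  }
  nest_to_phylo(frag[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small shared fixtures -----------------------------------------------------

three_taxon_forest <- function() {
  t1 <- read_tree("((A:5,B:5):1,C:6);", "coalescent")
  t2 <- read_tree("(A:6,(B:5,C:5):1);", "coalescent")
  parental_forest(list(t1, t2), c(a = "A", b = "B", c = "C"),
                  introgressed = 2L)
}

mouse_style_forest <- function() {
  t1 <- read_tree("(A:30,B:30);", "coalescent")
  t2 <- read_tree("(A:0.25,B:0.25);", "coalescent")
  parental_forest(list(t1, t2), c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
                  introgressed = 2L)
}

# 7-state generating model with distinct per-topology branch lengths, used
# by the parameter-recovery experiments. Branch lengths sit at typical
# phylogenetic divergences so the shared blocks (and hence the switch
# factors) are statistically identifiable at moderate alignment lengths.
recovery_model <- function(gamma = 0.05, s1 = 0.1, s2 = 0.3) {
  m <- build_model(three_taxon_forest(), gtr_params(),
                   hmm_params(gamma, s1, s2))
  short <- 0.05; long <- 0.25
  for (b in seq_along(m$blocks)) {
    tr <- m$blocks[[b]]$tree
    cs <- introscan:::clade_sets(tr)
    lens <- vapply(tr$edge[, 2], function(nd)
      if (length(cs[[nd]]) == 1) short else long, 0)
    # the odd tip out gets a long pendant so topologies are
    # emission-distinguishable
    pair <- cs[[tr$edge[which(vapply(tr$edge[, 2], function(nd)
      length(cs[[nd]]), 0) == 2)[1], 2]]]
    odd <- setdiff(tr$tip.label, pair)
    lens[tr$edge[, 2] == match(odd, tr$tip.label)] <- long
    m$blocks[[b]]$tree$edge.length <- lens
  }
  m
}
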