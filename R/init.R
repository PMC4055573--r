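# Hypothesis-based initialization of the shared gene-tree branch-length
# blocks. Coordinate ascent on the joint likelihood can stall in a
# no-introgression local optimum when every block starts from the same
# lengths, because states belonging to different parental classes then have
# identical emission distributions. Each block is therefore seeded from the
# coalescent-expected pairwise distances under the parental class that best
# supports its topology, with the mutation scale estimated from the data.

# Pairwise JC69-corrected distances between alignment rows (model alleles).
observed_jc_distances <- function(model, alignment) {
  idx <- match(model$alleles, alignment$labels)
  m <- alignment$codes[idx, , drop = FALSE]
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(model$alleles, model$alleles))
  plain <- m >= 1 & m <= 4
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- plain[i, ] & plain[j, ]
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    p <- min(p, 0.749)
    D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  D
}

# Expected coalescent-unit path time between two alleles under one parental
# tree: twice (species divergence time + 1), the +1 being the expected extra
# coalescent time above the barrier.
expected_coalescent_paths <- function(forest, class_index) {
  tr <- forest$trees[[class_index]]
  depth <- ape::node.depth.edgelength(tr)
  ntip <- length(tr$tip.label)
  times <- max(depth[seq_len(ntip)]) - depth
  alleles <- names(forest$allele_map)
  n <- length(alleles)
  M <- matrix(0, n, n, dimnames = list(alleles, alleles))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    si <- forest$allele_map[[alleles[i]]]
    sj <- forest$allele_map[[alleles[j]]]
    tau <- if (si == sj) 0 else {
      nd <- ape::getMRCA(tr, c(match(si, tr$tip.label), match(sj, tr$tip.label)))
      times[nd]
    }
    M[i, j] <- M[j, i] <- 2 * (tau + 1)
  }
  M
}

# Least-squares internal-edge lengths for a block tree given a target
# distance matrix over its tips and fixed per-tip pendant lengths; the
# redundant (non-free) edge stays 0. Returns the full edge-length vector.
ls_block_lengths <- function(block, target, pendants) {
  tr <- block$tree
  ntip <- length(tr$tip.label)
  pairs <- utils::combn(ntip, 2)
  npair <- ncol(pairs)
  # edge incidence of each tip-to-tip path
  parent_of <- integer(ntip + tr$Nnode)
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  edge_of <- integer(ntip + tr$Nnode)
  edge_of[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
  path_to_root <- function(nd) {
    out <- integer(0)
    while (parent_of[nd] != 0) { out <- c(out, edge_of[nd]); nd <- parent_of[nd] }
    out
  }
  lens <- numeric(nrow(tr$edge))
  pend_edge <- tr$edge[, 2] <= ntip
  lens[pend_edge] <- pendants[tr$tip.label[tr$edge[pend_edge, 2]]]
  internal_free <- intersect(which(!pend_edge), block$free_edges)
  A <- matrix(0, npair, nrow(tr$edge))
  d <- numeric(npair)
  for (k in seq_len(npair)) {
    p1 <- path_to_root(pairs[1, k]); p2 <- path_to_root(pairs[2, k])
    path <- c(setdiff(p1, p2), setdiff(p2, p1))
    A[k, path] <- 1
    d[k] <- target[tr$tip.label[pairs[1, k]], tr$tip.label[pairs[2, k]]] -
      sum(lens[intersect(path, which(pend_edge))])
  }
  if (length(internal_free)) {
    Ai <- A[, internal_free, drop = FALSE]
    keep <- rowSums(Ai) > 0
    co <- qr.coef(qr(Ai[keep, , drop = FALSE]), pmax(d[keep], 0))
    co[is.na(co)] <- 1e-5
    lens[internal_free] <- pmin(pmax(co, 1e-5), 10)
  }
  lens[pend_edge] <- pmin(pmax(lens[pend_edge], 1e-5), 10)
  lens
}

#' Seed gene-tree branch-length blocks from data and hypothesis
#'
#' For every shared branch-length block, picks the parental class giving
#' its topology the highest coalescent probability, computes the expected
#' pairwise coalescent path times under that class (scaled by a mutation
#' parameter estimated from the observed cross-species JC distances under
#' class 1), and fits the block's internal edges to those targets by least
#' squares. Pendant edges are fixed at a shared, data-driven reference --
#' half the observed distance to each allele's nearest neighbor -- except
#' that a block's own cherry pairs get shrunk pendants (conditional on the
#' genealogy, a cherry coalesced before the other pairs). Sharing the
#' pendant reference across blocks keeps singleton-site likelihoods equal
#' everywhere, so rare pendant mutations cannot masquerade as
#' introgression evidence, while the cherry and internal-edge structure
#' still separates the classes for the first ascent round.
#'
#' @param model A `phmm_model`.
#' @param alignment A [site_alignment()].
#' @return The model with updated block branch lengths.
#' @export
init_gene_blocks <- function(model, alignment) {
  D <- observed_jc_distances(model, alignment)
  M1 <- expected_coalescent_paths(model$forest, 1L)
  cross <- which(upper.tri(D) & M1 > 2)   # pairs from different species
  if (!length(cross) || all(D[cross] <= 0)) return(model)
  # mutation scale from the deepest class-1 pairs only: their divergence is
  # unaffected by introgression, so the estimate stays calibrated even when
  # most of the genome is of introgressive descent
  deepest <- cross[M1[cross] >= max(M1[cross]) - 1e-9]
  theta_hat <- 2 * mean(D[deepest] / M1[deepest])
  diag(D) <- Inf
  pend0 <- apply(D, 1, min) / 2           # shared nearest-neighbor reference
  diag(D) <- 0
  Tn <- model$n_topologies
  topo_block <- model$states$block[seq_len(Tn)]
  for (b in seq_along(model$blocks)) {
    g <- which(topo_block == b)[1]
    cl <- which.max(model$P[, g])
    target <- (theta_hat / 2) * expected_coalescent_paths(model$forest, cl)
    pend <- pend0
    for (p in block_cherries(model$blocks[[b]]$tree)) {
      same_species <- model$forest$allele_map[[p[1]]] ==
        model$forest$allele_map[[p[2]]]
      if (same_species) next   # already close; shrinking would only break
                               # pendant parity across blocks
      cherry_d <- min(target[p[1], p[2]], 0.25 * D[p[1], p[2]])
      target[p[1], p[2]] <- target[p[2], p[1]] <- cherry_d
      pend[p] <- pmin(pend[p], cherry_d / 2)
    }
    lens <- ls_block_lengths(model$blocks[[b]], target, pend)
    Mcl <- expected_coalescent_paths(model$forest, cl)
    off <- upper.tri(Mcl)
    if (cl %in% model$forest$introgressed &&
        min(Mcl[off] / M1[off]) < 0.5) {
      # when the introgressed hypothesis is genuinely shallow relative to
      # class 1, every in-group coalescence happens within ~1 coalescent
      # unit of the divergence, so internal edges cannot be deep; deep
      # outgroup distances otherwise leak into them through the least
      # squares and hand the class a spurious channel for explaining
      # chance homoplasies
      ntipb <- length(model$blocks[[b]]$tree$tip.label)
      internal <- model$blocks[[b]]$tree$edge[, 2] > ntipb
      lens[internal] <- pmin(lens[internal], theta_hat)
    }
    model$blocks[[b]]$tree$edge.length <- lens
    # the redundant rooted-representation edge stays fixed at zero
    fixed0 <- setdiff(seq_along(model$blocks[[b]]$tree$edge.length),
                      model$blocks[[b]]$free_edges)
    model$blocks[[b]]$tree$edge.length[fixed0] <- 0
  }
  model
}

# Tip-label pairs forming two-leaf clades (cherries) in a block tree.
block_cherries <- function(tr) {
  ntip <- length(tr$tip.label)
  kids <- node_children(tr)
  out <- list()
  for (nd in (ntip + 1L):(ntip + tr$Nnode)) {
    k <- kids[[nd]]
    if (length(k) == 2 && all(k <= ntip))
      out[[length(out) + 1L]] <- tr$tip.label[k]
  }
  out
}
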