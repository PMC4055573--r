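# Multispecies-coalescent gene-tree topology probabilities by enumeration of
# coalescent histories (assignments of gene-tree coalescences to species-tree
# branches). Exact for small allele counts (<= 6); each history contributes a
# product over species-tree populations of
#   g_{u,v}(t) * (#orderings consistent with the gene tree) / prod_k C(k,2),
# where g_{u,v}(t) is the probability that u lineages coalesce down to v in
# time t (Tavare's formula) and the combinatorial ratio is the probability
# that the d = u - v merges are exactly the ones the history prescribes.

#' Probability that i lineages coalesce to j lineages within time t
#'
#' Tavare's closed form for the pure-death lineage-count process of the
#' coalescent, on the time scale where each pair coalesces at rate 1.
#'
#' @param i Starting number of lineages.
#' @param j Ending number of lineages (1 <= j <= i).
#' @param t Branch duration in coalescent units; `Inf` allowed.
#' @return A probability.
#' @export
coalescent_gij <- function(i, j, t) {
  stopifnot(i >= 1, j >= 1, j <= i, t >= 0)
  if (t == 0) return(as.numeric(i == j))
  if (!is.finite(t)) return(as.numeric(j == 1))
  tot <- 0
  for (k in j:i) {
    term <- exp(-k * (k - 1) * t / 2) *
      (2 * k - 1) * (-1)^(k - j) /
      (factorial(j) * factorial(k - j) * (j + k - 1))
    for (y in seq_len(k) - 1) term <- term * (j + y) * (i - y) / (i + y)
    tot <- tot + term
  }
  min(max(tot, 0), 1)
}

# Species-tree population structure. A population sits above each node
# (edge-population above non-root nodes; the root population has infinite
# duration). Returns per-node: duration, parent node, species below.
species_populations <- function(species_tree) {
  ntip <- length(species_tree$tip.label)
  nnode <- ntip + species_tree$Nnode
  root <- ntip + 1L
  dur <- rep(Inf, nnode)
  parent <- rep(NA_integer_, nnode)
  for (e in seq_len(nrow(species_tree$edge))) {
    ch <- species_tree$edge[e, 2]
    dur[ch] <- species_tree$edge.length[e]
    parent[ch] <- species_tree$edge[e, 1]
  }
  list(ntip = ntip, nnode = nnode, root = root, dur = dur, parent = parent,
       below = clade_sets(species_tree))
}

# Chain of node ids from `nd` to the root, inclusive.
ancestor_chain <- function(pops, nd) {
  out <- nd
  while (!is.na(pops$parent[nd])) {
    nd <- pops$parent[nd]
    out <- c(out, nd)
  }
  out
}

# Number of linear extensions of the gene-tree ancestry order restricted to
# `nodes` (internal gene-tree node ids). desc[u, v] TRUE when u is a strict
# descendant of v.
count_linear_extensions <- function(nodes, desc) {
  n <- length(nodes)
  if (n <= 1) return(1)
  rec <- function(remaining) {
    if (length(remaining) == 1) return(1)
    tot <- 0
    for (m in remaining) {
      # m can come first iff no remaining node is a strict descendant of m
      if (!any(desc[remaining, m])) tot <- tot + rec(setdiff(remaining, m))
    }
    tot
  }
  rec(nodes)
}

#' Gene-tree topology probability under the multispecies coalescent
#'
#' Computes P(gene-tree topology | species tree) by enumerating coalescent
#' histories: every assignment of the gene tree's coalescences to
#' species-tree populations that respects both the species memberships of
#' the alleles and the gene tree's own ancestry order. Exact; intended for
#' small problems (at most 6 alleles).
#'
#' @param gene_topology `phylo` with allele-labeled leaves (topology only).
#' @param species_tree Rooted `phylo` in coalescent units
#'   (see [read_tree()]).
#' @param allele_map Named character vector, allele id -> species id.
#' @return The topology probability.
#' @export
#' @examples
#' sp <- read_tree("((A:1,B:1):1,C:2);", "coalescent")
#' g <- ape::read.tree(text = "((a,c),b);")
#' gene_tree_topology_probability(g, sp, c(a = "A", b = "B", c = "C"))
#' # = exp(-1)/3, the classic ILS probability of one incongruent topology
gene_tree_topology_probability <- function(gene_topology, species_tree,
                                           allele_map) {
  if (!is.null(tree_units(species_tree)) &&
      tree_units(species_tree) != "coalescent")
    stop("unit error: species tree must be in coalescent units", call. = FALSE)
  alleles <- gene_topology$tip.label
  if (length(alleles) > 6)
    stop("enumeration method supports at most 6 alleles", call. = FALSE)
  missing <- setdiff(alleles, names(allele_map))
  if (length(missing))
    stop("mapping error: unmapped allele(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  pops <- species_populations(species_tree)
  ntip_g <- length(alleles)
  nnode_g <- ntip_g + gene_topology$Nnode
  internal <- (ntip_g + 1L):nnode_g
  gsets <- clade_sets(gene_topology)

  # strict-descendant matrix among gene-tree internal nodes
  desc <- matrix(FALSE, nnode_g, nnode_g)
  for (u in internal) for (v in internal) {
    if (u != v && all(gsets[[u]] %in% gsets[[v]])) desc[u, v] <- TRUE
  }

  # candidate populations per gene coalescence: from the species-MRCA of the
  # coalescing alleles' species up to the root population
  sp_of <- function(gnd) unique(unname(allele_map[gsets[[gnd]]]))
  cand <- vector("list", length(internal))
  for (ii in seq_along(internal)) {
    spset <- sp_of(internal[ii])
    mrca <- NA_integer_
    for (nd in seq_len(pops$nnode)) {
      if (all(spset %in% pops$below[[nd]])) {
        if (is.na(mrca) || length(pops$below[[nd]]) < length(pops$below[[mrca]]))
          mrca <- nd
      }
    }
    cand[[ii]] <- ancestor_chain(pops, mrca)
  }

  # species-node ancestry (for the child-before-parent population constraint)
  anc_sp <- matrix(FALSE, pops$nnode, pops$nnode)  # anc_sp[a, b]: a ancestral-or-equal to b
  for (b in seq_len(pops$nnode)) {
    for (a in ancestor_chain(pops, b)) anc_sp[a, b] <- TRUE
  }

  # lineages entering each leaf population
  enter_leaf <- integer(pops$nnode)
  for (s in seq_len(pops$ntip)) {
    enter_leaf[s] <- sum(allele_map[alleles] == species_tree$tip.label[s])
  }
  kids_sp <- node_children(species_tree)
  post_sp <- rev(order_nodes_preorder(species_tree))  # children before parents

  total <- 0
  # depth-first enumeration over candidate assignments
  assign <- integer(length(internal))
  recurse <- function(level) {
    if (level > length(internal)) {
      total <<- total + history_probability(assign)
      return(invisible())
    }
    v <- internal[level]
    for (p in cand[[level]]) {
      ok <- TRUE
      # v's population must be ancestral-or-equal to its internal children's
      for (w_i in seq_along(internal)) {
        w <- internal[w_i]
        if (w_i < level && desc[w, v] && !anc_sp[p, assign[w_i]]) { ok <- FALSE; break }
        if (w_i < level && desc[v, w] && !anc_sp[assign[w_i], p]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[level] <<- p
      recurse(level + 1L)
    }
  }

  history_probability <- function(assign) {
    d <- tabulate(assign, nbins = pops$nnode)
    enter <- integer(pops$nnode)
    exit <- integer(pops$nnode)
    prob <- 1
    for (nd in post_sp) {
      enter[nd] <- if (nd <= pops$ntip) enter_leaf[nd] else
        sum(exit[kids_sp[[nd]]])
      exit[nd] <- enter[nd] - d[nd]
      if (enter[nd] == 0 && d[nd] == 0) next   # empty population
      if (exit[nd] < 1) return(0)
      if (nd == pops$root && exit[nd] != 1) return(0)
      if (d[nd] > 0 || nd != pops$root) {
        prob <- prob * coalescent_gij(enter[nd], exit[nd], pops$dur[nd])
      }
      if (d[nd] > 0) {
        here <- internal[assign == nd]
        w <- count_linear_extensions(here, desc)
        denom <- prod(choose(seq(exit[nd] + 1, enter[nd]), 2))
        prob <- prob * w / denom
      }
      if (prob == 0) return(0)
    }
    prob
  }

  recurse(1L)
  total
}

#' Topology-probability table for one parental tree
#'
#' Enumerates all rooted topologies on the allele set and computes each one's
#' multispecies-coalescent probability given the parental tree. Over a full
#' enumeration the probabilities sum to 1 (up to numerical error); the
#' `normalized` column divides by the realized sum.
#'
#' @param species_tree Rooted parental tree in coalescent units.
#' @param allele_map Named character vector, allele id -> species id.
#' @param topologies Optional list from [enumerate_topologies()] (computed
#'   from `names(allele_map)` when omitted).
#' @return A data frame with columns `topology` (canonical newick),
#'   `probability` and `normalized`.
#' @export
topology_probability_table <- function(species_tree, allele_map,
                                       topologies = NULL) {
  if (is.null(topologies))
    topologies <- enumerate_topologies(names(allele_map))
  p <- vapply(topologies, gene_tree_topology_probability, 0,
              species_tree = species_tree, allele_map = allele_map)
  if (any(is.na(p)))
    stop("numeric error: NaN topology probability", call. = FALSE)
  data.frame(
    topology = vapply(topologies, function(x) attr(x, "canonical") %||%
                        canonical_newick(x), ""),
    probability = p,
    normalized = p / sum(p),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
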