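# Rooted-tree plumbing: newick I/O with unit tags, canonical forms, topology
# enumeration and congruence testing. Trees are ape "phylo" objects carrying a
# "units" attribute ("coalescent" for species/parental trees, "substitutions"
# for gene trees).

#' Read a rooted binary tree from a newick string
#'
#' Thin wrapper around [ape::read.tree()] that validates the string, enforces
#' a binary rooted topology, replaces missing branch lengths with 0 and tags
#' the tree with its branch-length units.
#'
#' @param text A single newick string (must end with `;`).
#' @param units Branch-length units: `"coalescent"` (species/parental trees;
#'   one unit = 2N generations, the scale on which one pair of lineages
#'   coalesces at rate 1) or `"substitutions"` (gene trees; expected
#'   substitutions per site).
#' @return A rooted binary `phylo` with attribute `units`.
#' @export
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);", "coalescent")
read_tree <- function(text, units = c("coalescent", "substitutions")) {
  units <- match.arg(units)
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed newick string: ", text, call. = FALSE)
  if (is.null(phy$edge.length)) {
    phy$edge.length <- numeric(nrow(phy$edge))
  } else {
    phy$edge.length[is.na(phy$edge.length)] <- 0
  }
  if (any(phy$edge.length < 0))
    stop("negative branch length in newick input", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!is_binary_rooted(phy))
    stop("non-binary tree: every internal node must have exactly 2 children",
         call. = FALSE)
  attr(phy, "units") <- units
  phy
}

# Pre-parse check so syntax errors report a character position.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unbalanced ')' at character ", i, call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("malformed newick: ", depth, " unclosed '(' (string ends at character ",
         length(chars), ")", call. = FALSE)
  if (!grepl(";\\s*$", text))
    stop("malformed newick: missing terminal ';' at character ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

#' Write a tree as newick
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A newick string.
#' @export
write_tree <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Units tag of a tree
#' @param tree A `phylo` read with [read_tree()] or built by this package.
#' @return `"coalescent"`, `"substitutions"`, or `NULL` for bare topologies.
#' @export
tree_units <- function(tree) attr(tree, "units")

is_binary_rooted <- function(phy) {
  nkids <- tabulate(phy$edge[, 1], nbins = length(phy$tip.label) + phy$Nnode)
  all(nkids[nkids > 0L] == 2L)
}

# Children adjacency list indexed by node id.
node_children <- function(phy) {
  split(phy$edge[, 2], factor(phy$edge[, 1],
                              levels = seq_len(length(phy$tip.label) + phy$Nnode)))
}

# Tip-label set below each node (list over all node ids).
clade_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  kids <- node_children(phy)
  sets <- vector("list", nnode)
  ord <- rev(order_nodes_preorder(phy))    # children before parents
  for (nd in ord) {
    if (nd <= ntip) {
      sets[[nd]] <- phy$tip.label[nd]
    } else {
      sets[[nd]] <- unlist(sets[kids[[nd]]], use.names = FALSE)
    }
  }
  sets
}

# Preorder of all node ids starting at the root (parents before children).
order_nodes_preorder <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  kids <- node_children(phy)
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, nd)
    stack <- c(stack, rev(kids[[nd]]))
  }
  out
}

#' Canonical newick string of a rooted topology
#'
#' Children are sorted lexicographically at every node and branch lengths are
#' dropped, so two trees have equal canonical strings iff they are isomorphic
#' as rooted labeled topologies. Used for deterministic state ordering.
#'
#' @param tree A `phylo`.
#' @return A newick string without branch lengths.
#' @export
canonical_newick <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- node_children(tree)
  rec <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    parts <- sort(vapply(kids[[nd]], rec, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(ntip + 1L), ";")
}

# ---- topology enumeration -------------------------------------------------

# Nested-list tree helpers used only during enumeration.
nested_insert_everywhere <- function(t, lab) {
  out <- list(list(t, lab))                    # new root above t
  if (is.list(t)) {
    for (i in 1:2) {
      for (sub in nested_insert_everywhere(t[[i]], lab)) {
        t2 <- t
        t2[[i]] <- sub
        out <- c(out, list(t2))
      }
    }
  }
  out
}

nested_to_newick <- function(t) {
  if (!is.list(t)) return(t)
  parts <- sort(c(nested_to_newick(t[[1]]), nested_to_newick(t[[2]])))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Enumerate all rooted binary topologies on a label set
#'
#' There are (2n-3)!! rooted binary topologies on n labels. They are returned
#' in a deterministic canonical order (sorted canonical newick), which fixes
#' the HMM state ordering across runs.
#'
#' @param labels Character vector of 2 to 8 distinct labels.
#' @return List of `phylo` topologies (no branch lengths), each with
#'   attribute `canonical` (its canonical newick string).
#' @export
#' @examples
#' length(enumerate_topologies(c("a", "b", "c", "d")))  # 15
enumerate_topologies <- function(labels) {
  labels <- as.character(labels)
  n <- length(unique(labels))
  if (n != length(labels)) stop("labels must be distinct", call. = FALSE)
  if (n < 2 || n > 8)
    stop("size error: need between 2 and 8 labels, got ", n, call. = FALSE)
  labels <- sort(labels)
  trees <- list(labels[[1]])
  for (k in seq_len(n)[-1]) {
    trees <- unlist(lapply(trees, nested_insert_everywhere, lab = labels[[k]]),
                    recursive = FALSE)
  }
  nwk <- vapply(trees, nested_to_newick, "")
  nwk <- sort(nwk)
  lapply(nwk, function(s) {
    phy <- ape::read.tree(text = paste0(s, ";"))
    attr(phy, "canonical") <- paste0(s, ";")
    phy
  })
}

#' Number of rooted binary topologies on n leaves, (2n-3)!!
#' @param n Number of leaves (>= 2).
#' @return Integer count.
#' @export
n_rooted_topologies <- function(n) {
  if (n < 2) stop("n must be >= 2")
  prod(seq(3, max(3, 2 * n - 3), by = 2)[seq_len(max(0, n - 2))]) * 1
}

# ---- congruence -----------------------------------------------------------

#' Test whether a gene-tree topology is congruent with a parental tree
#'
#' A gene genealogy (leaves = alleles) is congruent with a parental species
#' tree when every species' alleles are monophyletic and the induced
#' species-level topology equals the parental topology. Any arrangement of
#' alleles within a species counts as congruent, so each parental tree has
#' exactly one congruent topology class.
#'
#' @param gene_tree `phylo` with allele-labeled leaves (topology suffices).
#' @param parental `phylo` with species-labeled leaves.
#' @param allele_map Named character vector, allele id -> species id.
#' @return `TRUE` or `FALSE`.
#' @export
is_congruent <- function(gene_tree, parental, allele_map) {
  alleles <- gene_tree$tip.label
  missing <- setdiff(alleles, names(allele_map))
  if (length(missing))
    stop("mapping error: unmapped allele(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sp <- allele_map[alleles]
  cl <- clade_sets(gene_tree)
  for (s in unique(sp)) {
    a <- alleles[sp == s]
    if (length(a) > 1) {
      mono <- any(vapply(cl, function(x) setequal(x, a), TRUE))
      if (!mono) return(FALSE)
    }
  }
  keep <- alleles[!duplicated(sp)]
  if (length(keep) < 2) return(TRUE)
  ind <- ape::keep.tip(gene_tree, keep)
  ind$tip.label <- unname(allele_map[ind$tip.label])
  identical(canonical_newick(ind), canonical_newick(parental))
}
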