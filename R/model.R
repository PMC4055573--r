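# Model assembly: parental forests, HMM parameters, state enumeration,
# branch-length sharing blocks and the structured transition matrix.
#
# States are ordered class-major, then by canonical gene-tree topology, with
# the silent start state kept outside the state table (its outgoing
# distribution is `pi0`). The transition matrix follows the two-parameter
# recombination/introgression parameterization:
#   within class  (c,i) -> (c,j), j != i :  (1-gamma) * s_i * Pt_c(j)
#   across classes (c,i) -> (c',j)       :  gamma/(K-1) * Pt_c'(j)
#   diagonal: remainder so each row sums to 1
# where Pt_c is the class-normalized coalescent topology probability and
# s_i is s1 for a congruent source genealogy, s2 for an incongruent one.

#' Parental forest: the set of parental trees displayed by a network
#'
#' @param trees List of rooted parental trees in coalescent units
#'   ([read_tree()] objects) sharing one leaf label set.
#' @param allele_map Named character vector mapping every allele (alignment
#'   row) to a species (parental-tree leaf).
#' @param introgressed Integer indices of the parental classes representing
#'   introgressive descent (default: every class but the first). Must be a
#'   non-empty proper subset unless a single degenerate class is supplied.
#' @return An object of class `parental_forest`.
#' @export
parental_forest <- function(trees, allele_map,
                            introgressed = seq_along(trees)[-1]) {
  stopifnot(is.list(trees), length(trees) >= 1)
  labs <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), labs))
      stop("all parental trees must share the same leaf label set",
           call. = FALSE)
  }
  if (!all(allele_map %in% labs))
    stop("allele_map assigns alleles to unknown species: ",
         paste(setdiff(allele_map, labs), collapse = ", "), call. = FALSE)
  introgressed <- as.integer(introgressed)
  K <- length(trees)
  if (K == 1) {
    if (length(introgressed))
      stop("a single-class forest has no introgressed class", call. = FALSE)
  } else {
    if (!length(introgressed) || length(introgressed) >= K ||
        any(introgressed < 1) || any(introgressed > K))
      stop("introgressed classes must be a non-empty proper subset of classes",
           call. = FALSE)
  }
  structure(list(trees = trees, allele_map = allele_map,
                 introgressed = introgressed, species = labs),
            class = "parental_forest")
}

#' HMM transition parameters
#'
#' @param gamma Probability that consecutive sites switch parental class
#'   (the introgression switching probability); in (0,1), or 0 for a
#'   degenerate single-class model.
#' @param s1 Genealogy-switch factor out of a congruent genealogy, in (0,1).
#' @param s2 Genealogy-switch factor out of an incongruent genealogy.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(gamma = 0.05, s1 = 0.1, s2 = 0.1) {
  stopifnot(gamma >= 0, gamma < 1, s1 > 0, s1 < 1, s2 > 0, s2 < 1)
  structure(list(gamma = gamma, s1 = s1, s2 = s2), class = "hmm_params")
}

# Unrooted sharing key for a rooted gene topology. For n >= 4 leaves the key
# is the canonical form of the unrooted topology (rooted trees that unroot
# identically share branch lengths, valid under a reversible model). For
# n = 3 every rooted tree unroots to the same star, which would make all
# states emission-equivalent, so rooted topologies keep separate blocks.
unrooted_key <- function(topo) {
  ntip <- length(topo$tip.label)
  if (ntip <= 3) return(canonical_newick(topo))
  u <- ape::unroot(topo)
  r <- ape::root(u, outgroup = sort(topo$tip.label)[1], resolve.root = TRUE)
  canonical_newick(r)
}

# Build the branch-length block tree for one sharing key: a rooted
# representation whose likelihood equals the unrooted one. Returns the tree
# (substitution units) and the indices of its free edges.
make_block_tree <- function(topo, init_len) {
  ntip <- length(topo$tip.label)
  if (ntip <= 3) {
    tr <- topo
    tr$edge.length <- rep(init_len, nrow(tr$edge))
    free <- seq_len(nrow(tr$edge))
  } else {
    u <- ape::unroot(topo)
    tr <- ape::root(u, outgroup = sort(topo$tip.label)[1], resolve.root = TRUE)
    tr$edge.length <- rep(init_len, nrow(tr$edge))
    root <- ntip + 1L
    # the two root edges lie on a single unrooted edge: fix the internal-side
    # one at 0 so the block has exactly 2n-3 free lengths
    redundant <- which(tr$edge[, 1] == root & tr$edge[, 2] > ntip)[1]
    tr$edge.length[redundant] <- 0
    free <- setdiff(seq_len(nrow(tr$edge)), redundant)
  }
  attr(tr, "units") <- "substitutions"
  list(tree = tr, free_edges = free)
}

#' Build a phylo-HMM model
#'
#' Enumerates one state per (parental class, rooted gene-tree topology),
#' computes the coalescent topology-probability table of each class, assigns
#' branch-length sharing blocks, and caches the transition structure.
#'
#' @param forest A [parental_forest()].
#' @param gtr A [gtr_params()] object (default: equal frequencies and rates).
#' @param hmm An [hmm_params()] object.
#' @param gene_bl_init Initial gene-tree branch length (substitutions/site)
#'   used to populate the shared blocks.
#' @return An object of class `phmm_model`.
#' @export
#' @examples
#' t1 <- read_tree("((A:6,B:6):4,C:10);", "coalescent")
#' t2 <- read_tree("(A:10,(B:1,C:1):9);", "coalescent")
#' amap <- c(a = "A", b = "B", c = "C")
#' m <- build_model(parental_forest(list(t1, t2), amap))
#' n_states(m)  # 7: one start state + 2 classes x 3 topologies
build_model <- function(forest, gtr = gtr_params(), hmm = hmm_params(),
                        gene_bl_init = 0.005) {
  stopifnot(inherits(forest, "parental_forest"))
  alleles <- names(forest$allele_map)
  topologies <- enumerate_topologies(alleles)
  Tn <- length(topologies)
  K <- length(forest$trees)

  # coalescent topology probabilities per class
  P <- matrix(0, K, Tn)
  for (c in seq_len(K)) {
    tab <- topology_probability_table(forest$trees[[c]], forest$allele_map,
                                      topologies)
    if (any(!is.finite(tab$probability)))
      stop("numeric error: non-finite topology probability in class ", c,
           call. = FALSE)
    P[c, ] <- tab$probability
  }
  Ptilde <- P / rowSums(P)

  congruent <- matrix(FALSE, K, Tn)
  for (c in seq_len(K)) {
    congruent[c, ] <- vapply(topologies, is_congruent, TRUE,
                             parental = forest$trees[[c]],
                             allele_map = forest$allele_map)
  }

  # branch-length sharing blocks
  keys <- vapply(topologies, unrooted_key, "")
  ukeys <- unique(keys)
  blocks <- lapply(ukeys, function(k) {
    make_block_tree(topologies[[match(k, keys)]], gene_bl_init)
  })
  names(blocks) <- ukeys
  topo_block <- match(keys, ukeys)

  states <- data.frame(
    class = rep(seq_len(K), each = Tn),
    topology = rep(seq_len(Tn), K),
    block = rep(topo_block, K),
    congruent = as.vector(t(congruent)),
    introgressed = rep(seq_len(K) %in% forest$introgressed, each = Tn)
  )
  states$label <- paste0(ifelse(states$introgressed, "f", "e"),
                         states$topology, ".c", states$class)

  if (K == 1 && hmm$gamma != 0) hmm$gamma <- 0

  model <- structure(list(
    forest = forest, alleles = alleles, topologies = topologies,
    topo_canon = vapply(topologies, function(x)
      attr(x, "canonical") %||% canonical_newick(x), ""),
    n_classes = K, n_topologies = Tn, states = states,
    P = P, Ptilde = Ptilde, blocks = blocks, hmm = hmm, gtr = gtr
  ), class = "phmm_model")
  model$pi0 <- start_distribution(model)
  model
}

# Start-state distribution: normalized gene-tree probability over all
# non-start states jointly.
start_distribution <- function(model) {
  v <- as.vector(t(model$P))     # state order is class-major
  v / sum(v)
}

#' Number of HMM states, including the start state
#' @param model A `phmm_model`.
#' @return Integer state count (1 + classes x topologies).
#' @export
n_states <- function(model) nrow(model$states) + 1L

#' Transition matrix over the non-start states
#'
#' @param model A `phmm_model`.
#' @return A row-stochastic matrix (rows/columns ordered as
#'   `model$states`). The start state has no incoming transitions; its
#'   outgoing row is `model$pi0`.
#' @export
transition_matrix <- function(model) {
  st <- model$states
  ns <- nrow(st)
  K <- model$n_classes
  g <- model$hmm$gamma
  gp <- if (K > 1) g / (K - 1) else 0
  svec <- ifelse(st$congruent, model$hmm$s1, model$hmm$s2)
  ptil <- model$Ptilde[cbind(st$class, st$topology)]
  M <- matrix(0, ns, ns, dimnames = list(st$label, st$label))
  for (i in seq_len(ns)) {
    same <- st$class == st$class[i]
    M[i, same] <- (1 - g) * svec[i] * ptil[same]
    M[i, !same] <- gp * ptil[!same]
    M[i, i] <- 0
    M[i, i] <- 1 - sum(M[i, ])
    if (M[i, i] < 0)
      stop("parameter infeasibility: negative diagonal remainder for ",
           "(gamma, s1, s2) = (", g, ", ", model$hmm$s1, ", ", model$hmm$s2,
           ")", call. = FALSE)
  }
  M
}

# Components consumed by the O(K)-per-site structured C++ recursions.
transition_struct <- function(model) {
  st <- model$states
  K <- model$n_classes
  g <- model$hmm$gamma
  svec <- ifelse(st$congruent, model$hmm$s1, model$hmm$s2)
  ptil <- model$Ptilde[cbind(st$class, st$topology)]
  D <- (1 - g) * (1 - svec * (1 - ptil))
  list(cls = st$class - 1L, ptil = ptil, svec = svec, D = D,
       gamma = g, gammap = if (K > 1) g / (K - 1) else 0, K = K)
}

#' @export
print.phmm_model <- function(x, ...) {
  cat("phylo-HMM model:", n_states(x), "states (1 start +", x$n_classes,
      "classes x", x$n_topologies, "topologies)\n")
  cat("  alleles:", paste(x$alleles, collapse = ", "), "\n")
  cat("  introgressed classes:",
      paste(x$forest$introgressed, collapse = ", "), "\n")
  cat("  gamma =", x$hmm$gamma, " s1 =", x$hmm$s1, " s2 =", x$hmm$s2, "\n")
  invisible(x)
}

# ---- alignments -----------------------------------------------------------

#' Construct a site alignment
#'
#' @param x Character matrix (rows = alleles, columns = sites) of IUPAC
#'   codes, or an integer code matrix from [encode_bases()].
#' @param labels Row labels (allele ids); taken from rownames when omitted.
#' @param chrom Optional chromosome label.
#' @param pos Optional integer genomic coordinates (strictly increasing),
#'   one per column.
#' @return An object of class `site_alignment`.
#' @export
site_alignment <- function(x, labels = rownames(x), chrom = NULL, pos = NULL) {
  if (is.character(x)) x <- encode_bases(x)
  stopifnot(is.matrix(x))
  if (is.null(labels)) stop("alignment rows must be labeled", call. = FALSE)
  if (!is.null(pos)) {
    if (length(pos) != ncol(x))
      stop("coordinates must match the number of sites", call. = FALSE)
    if (any(diff(pos) <= 0))
      stop("coordinates must be strictly increasing", call. = FALSE)
  }
  x <- unname(x)
  attr(x, "n_unknown") <- NULL
  structure(list(labels = labels, codes = x, chrom = chrom,
                 pos = pos, L = ncol(x)),
            class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat("site alignment:", length(x$labels), "sequences x", x$L, "sites\n")
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  if (!is.null(x$pos))
    cat("  coordinates:", x$pos[1], "..", x$pos[x$L],
        if (!is.null(x$chrom)) paste0("(", x$chrom, ")"), "\n")
  invisible(x)
}

# Compress an alignment into unique site patterns for the model's alleles.
# Returns codes (n_alleles x n_patterns) and the per-site pattern index.
alignment_patterns <- function(model, alignment) {
  stopifnot(inherits(alignment, "site_alignment"))
  idx <- match(model$alleles, alignment$labels)
  if (any(is.na(idx)))
    stop("alignment is missing allele(s): ",
         paste(model$alleles[is.na(idx)], collapse = ", "), call. = FALSE)
  m <- alignment$codes[idx, , drop = FALSE]
  # base-|codes| hash of each column (fast unique-pattern compression)
  base <- length(CODE_LEVELS) + 1
  key <- as.vector(base^(seq_len(nrow(m)) - 1) %*% m)
  ukey <- unique(key)
  pat <- m[, match(ukey, key), drop = FALSE]
  rownames(pat) <- model$alleles
  list(patterns = pat, index = match(key, ukey))
}

# Per-block and per-state emission tables on a pattern set.
emission_tables <- function(model, patterns) {
  logEb <- vapply(model$blocks, function(b)
    tree_pattern_loglik(b$tree, model$gtr, patterns),
    numeric(ncol(patterns)))
  logEb <- matrix(logEb, ncol = length(model$blocks))  # P x nblock
  logE <- t(logEb)[model$states$block, , drop = FALSE] # ns x P
  list(logE_block = t(logEb), logE = logE)
}
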