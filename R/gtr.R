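# GTR substitution model: stationary frequencies + six symmetric
# exchangeabilities, rate matrix normalized to mean rate 1 so gene-tree
# branch lengths are expected substitutions/site. Emission likelihoods are
# computed with Felsenstein's pruning algorithm; ambiguity codes are
# marginalized over their compatible bases.

BASES <- c("A", "C", "G", "T")
RATE_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

# Column k of this matrix is the 0/1 partial-likelihood vector of code k.
iupac_partials <- local({
  codes <- list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"),
    N = BASES, `-` = BASES, `?` = BASES
  )
  m <- vapply(codes, function(b) as.numeric(BASES %in% b), numeric(4))
  rownames(m) <- BASES
  m
})

CODE_LEVELS <- colnames(iupac_partials)

#' Construct GTR substitution-model parameters
#'
#' @param base_frequencies Stationary frequencies for A, C, G, T
#'   (positive, summing to 1).
#' @param exchangeabilities Six positive rates named AC, AG, AT, CG, CT, GT;
#'   only ratios matter (GT serves as the reference and is conventionally 1).
#' @param normalize Scale the rate matrix to mean rate 1 at stationarity
#'   (default), making branch lengths expected substitutions/site.
#' @return An object of class `gtr_params` with the rate matrix and its
#'   symmetric eigendecomposition cached for fast transition matrices.
#' @export
gtr_params <- function(base_frequencies = rep(0.25, 4),
                       exchangeabilities = stats::setNames(rep(1, 6), RATE_NAMES),
                       normalize = TRUE) {
  pi <- as.numeric(base_frequencies)
  stopifnot(length(pi) == 4, all(pi > 0))
  if (abs(sum(pi) - 1) > 1e-12) stop("base frequencies must sum to 1",
                                     call. = FALSE)
  r <- as.numeric(exchangeabilities)
  stopifnot(length(r) == 6, all(r > 0))
  names(pi) <- BASES
  names(r) <- RATE_NAMES
  R <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  R["A", "C"] <- R["C", "A"] <- r["AC"]
  R["A", "G"] <- R["G", "A"] <- r["AG"]
  R["A", "T"] <- R["T", "A"] <- r["AT"]
  R["C", "G"] <- R["G", "C"] <- r["CG"]
  R["C", "T"] <- R["T", "C"] <- r["CT"]
  R["G", "T"] <- R["T", "G"] <- r["GT"]
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  if (normalize) Q <- Q / sum(-diag(Q) * pi)
  # symmetric form diag(sqrt(pi)) Q diag(1/sqrt(pi)) for stable expm
  sp <- sqrt(pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((S + t(S)) / 2, symmetric = TRUE)
  structure(list(freqs = pi, rates = r, normalize = normalize, Q = Q,
                 eigval = eig$values,
                 left = diag(1 / sp) %*% eig$vectors,
                 right = t(eig$vectors) %*% diag(sp)),
            class = "gtr_params")
}

#' GTR transition-probability matrix over a branch
#' @param gtr A [gtr_params()] object.
#' @param t Branch length (expected substitutions/site).
#' @return 4x4 row-stochastic matrix P(t) = exp(Qt).
#' @export
gtr_pmat <- function(gtr, t) {
  P <- gtr$left %*% (exp(gtr$eigval * t) * gtr$right)
  P[P < 0] <- 0
  dimnames(P) <- list(BASES, BASES)
  P
}

# Encode a character matrix of bases into integer code indices; anything
# outside the IUPAC table becomes N (count reported via attribute).
encode_bases <- function(x) {
  x <- toupper(x)
  idx <- match(x, CODE_LEVELS)
  n_bad <- sum(is.na(idx))
  idx[is.na(idx)] <- match("N", CODE_LEVELS)
  out <- matrix(as.integer(idx), nrow = nrow(x), dimnames = dimnames(x))
  attr(out, "n_unknown") <- n_bad
  out
}

decode_bases <- function(codes) {
  matrix(CODE_LEVELS[codes], nrow = nrow(codes), dimnames = dimnames(codes))
}

#' Log-likelihood of site patterns on a gene tree under GTR
#'
#' Felsenstein pruning with the stationary distribution at the root.
#' Ambiguous or missing codes contribute a partial likelihood of 1 for each
#' compatible base, so an all-missing column has log-likelihood 0.
#'
#' @param tree Rooted `phylo` with branch lengths in substitutions/site
#'   (a multifurcating root is allowed, as used for unrooted
#'   representations under the reversible model).
#' @param gtr A [gtr_params()] object.
#' @param patterns Integer matrix (rows = tree tip labels, columns = site
#'   patterns) of code indices from [encode_bases()], or a character matrix.
#' @return Numeric vector of per-pattern log-likelihoods.
#' @export
tree_pattern_loglik <- function(tree, gtr, patterns) {
  if (is.character(patterns)) patterns <- encode_bases(patterns)
  ntip <- length(tree$tip.label)
  if (nrow(patterns) != ntip)
    stop("pattern rows must match the number of tree leaves", call. = FALSE)
  if (!is.null(rownames(patterns)))
    patterns <- patterns[tree$tip.label, , drop = FALSE]
  P <- ncol(patterns)
  kids <- node_children(tree)
  edge_len <- numeric(ntip + tree$Nnode)
  edge_len[tree$edge[, 2]] <- tree$edge.length
  partial <- vector("list", ntip + tree$Nnode)
  ord <- rev(order_nodes_preorder(tree))
  for (nd in ord) {
    if (nd <= ntip) {
      partial[[nd]] <- iupac_partials[, patterns[nd, ], drop = FALSE]
    } else {
      L <- matrix(1, 4, P)
      for (ch in kids[[nd]]) {
        L <- L * (gtr_pmat(gtr, edge_len[ch]) %*% partial[[ch]])
      }
      partial[[nd]] <- L
    }
  }
  root <- ntip + 1L
  log(as.numeric(gtr$freqs %*% partial[[root]]))
}

#' Emission log-probability of one alignment column on a state's gene tree
#'
#' @param tree Gene tree (substitution-unit branch lengths).
#' @param gtr A [gtr_params()] object.
#' @param column Character vector of base codes, named by allele (or ordered
#'   as the tree's tip labels).
#' @return The log emission probability.
#' @export
emission_log_probability <- function(tree, gtr, column) {
  bad <- setdiff(toupper(column), CODE_LEVELS)
  if (length(bad))
    stop("input error: non-IUPAC code(s) ", paste(bad, collapse = ", "),
         " in column", call. = FALSE)
  m <- matrix(column, ncol = 1)
  rownames(m) <- names(column) %||% tree$tip.label
  tree_pattern_loglik(tree, gtr, m)
}
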