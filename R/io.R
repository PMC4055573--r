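# Readers and writers for the standard formats the tool touches: FASTA and
# relaxed PHYLIP alignments (via ape), a haplotype TSV dialect for phased
# SNP-style data (header: chrom, pos, then one column per haplotype;
# positions 1-based), BED/TSV tracks, and JSON model serialization.

#' Read an alignment
#'
#' @param path File path.
#' @param format `"fasta"`, `"phylip"`, or `"tsv"` (haplotype table with
#'   columns `chrom`, `pos`, then one column per haplotype). Guessed from
#'   the file extension by default.
#' @return A [site_alignment()]; TSV input carries genomic coordinates.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     fa = , fas = , fasta = "fasta",
                     phy = , phylip = "phylip",
                     tsv = , txt = "tsv",
                     stop("cannot guess alignment format of ", path,
                          call. = FALSE))
  }
  if (format == "tsv") return(read_haplotype_tsv(path))
  if (format == "fasta") {
    # BStringSet keeps arbitrary symbols, so junk can be N-coded with a
    # count instead of being silently dropped
    ss <- Biostrings::readBStringSet(path)
    lens <- Biostrings::width(ss)
    if (length(unique(lens)) > 1)
      stop("ragged alignment: row '",
           names(ss)[which(lens != lens[1])[1]], "' has length ",
           lens[lens != lens[1]][1], ", expected ", lens[1], call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
    rownames(m) <- names(ss)
  } else {
    dna <- ape::read.dna(path, format = "sequential")
    m <- toupper(as.character(as.matrix(dna)))
  }
  codes <- encode_bases(m)
  n_bad <- attr(codes, "n_unknown")
  if (n_bad > 0)
    message(n_bad, " unknown symbol(s) coded as N")
  site_alignment(codes, labels = rownames(m))
}

read_haplotype_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos")
  if (!all(need %in% names(df)))
    stop("haplotype TSV must have 'chrom' and 'pos' columns", call. = FALSE)
  haps <- setdiff(names(df), need)
  if (!length(haps)) stop("haplotype TSV has no haplotype columns",
                          call. = FALSE)
  m <- t(as.matrix(df[, haps, drop = FALSE]))
  codes <- encode_bases(m)
  n_bad <- attr(codes, "n_unknown")
  if (n_bad > 0) message(n_bad, " unknown symbol(s) coded as N")
  site_alignment(codes, labels = haps,
                 chrom = df$chrom[1], pos = as.integer(df$pos))
}

#' Write an alignment as FASTA
#' @param alignment A [site_alignment()].
#' @param path Output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  chars <- decode_bases(alignment$codes)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$labels)) {
    writeLines(paste0(">", alignment$labels[i]), con)
    writeLines(paste(chars[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Write an alignment as a haplotype TSV
#' @param alignment A [site_alignment()] (positions default to 1..L).
#' @param path Output path.
#' @export
write_haplotype_tsv <- function(alignment, path) {
  chars <- decode_bases(alignment$codes)
  df <- data.frame(chrom = alignment$chrom %||% "chr1",
                   pos = alignment$pos %||% seq_len(alignment$L))
  for (i in seq_along(alignment$labels)) df[[alignment$labels[i]]] <- chars[i, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write regions as BED (0-based half-open)
#' @param regions Data frame with `chrom`, `start`, `end` columns.
#' @param path Output path.
#' @export
write_bed <- function(regions, path) {
  df <- regions[, c("chrom", "start", "end")]
  df$chrom[is.na(df$chrom)] <- "chr1"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- model serialization --------------------------------------------------

#' Save a model as structured JSON
#'
#' Serializes parental trees (newick, full precision), the allele map,
#' introgressed classes, GTR block, transition parameters and the shared
#' branch-length block trees; [load_model()] rebuilds a model reproducing
#' the same likelihoods.
#'
#' @param model A `phmm_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  obj <- list(
    format = "introscan-model-1",
    parental_trees = vapply(model$forest$trees, write_tree, "", digits = 17),
    allele_map = as.list(model$forest$allele_map),
    introgressed = model$forest$introgressed,
    gtr = list(freqs = unname(model$gtr$freqs),
               rates = unname(model$gtr$rates)),
    hmm = list(gamma = model$hmm$gamma, s1 = model$hmm$s1, s2 = model$hmm$s2),
    blocks = lapply(model$blocks, function(b) write_tree(b$tree, digits = 17)),
    state_order = model$topo_canon
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a model saved with [save_model()]
#' @param path Path to the JSON file.
#' @return A `phmm_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "introscan-model-1"))
    stop("not an introscan model file: ", path, call. = FALSE)
  amap <- unlist(obj$allele_map)
  trees <- lapply(obj$parental_trees, read_tree, units = "coalescent")
  forest <- parental_forest(trees, amap,
                            introgressed = as.integer(obj$introgressed))
  gtr <- gtr_params(obj$gtr$freqs, obj$gtr$rates)
  hmm <- hmm_params(obj$hmm$gamma, obj$hmm$s1, obj$hmm$s2)
  model <- build_model(forest, gtr, hmm)
  # restore block branch lengths (keys are canonical and order-stable)
  for (k in names(obj$blocks)) {
    tr <- ape::read.tree(text = obj$blocks[[k]])
    saved <- setNames(tr$edge.length, tree_edge_keys(tr))
    cur <- model$blocks[[k]]$tree
    model$blocks[[k]]$tree$edge.length <-
      unname(saved[tree_edge_keys(cur)])
  }
  model
}

# Stable edge identifiers (canonical newick of the clade below each edge).
tree_edge_keys <- function(tr) {
  cs <- clade_sets(tr)
  vapply(tr$edge[, 2], function(nd)
    paste(sort(cs[[nd]]), collapse = "|"), "")
}

#' Write the per-site posterior track as TSV
#'
#' Columns: position, introgression posterior, argmax state label and its
#' gene-tree topology.
#'
#' @param decoding A `phmm_decoding`.
#' @param model The `phmm_model`.
#' @param path Output path.
#' @param pos Optional per-site coordinates.
#' @export
write_posterior_tsv <- function(decoding, model, path, pos = NULL) {
  am <- max.col(decoding$posterior, ties.method = "first")
  df <- data.frame(
    pos = pos %||% seq_along(decoding$introgression_posterior),
    p_introgression = decoding$introgression_posterior,
    argmax_state = model$states$label[am],
    argmax_topology = model$topo_canon[model$states$topology[am]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
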