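# Phylogenetic network -> MUL-tree conversion. A network is given in
# extended newick: hybrid nodes are tagged "#H<k>" and may appear once with
# children (the definition) and once or more as bare references; the third
# colon field of a hybrid edge, when present, is its inheritance
# probability. Converting to a multi-labeled tree duplicates the subtree
# under each reticulation once per parent edge; alleles then map to any leaf
# carrying their own species label, and all such allele mappings are
# enumerated.

#' Parse an extended-newick phylogenetic network
#'
#' @param text Extended-newick string, e.g.
#'   `"((A:1,(B:1)#H1:1):1,(#H1:1::0.3,C:1):1);"`.
#' @return A list of class `phylo_network` with a node table (`id`,
#'   `label`, `hybrid_tag`), an edge list (`parent`, `child`, `length`,
#'   `inheritance`), and `root`.
#' @export
read_enewick <- function(text) {
  text <- sub(";\\s*$", "", trimws(text))
  check_newick_syntax(paste0(text, ";"))
  nodes <- list()
  edges <- list()
  new_node <- function(label = NA_character_, tag = NA_character_) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, label = label, tag = tag)
    id
  }
  add_edge <- function(parent, child, len, inh) {
    edges[[length(edges) + 1L]] <<- list(parent = parent, child = child,
                                         length = len, inheritance = inh)
  }
  pos <- 1L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  # returns list(id, length, inheritance) for one subtree + its edge fields
  parse_node <- function() {
    kids <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids[[length(kids) + 1L]] <- parse_node()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed extended newick near character ", pos, call. = FALSE)
      }
    }
    lab <- ""
    while (!(peek() %in% c(":", ",", ")", "", "("))) {
      lab <- paste0(lab, peek()); pos <<- pos + 1L
    }
    fields <- c(NA_real_, NA_real_, NA_real_)
    fi <- 0L
    while (peek() == ":") {
      pos <<- pos + 1L; fi <- fi + 1L
      num <- ""
      while (grepl("[-0-9.eE+]", peek()) && peek() != "")
        { num <- paste0(num, peek()); pos <<- pos + 1L }
      if (nzchar(num) && fi <= 3) fields[fi] <- as.numeric(num)
    }
    tag <- if (grepl("#", lab)) sub("^.*#", "#", lab) else NA_character_
    name <- if (grepl("#", lab)) sub("#.*$", "", lab) else lab
    if (!nzchar(name)) name <- NA_character_
    id <- new_node(name, tag)
    for (k in kids) add_edge(id, k$id, k$len, k$inh)
    list(id = id, len = fields[1] %|na|% 0, inh = fields[3])
  }
  root <- parse_node()
  if (pos <= length(chars))
    stop("trailing characters in extended newick at character ", pos,
         call. = FALSE)
  # merge hybrid nodes sharing a tag: the instance with children defines the
  # subtree; references redirect their incoming edges to it
  tags <- vapply(nodes, function(n) n$tag %|na|% "", "")
  for (tg in unique(tags[nzchar(tags)])) {
    ids <- which(tags == tg)
    has_kids <- vapply(ids, function(i)
      any(vapply(edges, function(e) e$parent == i, TRUE)), TRUE)
    def <- if (any(has_kids)) ids[has_kids][1] else ids[1]
    for (i in setdiff(ids, def)) {
      for (k in seq_along(edges)) {
        if (edges[[k]]$child == i) edges[[k]]$child <- def
      }
    }
  }
  structure(list(nodes = nodes, edges = edges, root = root$id),
            class = "phylo_network")
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Number of reticulations in a network
#' @param network A [read_enewick()] network.
#' @return Integer count of nodes with more than one parent.
#' @export
n_reticulations <- function(network) {
  parents <- table(vapply(network$edges, function(e) e$child, 0L))
  sum(parents > 1)
}

#' Convert a phylogenetic network to a MUL-tree with all allele mappings
#'
#' Duplicates the subtree below each reticulation once per parent edge
#' (carrying branch lengths and tagging each copy with the parent edge's
#' inheritance probability), yielding a multi-labeled tree whose leaf
#' labels may repeat. Every allele of species `s` may map to any leaf
#' labeled `s`; all such mappings are enumerated.
#'
#' @param network A [read_enewick()] network.
#' @param samples Named list: species id -> character vector of allele ids
#'   sampled from it. Defaults to one allele (`<species>_1`) per leaf
#'   species.
#' @return A list of class `mul_tree`: `tree` (`phylo`, possibly with
#'   duplicated tip labels), `leaf_species`, `inheritance` (per-tip product
#'   of inheritance probabilities along its path, NA when unannotated),
#'   `allele_mappings` (data frame: `mapping_index`, `allele`, `leaf`).
#' @export
network_to_multree <- function(network, samples = NULL) {
  kids_of <- function(id) Filter(function(e) e$parent == id, network$edges)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  # expand the DAG into a tree of nested newick fragments; inheritance
  # probabilities multiply along the path
  expand <- function(id, inh) {
    node <- network$nodes[[id]]
    kids <- kids_of(id)
    if (!length(kids)) {
      counter$n <- counter$n + 1L
      return(list(newick = node$label, species = node$label, inh = inh))
    }
    parts <- lapply(kids, function(e) {
      sub <- expand(e$child, inh * (e$inheritance %|na|% 1))
      list(newick = sprintf("%s:%.10g", sub$newick, e$length %|na|% 0),
           species = sub$species, inh = sub$inh)
    })
    list(newick = paste0("(", paste(vapply(parts, `[[`, "", "newick"),
                                    collapse = ","), ")"),
         species = unlist(lapply(parts, `[[`, "species")),
         inh = unlist(lapply(parts, `[[`, "inh")))
  }
  ex <- expand(network$root, 1)
  tree <- ape::read.tree(text = paste0(ex$newick, ";"))
  leaf_species <- tree$tip.label
  if (is.null(samples)) {
    samples <- lapply(unique(leaf_species), function(s) paste0(s, "_1"))
    names(samples) <- unique(leaf_species)
  }
  # enumerate allele mappings: each allele of species s picks a leaf
  # labeled s, independently
  choices <- list()
  for (s in names(samples)) {
    leaves_s <- which(leaf_species == s)
    if (!length(leaves_s))
      stop("species ", s, " has no leaf in the MUL-tree", call. = FALSE)
    for (a in samples[[s]]) choices[[a]] <- leaves_s
  }
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  mappings <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(mapping_index = i, allele = names(choices),
               leaf = as.integer(grid[i, ]), stringsAsFactors = FALSE)
  }))
  structure(list(tree = tree, leaf_species = leaf_species,
                 inheritance = ex$inh,
                 allele_mappings = mappings),
            class = "mul_tree")
}

#' Write MUL-tree outputs
#'
#' The tree as newick (repeated labels allowed) plus a sidecar TSV of all
#' allele mappings (`allele`, `mapping_index`, `leaf_path` -- the tip index
#' and label in the MUL-tree).
#'
#' @param mul A [network_to_multree()] result.
#' @param prefix Output path prefix; writes `<prefix>.nwk` and
#'   `<prefix>.mappings.tsv`.
#' @export
write_multree <- function(mul, prefix) {
  writeLines(write_tree(mul$tree), paste0(prefix, ".nwk"))
  df <- mul$allele_mappings
  df$leaf_path <- paste0(df$leaf, ":", mul$leaf_species[df$leaf])
  utils::write.table(df[, c("allele", "mapping_index", "leaf_path")],
                     paste0(prefix, ".mappings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
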