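# Synthetic-data generator: structured coalescent with isolation, a bounded
# backwards-in-time migration window (A -> B looking backwards, i.e. B -> A
# gene flow forward in time), recombination modeled as sequentially
# independent segments, Jukes-Cantor sequence evolution, and per-site truth
# labels giving a sound lower bound on migration evidence.
#
# Time is measured in coalescent units (one unit = 2N generations; a pair of
# lineages in one population coalesces at rate 1). Branch lengths convert to
# substitutions/site as (theta/2) * coalescent time.

#' Simulation configuration
#'
#' Defaults emulate a house-mouse-like history: in-group divergence 1.5 Mya
#' at 2 generations/year with Ne = 50,000 gives t_split_AB = 30 coalescent
#' units; theta = 4.5e-4/bp reproduces a mutation rate near 4.5e-9
#' substitutions/site/year; migration windows are recent relative to the
#' species split.
#'
#' @param n_A,n_B,n_out Haploid samples per population (outgroup optional).
#' @param t_split_AB Split time of populations A and B (coalescent units).
#' @param t_split_outgroup Split time of the outgroup from the A+B ancestor.
#' @param m Backwards migration rate per A lineage during the window
#'   (0 disables migration; forward-time direction is B into A).
#' @param t_mig_start,t_mig_end Migration window; requires
#'   `0 <= t_mig_start < t_mig_end <= t_split_AB`.
#' @param rho Recombination-breakpoint rate per bp (segments are
#'   independent between breakpoints).
#' @param theta Mutation parameter per bp; substitutions/site =
#'   `(theta/2) * coalescent time`.
#' @param L Sequence length in bp.
#' @param seed Optional seed applied at the start of [simulate_replicate()].
#' @param replicates Replicates per condition (used by experiment drivers).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_A = 2, n_B = 2, n_out = 1,
                       t_split_AB = 30, t_split_outgroup = 45,
                       m = 0, t_mig_start = 0, t_mig_end = 0.5,
                       rho = 2e-4, theta = 4.5e-4, L = 100000L,
                       seed = NULL, replicates = 20) {
  stopifnot(n_A >= 1, n_B >= 1, n_out >= 0, L >= 1, m >= 0,
            rho >= 0, theta >= 0,
            t_mig_start >= 0, t_mig_start < t_mig_end,
            t_mig_end <= t_split_AB, t_split_AB < t_split_outgroup)
  structure(as.list(environment()), class = "sim_config")
}

#' Allele-to-species map implied by a simulation configuration
#' @param config A [sim_config()].
#' @param include_outgroup Include outgroup alleles in the map.
#' @return Named character vector (allele id -> species id).
#' @export
sim_allele_map <- function(config, include_outgroup = FALSE) {
  a <- setNames(rep("A", config$n_A), paste0("a", seq_len(config$n_A)))
  b <- setNames(rep("B", config$n_B), paste0("b", seq_len(config$n_B)))
  o <- if (include_outgroup && config$n_out > 0)
    setNames(rep("O", config$n_out), paste0("o", seq_len(config$n_out)))
  else NULL
  c(a, b, o)
}

#' Draw one genealogy from the structured coalescent
#'
#' Within-population pairs coalesce at rate 1; during the migration window
#' each A-resident lineage moves (backwards in time) to B at rate `m`;
#' populations A and B merge at `t_split_AB` and the outgroup joins at
#' `t_split_outgroup`. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @return An object of class `genealogy`: `phylo` (coalescent-unit branch
#'   lengths), `times` (node times, tips at 0), `tip_pop`.
#' @export
simulate_genealogy <- function(config) {
  labs <- names(sim_allele_map(config, include_outgroup = TRUE))
  pop0 <- unname(sim_allele_map(config, include_outgroup = TRUE))
  n <- length(labs)
  act <- as.list(seq_len(n))          # active subtrees as newick fragments
  frag <- labs
  node_time <- rep(0, n)
  act_pop <- pop0
  act_time <- rep(0, n)               # time of each active subtree's root
  time <- 0
  boundaries <- sort(unique(c(config$t_mig_start, config$t_mig_end,
                              config$t_split_AB, config$t_split_outgroup, Inf)))
  merge_pops <- function(t) {
    if (t >= config$t_split_AB) act_pop[act_pop %in% c("A", "B")] <<- "AB"
    if (t >= config$t_split_outgroup) act_pop[TRUE] <<- "R"
  }
  events <- 0L
  while (length(frag) > 1) {
    events <- events + 1L
    if (events > 1e6) stop("coalescent event cap exceeded")
    tabp <- table(act_pop)
    coal_rates <- vapply(names(tabp), function(p) choose(tabp[[p]], 2), 0)
    in_window <- time >= config$t_mig_start && time < config$t_mig_end
    mig_rate <- if (in_window) config$m * sum(act_pop == "A") else 0
    tot <- sum(coal_rates) + mig_rate
    nxt_boundary <- boundaries[boundaries > time][1]
    if (tot == 0) {
      time <- nxt_boundary
      merge_pops(time)
      next
    }
    dt <- rexp(1, tot)
    if (time + dt >= nxt_boundary) {
      time <- nxt_boundary
      merge_pops(time)
      next
    }
    time <- time + dt
    if (runif(1) < mig_rate / tot) {
      i <- sample(which(act_pop == "A"), 1)
      act_pop[i] <- "B"
    } else {
      p <- sample(names(coal_rates), 1, prob = coal_rates)
      pair <- sample(which(act_pop == p), 2)
      i <- pair[1]; j <- pair[2]
      newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], time - act_time[i],
                         frag[j], time - act_time[j])
      frag[i] <- newfrag
      act_time[i] <- time
      keep <- setdiff(seq_along(frag), j)
      frag <- frag[keep]; act_pop <- act_pop[keep]; act_time <- act_time[keep]
    }
  }
  phy <- ape::read.tree(text = paste0(frag[1], ";"))
  attr(phy, "units") <- "coalescent"
  depth <- ape::node.depth.edgelength(phy)
  times <- max(depth[seq_len(n)]) - depth
  structure(list(phylo = phy, times = times,
                 tip_pop = setNames(pop0, labs)),
            class = "genealogy")
}

#' Sound lower-bound label for migration evidence in a genealogy
#'
#' `TRUE` iff some clade consisting of exactly one A lineage plus one or
#' more B lineages (and nothing else) has its root time strictly inside the
#' migration window `(t_mig_start, t_mig_end)`. Because the window closes
#' before the species split, such a clade cannot form under isolation
#' (m = 0), so the label certifies migration; migrant lineages that
#' coalesce only after the window escape the label, which is why the
#' per-site frequency of `TRUE` labels is a (strict) lower bound on the
#' fraction of migration-affected sequence.
#'
#' @param genealogy A [simulate_genealogy()] result.
#' @param config The [sim_config()] used to generate it.
#' @return Logical.
#' @export
label_migration_lower_bound <- function(genealogy, config) {
  phy <- genealogy$phylo
  ntip <- length(phy$tip.label)
  cs <- clade_sets(phy)
  for (nd in (ntip + 1L):(ntip + phy$Nnode)) {
    tips <- cs[[nd]]
    nA <- sum(startsWith(tips, "a"))
    nB <- sum(startsWith(tips, "b"))
    if (nA == 1L && nB >= 1L && nA + nB == length(tips) &&
        genealogy$times[nd] > config$t_mig_start &&
        genealogy$times[nd] < config$t_mig_end) {
      return(TRUE)
    }
  }
  FALSE
}

# Jukes-Cantor sequence simulation on a genealogy; returns an integer base
# matrix (tips x sites), codes 1..4 = A,C,G,T.
simulate_jc_sequences <- function(phy, nsites, theta) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  seqs <- matrix(0L, nnode, nsites)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, nsites, replace = TRUE)
  ord <- order_nodes_preorder(phy)
  parent_of <- integer(nnode)
  elen <- numeric(nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  elen[phy$edge[, 2]] <- phy$edge.length
  for (nd in ord) {
    if (nd == root) next
    d <- elen[nd] * theta / 2
    p_change <- 0.75 * (1 - exp(-4 * d / 3))
    x <- seqs[parent_of[nd], ]
    mut <- runif(nsites) < p_change
    nm <- sum(mut)
    if (nm > 0) {
      # uniform over the three other bases
      x[mut] <- ((x[mut] - 1L + sample.int(3L, nm, replace = TRUE)) %% 4L) + 1L
    }
    seqs[nd, ] <- x
  }
  out <- seqs[seq_len(ntip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  out
}

#' Simulate one replicate dataset
#'
#' Places recombination breakpoints by a Poisson process (rate `rho` per
#' bp), draws an independent structured-coalescent genealogy per segment,
#' evolves Jukes-Cantor sequences on each genealogy (branch lengths scaled
#' by `theta/2`), and records the per-segment migration lower-bound truth
#' label expanded to a per-site track.
#'
#' @param config A [sim_config()]; its `seed`, when non-`NULL`, is applied
#'   first so identical configurations reproduce bit-identical replicates.
#' @return An object of class `sim_replicate`: `alignment`
#'   ([site_alignment()] with 1-based coordinates), `truth` (per-site
#'   logical), `segments` (data frame: `start`, `end` 0-based half-open,
#'   `label`, `tmrca`, `newick`), `config`.
#' @export
simulate_replicate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- as.integer(config$L)
  nb <- rpois(1, config$rho * L)
  bp <- if (nb > 0 && L > 1) sort(sample.int(L - 1L, min(nb, L - 1L))) else integer(0)
  starts <- c(0L, bp)
  ends <- c(bp, L)
  labs <- names(sim_allele_map(config, include_outgroup = TRUE))
  codes <- matrix(0L, length(labs), L, dimnames = list(labs, NULL))
  truth <- logical(L)
  seg_label <- logical(length(starts))
  seg_newick <- character(length(starts))
  seg_tmrca <- numeric(length(starts))
  for (k in seq_along(starts)) {
    gen <- simulate_genealogy(config)
    lab <- label_migration_lower_bound(gen, config)
    cols <- (starts[k] + 1L):ends[k]
    if (config$theta > 0) {
      sq <- simulate_jc_sequences(gen$phylo, length(cols), config$theta)
      codes[rownames(sq), cols] <- sq
    } else {
      codes[, cols] <- 1L
    }
    truth[cols] <- lab
    seg_label[k] <- lab
    seg_newick[k] <- write_tree(gen$phylo, digits = 10)
    seg_tmrca[k] <- max(gen$times)
  }
  structure(list(
    alignment = site_alignment(codes, labels = labs, pos = seq_len(L)),
    truth = truth,
    segments = data.frame(start = starts, end = ends, label = seg_label,
                          tmrca = seg_tmrca, newick = seg_newick,
                          stringsAsFactors = FALSE),
    config = config
  ), class = "sim_replicate")
}

#' Parental forest matching a simulation configuration
#'
#' Class 1 is the isolation history (A/B split at `t_split_AB`); class 2 is
#' the introgressed history with A/B divergence at the middle of the
#' migration window. With `include_outgroup = TRUE` both parental trees
#' carry the outgroup, which makes deep lineages that escaped introgression
#' topologically separable from shallow introgressed clades (they attach on
#' the outgroup side).
#'
#' @param config A [sim_config()].
#' @param include_outgroup Include the outgroup species/alleles.
#' @return A [parental_forest()] with two classes; class 2 is introgressed.
#' @export
sim_parental_forest <- function(config, include_outgroup = FALSE) {
  tmid <- max((config$t_mig_start + config$t_mig_end) / 2, 1e-3)
  tAB <- config$t_split_AB
  tO <- config$t_split_outgroup
  if (include_outgroup && config$n_out > 0) {
    t1 <- read_tree(sprintf("((A:%.10g,B:%.10g):%.10g,O:%.10g);",
                            tAB, tAB, tO - tAB, tO), "coalescent")
    t2 <- read_tree(sprintf("((A:%.10g,B:%.10g):%.10g,O:%.10g);",
                            tmid, tmid, tO - tmid, tO), "coalescent")
    amap <- sim_allele_map(config, include_outgroup = TRUE)
  } else {
    t1 <- read_tree(sprintf("(A:%.10g,B:%.10g);", tAB, tAB), "coalescent")
    t2 <- read_tree(sprintf("(A:%.10g,B:%.10g);", tmid, tmid), "coalescent")
    amap <- sim_allele_map(config)
  }
  parental_forest(list(t1, t2), amap, introgressed = 2L)
}

# ---- ms interoperability --------------------------------------------------

#' Export replicate segments in ms-style tree lines
#' @param replicate A [simulate_replicate()] result.
#' @return Character vector of `[length](newick);` lines.
#' @export
export_ms_segments <- function(replicate) {
  with(replicate$segments, sprintf("[%d]%s", end - start, newick))
}

#' Read ms-style tree output
#'
#' Parses lines of the form `[length](...);` as produced by coalescent
#' simulators with recombination (and by [export_ms_segments()]).
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @return Data frame with columns `length` and `newick`.
#' @export
read_ms_output <- function(text) {
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- text[grepl("^\\[", text)]
  if (!length(lines)) stop("no ms tree lines (expected '[len](...);')",
                           call. = FALSE)
  out <- lapply(seq_along(lines), function(i) {
    m <- regmatches(lines[i], regexec("^\\[([0-9]+)\\](.*;)\\s*$", lines[i]))[[1]]
    if (length(m) != 3)
      stop("malformed ms tree line ", i, ": ", lines[i], call. = FALSE)
    tr <- tryCatch(ape::read.tree(text = m[3]), error = function(e) NULL)
    if (is.null(tr))
      stop("malformed newick in ms tree line ", i, call. = FALSE)
    data.frame(length = as.integer(m[2]), newick = m[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- sampling data directly from the HMM ---------------------------------

#' Simulate an alignment from a phylo-HMM model
#'
#' Draws a state path from the chain (start distribution + transition
#' matrix) and emits each column by simulating GTR evolution down the
#' state's gene tree. Used for parameter-recovery experiments where the
#' generating HMM is known exactly.
#'
#' @param model A `phmm_model`.
#' @param L Number of sites.
#' @return List with `alignment` ([site_alignment()]) and `path` (true
#'   state indices).
#' @export
simulate_from_model <- function(model, L) {
  Tm <- transition_matrix(model)
  ns <- nrow(Tm)
  path <- integer(L)
  path[1] <- sample.int(ns, 1, prob = model$pi0)
  for (t in seq_len(L)[-1]) {
    path[t] <- sample.int(ns, 1, prob = Tm[path[t - 1], ])
  }
  codes <- matrix(0L, length(model$alleles), L,
                  dimnames = list(model$alleles, NULL))
  for (b in seq_along(model$blocks)) {
    sites <- which(model$states$block[path] == b)
    if (!length(sites)) next
    sq <- simulate_gtr_sequences(model$blocks[[b]]$tree, model$gtr,
                                 length(sites))
    codes[rownames(sq), sites] <- sq   # block trees order tips differently
  }
  list(alignment = site_alignment(codes, labels = model$alleles,
                                  pos = seq_len(L)),
       path = path)
}

simulate_gtr_sequences <- function(phy, gtr, nsites) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  seqs <- matrix(0L, nnode, nsites)
  root <- ntip + 1L
  seqs[root, ] <- sample.int(4L, nsites, replace = TRUE, prob = gtr$freqs)
  parent_of <- integer(nnode); elen <- numeric(nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  elen[phy$edge[, 2]] <- phy$edge.length
  for (nd in order_nodes_preorder(phy)) {
    if (nd == root) next
    P <- gtr_pmat(gtr, elen[nd])
    x <- seqs[parent_of[nd], ]
    out <- integer(nsites)
    for (base in 1:4) {
      idx <- which(x == base)
      if (length(idx))
        out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = pmax(P[base, ], 0))
    }
    seqs[nd, ] <- out
  }
  out <- seqs[seq_len(ntip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  out
}
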