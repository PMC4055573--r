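# End-to-end pipeline: build the model from a parental forest, fit the free
# parameters, decode, and call regions.

#' Scan an alignment for introgression
#'
#' Builds the phylo-HMM for the supplied parental forest, fits its free
#' parameters by coordinate-ascent maximum likelihood, runs posterior
#' decoding and Viterbi, and calls introgressed regions on the per-site
#' introgression-posterior track.
#'
#' @param alignment A [site_alignment()].
#' @param forest A [parental_forest()].
#' @param gtr,hmm Starting substitution-model and transition parameters.
#' @param fit Either a [fit_config()], or `FALSE` to decode with the
#'   supplied parameters without fitting. The `"fast"` preset
#'   (`scan_fit_preset("fast")`) frees the transition parameters and
#'   gene-tree branch lengths only and limits the sweep, which is the
#'   configuration used for replicate-scale validation experiments.
#' @param threshold Posterior threshold for region calling and site
#'   percentages.
#' @param min_sites,merge_gap Region-calling controls (see
#'   [call_regions()]).
#' @param gene_bl_init Initial shared gene-tree branch length.
#' @param init_blocks Seed the branch-length blocks from observed distances
#'   and the parental hypothesis via [init_gene_blocks()] (default TRUE);
#'   set `FALSE` to start all blocks from `gene_bl_init`.
#' @param viterbi Also compute the Viterbi path (can be disabled for large
#'   state spaces where only the posterior track is needed).
#' @param model Optional pre-built `phmm_model` (skips [build_model()],
#'   which lets one model be reused across replicate scans).
#' @return An object of class `phmm_scan`: `model` (fitted), `fit`,
#'   `decoding`, `viterbi`, `track`, `regions`, `summary`.
#' @export
scan_alignment <- function(alignment, forest, gtr = gtr_params(),
                           hmm = hmm_params(), fit = fit_config(),
                           threshold = 0.9, min_sites = 2, merge_gap = 0,
                           gene_bl_init = 0.005, init_blocks = TRUE,
                           viterbi = TRUE, model = NULL) {
  if (is.null(model))
    model <- build_model(forest, gtr, hmm, gene_bl_init = gene_bl_init)
  if (init_blocks) model <- init_gene_blocks(model, alignment)
  fit_res <- NULL
  if (!isFALSE(fit)) {
    fit_res <- fit_model(model, alignment, fit)
    model <- fit_res$model
  }
  dec <- forward_backward(model, alignment)
  vit <- if (viterbi) viterbi_path(model, alignment) else NULL
  regions <- call_regions(dec$introgression_posterior,
                          coordinates = alignment$pos,
                          threshold = threshold, min_sites = min_sites,
                          merge_gap = merge_gap,
                          chrom = alignment$chrom %||% NA_character_)
  structure(list(model = model, fit = fit_res, decoding = dec,
                 viterbi = vit, track = dec$introgression_posterior,
                 regions = regions,
                 summary = summarize_scan(model, dec, vit, regions,
                                          threshold)),
            class = "phmm_scan")
}

#' Preset fit configurations for scans
#'
#' `"full"` optimizes every free parameter group at tight tolerance;
#' `"fast"` optimizes the transition parameters and shared gene-tree
#' branch lengths over a short sweep (two rounds, single start), which is
#' sufficient for replicate-scale simulation experiments where the
#' substitution model is known to be homogeneous.
#'
#' @param preset `"full"` or `"fast"`.
#' @param seed Seed passed to [fit_config()].
#' @return A [fit_config()].
#' @export
scan_fit_preset <- function(preset = c("full", "fast"), seed = 1) {
  preset <- match.arg(preset)
  if (preset == "full") {
    fit_config(seed = seed)
  } else {
    fit_config(tolerance = 1e-3, max_rounds = 2, restarts = 1, seed = seed,
               free = c("hmm", "gene_bl"), brent_rel_tol = 1e-3)
  }
}

#' @export
print.phmm_scan <- function(x, ...) {
  print(x$model)
  if (!is.null(x$fit))
    cat("fitted log-likelihood:", format(x$fit$log_likelihood, digits = 10),
        "\n")
  print(x$summary)
  invisible(x)
}

#' Write all scan outputs to a directory
#'
#' Per-site posterior TSV, regions BED, Viterbi path TSV, missing-data mask
#' BED, summary text and the fitted model JSON.
#'
#' @param scan A `phmm_scan`.
#' @param alignment The scanned [site_alignment()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scan_outputs <- function(scan, alignment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_posterior_tsv(scan$decoding, scan$model,
                      file.path(dir, "posterior.tsv"), pos = alignment$pos)
  write_bed(scan$regions, file.path(dir, "regions.bed"))
  utils::write.table(
    data.frame(pos = alignment$pos %||% seq_len(alignment$L),
               state = scan$viterbi$labels,
               introgressed = scan$viterbi$introgressed),
    file.path(dir, "viterbi.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_bed(missing_data_mask(alignment), file.path(dir, "mask.bed"))
  save_model(scan$model, file.path(dir, "model.json"))
  s <- scan$summary
  writeLines(c(
    sprintf("percent_sites_posterior\t%.6f", s$percent_sites_posterior),
    sprintf("percent_sites_viterbi\t%.6f", s$percent_sites_viterbi),
    sprintf("gamma_readback\t%.8g", s$gamma_readback),
    sprintf("threshold\t%g", s$threshold),
    sprintf("n_regions\t%d", nrow(scan$regions))
  ), file.path(dir, "summary.txt"))
  invisible(dir)
}
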