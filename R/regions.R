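# Turning decodings into genome annotation: thresholded region calls on the
# introgression-posterior track, merging/filtering, and scan summaries
# (posterior-rule and Viterbi-rule site percentages, gamma read-back).

#' Call introgressed regions from a posterior track
#'
#' Maximal runs of sites with posterior > `threshold`; runs separated by at
#' most `merge_gap` below-threshold sites are merged, then runs with fewer
#' than `min_sites` qualifying sites are dropped. Coordinates are 0-based
#' half-open in site index space, or genomic bp when `coordinates` are
#' supplied (regions then span first to last qualifying site).
#'
#' @param track Numeric vector of per-site introgression posteriors.
#' @param coordinates Optional per-site genomic positions (1-based,
#'   strictly increasing).
#' @param threshold Posterior threshold in (0,1); default 0.9.
#' @param min_sites Minimum qualifying sites per region.
#' @param merge_gap Maximum run gap (in sites) to merge across.
#' @param chrom Optional chromosome label copied into the output.
#' @return Data frame of regions: `chrom`, `start`, `end`, `n_sites`,
#'   `mean_posterior`, `min_posterior` (over qualifying sites).
#' @export
call_regions <- function(track, coordinates = NULL, threshold = 0.9,
                         min_sites = 2, merge_gap = 0, chrom = NA_character_) {
  stopifnot(threshold > 0, threshold < 1)
  if (!is.null(coordinates) && length(coordinates) != length(track))
    stop("coordinates must match track length", call. = FALSE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      mean_posterior = numeric(), min_posterior = numeric(),
                      stringsAsFactors = FALSE)
  above <- track > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by small gaps
  if (nrow(runs) > 1 && merge_gap > 0) {
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs$start[i] - last$end - 1L <= merge_gap) {
        last$end <- runs$end[i]
        keep[[length(keep)]] <- last
      } else {
        keep[[length(keep) + 1L]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, keep)
  }
  out <- lapply(seq_len(nrow(runs)), function(i) {
    sites <- runs$start[i]:runs$end[i]
    qual <- sites[above[sites]]
    if (length(qual) < min_sites) return(NULL)
    if (is.null(coordinates)) {
      start0 <- runs$start[i] - 1L
      end0 <- runs$end[i]
    } else {
      start0 <- coordinates[runs$start[i]] - 1L
      end0 <- coordinates[runs$end[i]]
    }
    data.frame(chrom = chrom, start = start0, end = end0,
               n_sites = length(qual),
               mean_posterior = mean(track[qual]),
               min_posterior = min(track[qual]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Summarize a scan
#'
#' Reports the percentage of sites called introgressed under the posterior
#' rule (Eq.-2-style track > threshold) and under the Viterbi rule (optimal
#' path in an introgressed-class state), the gamma value read back from the
#' fitted transition matrix (the summed cross-class mass of any
#' non-introgressed row, averaged over rows -- an algebraic identity equal
#' to the model's gamma under this parameterization), and the per-topology
#' posterior mass.
#'
#' @param model A fitted `phmm_model`.
#' @param decoding A `phmm_decoding` from [forward_backward()].
#' @param viterbi A [viterbi_path()] result (optional).
#' @param regions A [call_regions()] data frame (optional).
#' @param threshold Posterior threshold for the site percentage.
#' @return An object of class `scan_summary`.
#' @export
summarize_scan <- function(model, decoding, viterbi = NULL, regions = NULL,
                           threshold = 0.9) {
  track <- decoding$introgression_posterior
  pct_post <- 100 * mean(track > threshold)
  pct_vit <- if (!is.null(viterbi)) 100 * mean(viterbi$introgressed) else NA_real_
  Tm <- transition_matrix(model)
  e_rows <- which(!model$states$introgressed)
  f_cols <- which(model$states$introgressed)
  gamma_rb <- if (length(f_cols))
    mean(rowSums(Tm[e_rows, f_cols, drop = FALSE])) else 0
  L <- length(track)
  topo_mass <- vapply(seq_len(model$n_topologies), function(g)
    sum(decoding$state_mass[model$states$topology == g]) / L, 0)
  names(topo_mass) <- model$topo_canon
  structure(list(
    percent_sites_posterior = pct_post,
    percent_sites_viterbi = pct_vit,
    gamma_readback = gamma_rb,
    gamma_model = model$hmm$gamma,
    threshold = threshold,
    topology_posterior_mass = topo_mass,
    n_regions = if (is.null(regions)) NA_integer_ else nrow(regions),
    regions = regions
  ), class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("introgressed sites: %.2f%% (posterior > %.2g), %s%% (Viterbi)\n",
              x$percent_sites_posterior, x$threshold,
              ifelse(is.na(x$percent_sites_viterbi), "NA",
                     sprintf("%.2f", x$percent_sites_viterbi))))
  cat(sprintf("gamma: fitted %.4g, transition-matrix read-back %.4g\n",
              x$gamma_model, x$gamma_readback))
  if (!is.na(x$n_regions)) cat("called regions:", x$n_regions, "\n")
  invisible(x)
}

#' Missing-data mask regions
#'
#' Maximal stretches where every model allele is missing/ambiguous, at or
#' above a minimum length; reported separately rather than interpolated.
#'
#' @param alignment A [site_alignment()].
#' @param min_length Minimum stretch length in sites.
#' @return Data frame `chrom`, `start`, `end` (0-based half-open).
#' @export
missing_data_mask <- function(alignment, min_length = 100) {
  allN <- apply(alignment$codes, 2, function(col)
    all(CODE_LEVELS[col] %in% c("N", "-", "?")))
  r <- rle(allN)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values & r$lengths >= min_length
  data.frame(chrom = rep(alignment$chrom %||% NA_character_, sum(sel)),
             start = starts[sel] - 1L, end = ends[sel],
             stringsAsFactors = FALSE)
}
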