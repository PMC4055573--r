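# Replicate-scale validation experiment: simulate isolation-with-migration
# replicates across migration settings, run the full pipeline on each
# (block initialization, transition-parameter fitting, posterior decoding),
# and compare the inferred percentage of introgressed sites with the
# per-replicate migration lower bound from the simulation truth track.

#' GTR-frequency recovery experiment
#'
#' Simulates replicates under the isolation-with-migration generator (whose
#' sequence evolution is Jukes-Cantor, i.e. equal true base frequencies and
#' exchangeabilities), fits the four-allele two-class model including the
#' GTR block, and returns the fitted stationary frequencies per replicate.
#'
#' @param replicates Number of replicates.
#' @param L Sequence length per replicate.
#' @param seed Master seed (replicate seeds derive from it).
#' @param m Migration rate used for the simulated data.
#' @return Matrix (replicates x 4) of fitted base frequencies, with the
#'   fitted exchangeabilities in attribute `rates`.
#' @export
gtr_recovery_experiment <- function(replicates = 5, L = 100000L, seed = 1,
                                    m = 0.5) {
  cfg0 <- sim_config(m = m, L = L)
  forest <- sim_parental_forest(cfg0)   # four in-group alleles, 31 states
  base_model <- build_model(forest)
  freqs <- matrix(NA_real_, replicates, 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  rates <- matrix(NA_real_, replicates, 6,
                  dimnames = list(NULL, RATE_NAMES))
  for (r in seq_len(replicates)) {
    cfg <- sim_config(m = m, L = L, seed = seed + 17L * r)
    rep <- simulate_replicate(cfg)
    model <- init_gene_blocks(base_model, rep$alignment)
    fitcfg <- fit_config(tolerance = 1e-3, max_rounds = 2, restarts = 1,
                         seed = seed + r,
                         free = c("hmm", "gtr_freq", "gtr_rates", "gene_bl"),
                         brent_rel_tol = 1e-3)
    ft <- fit_model(model, rep$alignment, fitcfg)
    freqs[r, ] <- ft$model$gtr$freqs
    rates[r, ] <- ft$model$gtr$rates
  }
  attr(freqs, "rates") <- rates
  freqs
}

#' Transition-parameter recovery experiment
#'
#' Generates alignments directly from a known 7-state model (three species,
#' two parental classes, distinct branch lengths per rooted genealogy) and
#' refits gamma, s1, s2 and the branch-length blocks from each, recording
#' the recovered transition parameters and the spread of restart final
#' log-likelihoods.
#'
#' @param truth A generating `phmm_model`.
#' @param replicates Number of replicates.
#' @param L Sites per replicate.
#' @param seed Master seed.
#' @param restarts Restarts per fit.
#' @return Data frame per replicate: `gamma_hat`, `s1_hat`, `s2_hat`,
#'   `ll_spread` (best minus worst restart final log-likelihood),
#'   `n_restarts_close` (restarts within 0.1 of the best).
#' @export
parameter_recovery_experiment <- function(truth, replicates = 20, L = 10000L,
                                          seed = 1, restarts = 3) {
  out <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + 31L * r)
    sim <- simulate_from_model(truth, L)
    # generic start: neutral transition parameters, distance-seeded blocks
    start <- build_model(truth$forest, truth$gtr, hmm_params(0.2, 0.3, 0.3))
    start <- init_gene_blocks(start, sim$alignment)
    fitcfg <- fit_config(tolerance = 1e-4, max_rounds = 16,
                         restarts = restarts, seed = seed + r,
                         free = c("hmm", "gene_bl"), brent_rel_tol = 1e-4)
    ft <- fit_model(start, sim$alignment, fitcfg)
    out[[r]] <- data.frame(
      gamma_hat = ft$model$hmm$gamma,
      s1_hat = ft$model$hmm$s1,
      s2_hat = ft$model$hmm$s2,
      ll_spread = max(ft$restart_logliks) - min(ft$restart_logliks),
      n_restarts_close = sum(ft$restart_logliks >=
                               max(ft$restart_logliks) - 0.1))
  }
  do.call(rbind, out)
}

#' Run the migration validation experiment
#'
#' For each migration rate, simulates `replicates` datasets, scans each with
#' the two-class model (outgroup included, so escape-from-introgression
#' lineages are topologically separable), and records the percentage of
#' sites with introgression posterior above `threshold` alongside the
#' truth-track lower-bound percentage and the number of called regions.
#'
#' @param m_values Migration rates to simulate (0 = isolation control).
#' @param replicates Replicates per rate.
#' @param L Sequence length per replicate (bp).
#' @param seed Master seed; replicate seeds derive from it.
#' @param t_mig_start,t_mig_end Migration window (coalescent units).
#' @param threshold Posterior threshold for calling a site introgressed.
#' @param fit_seed Seed for the per-replicate fits.
#' @param progress Print one line per replicate.
#' @return Data frame with one row per replicate: `m`, `replicate`,
#'   `truth_pct`, `inferred_pct`, `n_regions`, `gamma_hat`.
#' @export
migration_experiment <- function(m_values = c(0, 0.5, 5), replicates = 20,
                                 L = 100000L, seed = 1,
                                 t_mig_start = 0, t_mig_end = 0.5,
                                 threshold = 0.9, fit_seed = 1,
                                 progress = FALSE) {
  out <- list()
  for (mi in seq_along(m_values)) {
    m <- m_values[mi]
    cfg0 <- sim_config(m = m, L = L, t_mig_start = t_mig_start,
                       t_mig_end = t_mig_end)
    forest <- sim_parental_forest(cfg0, include_outgroup = TRUE)
    base_model <- build_model(forest)
    for (r in seq_len(replicates)) {
      cfg <- sim_config(m = m, L = L, t_mig_start = t_mig_start,
                        t_mig_end = t_mig_end,
                        seed = seed + 1000L * mi + r)
      rep <- simulate_replicate(cfg)
      # transition parameters only, two sweeps: emissions come from the
      # distance-based block initialization, which keeps the 211-state
      # replicate fits tractable
      fitcfg <- fit_config(tolerance = 1e-3, max_rounds = 2, restarts = 1,
                           seed = fit_seed, free = "hmm",
                           brent_rel_tol = 1e-3)
      sc <- scan_alignment(rep$alignment, forest, model = base_model,
                           fit = fitcfg, threshold = threshold,
                           viterbi = FALSE)
      row <- data.frame(m = m, replicate = r,
                        truth_pct = 100 * mean(rep$truth),
                        inferred_pct = sc$summary$percent_sites_posterior,
                        n_regions = nrow(sc$regions),
                        gamma_hat = sc$model$hmm$gamma)
      if (progress)
        message(sprintf("m=%g rep=%d truth=%.2f inferred=%.2f regions=%d",
                        m, r, row$truth_pct, row$inferred_pct, row$n_regions))
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
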