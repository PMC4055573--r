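# Decoding: forward/backward posterior decoding, Viterbi paths and the
# per-site introgression posterior (the summed posterior mass of every state
# whose parental class is flagged introgressed).

prepare_emissions <- function(model, alignment) {
  ap <- alignment_patterns(model, alignment)
  et <- emission_tables(model, ap$patterns)
  logEmax <- apply(et$logE, 2, max)
  E <- exp(sweep(et$logE, 2, logEmax, "-"))
  list(patterns = ap$patterns, index = ap$index, logE = et$logE,
       E = E, logEmax = logEmax)
}

#' Forward-backward posterior decoding
#'
#' Runs the scaled forward and backward recursions and returns the total
#' log-likelihood, the per-site state posterior matrix, and the per-site
#' introgression posterior (summed posterior over introgressed-class
#' states).
#'
#' @param model A `phmm_model`.
#' @param alignment A [site_alignment()] containing every model allele.
#' @param full Return the full sites-x-states posterior matrix. Defaults to
#'   `TRUE` for small problems; for large state spaces x long alignments the
#'   matrix is skipped and only the per-site introgression track and the
#'   per-state total posterior mass are kept (a fused forward-backward pass
#'   that never materializes the matrix).
#' @return An object of class `phmm_decoding` with elements `log_likelihood`,
#'   `log_likelihood_backward`, `posterior` (sites x states, or `NULL` when
#'   `full = FALSE`), `state_mass` (summed posterior per state) and
#'   `introgression_posterior`.
#' @export
forward_backward <- function(model, alignment,
                             full = nrow(model$states) * alignment$L <= 2e7) {
  em <- prepare_emissions(model, alignment)
  ts <- transition_struct(model)
  if (!full) {
    fu <- hmm_posterior_track_cpp(model$pi0, ts$cls, ts$ptil, ts$svec, ts$D,
                                  ts$gamma, ts$gammap, ts$K, em$E,
                                  em$logEmax, em$index - 1L,
                                  model$states$introgressed)
    return(structure(list(
      log_likelihood = fu$loglik,
      log_likelihood_backward = fu$loglik_backward,
      posterior = NULL,
      state_mass = setNames(fu$state_mass, model$states$label),
      introgression_posterior = fu$track
    ), class = "phmm_decoding"))
  }
  fw <- hmm_forward_cpp(model$pi0, ts$cls, ts$ptil, ts$svec, ts$D,
                        ts$gamma, ts$gammap, ts$K, em$E, em$logEmax,
                        em$index - 1L, TRUE)
  bw <- hmm_backward_cpp(model$pi0, ts$cls, ts$ptil, ts$svec, ts$D,
                         ts$gamma, ts$gammap, ts$K, em$E, em$logEmax,
                         em$index - 1L, TRUE)
  post <- t(fw$alpha * bw$beta)
  post <- post / rowSums(post)
  colnames(post) <- model$states$label
  res <- structure(list(
    log_likelihood = fw$loglik,
    log_likelihood_backward = bw$loglik,
    posterior = post,
    state_mass = colSums(post)
  ), class = "phmm_decoding")
  res$introgression_posterior <- introgression_posterior(res, model)
  res
}

#' Model log-likelihood of an alignment (forward algorithm only)
#' @inheritParams forward_backward
#' @return The total log-likelihood.
#' @export
model_log_likelihood <- function(model, alignment) {
  em <- prepare_emissions(model, alignment)
  ts <- transition_struct(model)
  hmm_forward_cpp(model$pi0, ts$cls, ts$ptil, ts$svec, ts$D, ts$gamma,
                  ts$gammap, ts$K, em$E, em$logEmax, em$index - 1L,
                  FALSE)$loglik
}

#' Viterbi-optimal state path
#'
#' @inheritParams forward_backward
#' @return A list with `path` (per-site state index into `model$states`),
#'   `labels` (state labels along the path), `introgressed` (logical track)
#'   and `log_joint` (the path's joint log-probability). Ties are broken
#'   toward the lowest state index.
#' @export
viterbi_path <- function(model, alignment) {
  em <- prepare_emissions(model, alignment)
  logT <- log(transition_matrix(model))
  vt <- hmm_viterbi_cpp(log(model$pi0), logT, em$logE, em$index - 1L)
  list(path = vt$path,
       labels = model$states$label[vt$path],
       introgressed = model$states$introgressed[vt$path],
       log_joint = vt$logprob)
}

#' Per-site introgression posterior
#'
#' Sums the posterior-state probabilities over every state whose parental
#' class is in the forest's introgressed set; this is the per-column
#' probability that the site lies in a region of introgressive descent.
#'
#' @param decoding A `phmm_decoding` from [forward_backward()].
#' @param model The `phmm_model` used to produce it.
#' @return Numeric vector in [0,1], one value per site.
#' @export
introgression_posterior <- function(decoding, model) {
  if (is.null(decoding$posterior)) return(decoding$introgression_posterior)
  idx <- which(model$states$introgressed)
  if (!length(idx)) return(rep(0, nrow(decoding$posterior)))
  rowSums(decoding$posterior[, idx, drop = FALSE])
}
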