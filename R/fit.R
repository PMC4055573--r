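# Maximum-likelihood training: every free scalar (transition parameters,
# GTR frequencies via stick-breaking, GTR exchangeabilities, shared gene-tree
# branch-length blocks, parental-tree branch lengths) is swept in a fixed
# order, each optimized on its profile log-likelihood with Brent's method
# (stats::optimize) over its bound interval. Coalescent topology-probability
# tables are recomputed whenever a parental branch length moves; they are
# never free parameters themselves.

PARAM_GROUPS <- c("hmm", "gtr_freq", "gtr_rates", "gene_bl", "parental_bl")

param_bounds <- list(
  hmm = c(1e-6, 1 - 1e-6),
  gtr_freq = c(1e-6, 1 - 1e-6),
  gtr_rates = c(1e-3, 100),
  gene_bl = c(1e-6, 10),
  parental_bl = c(1e-3, 50)
)

# Stick-breaking view of the frequency simplex (3 free scalars in (0,1)).
freqs_to_sticks <- function(p) {
  v1 <- p[1]
  v2 <- p[2] / (1 - p[1])
  v3 <- p[3] / (1 - p[1] - p[2])
  c(v1, v2, v3)
}
sticks_to_freqs <- function(v) {
  a <- v[1]
  c_ <- (1 - a) * v[2]
  g <- (1 - a - c_) * v[3]
  p <- c(a, c_, g, 1 - a - c_ - g)
  pmax(p, 1e-9) / sum(pmax(p, 1e-9))
}

#' Table of free parameters for a model
#'
#' @param model A `phmm_model`.
#' @param free Character vector of parameter groups to include, from
#'   `"hmm"` (gamma, s1, s2), `"gtr_freq"`, `"gtr_rates"`, `"gene_bl"`
#'   (shared gene-tree branch-length blocks) and `"parental_bl"`.
#' @return Data frame with columns `name`, `group`, `lower`, `upper`,
#'   `value`, in the fixed sweep order used by [fit_model()].
#' @export
param_table <- function(model, free = PARAM_GROUPS) {
  free <- match.arg(free, PARAM_GROUPS, several.ok = TRUE)
  rows <- list()
  add <- function(name, group, value) {
    b <- param_bounds[[group]]
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, group = group, lower = b[1], upper = b[2], value = value)
  }
  if ("hmm" %in% free) {
    add("gamma", "hmm", model$hmm$gamma)
    add("s1", "hmm", model$hmm$s1)
    add("s2", "hmm", model$hmm$s2)
  }
  if ("gtr_freq" %in% free) {
    v <- freqs_to_sticks(model$gtr$freqs)
    for (k in 1:3) add(paste0("freq_v", k), "gtr_freq", v[k])
  }
  if ("gtr_rates" %in% free) {
    for (r in RATE_NAMES[-6]) # GT is the fixed reference rate
      add(paste0("exch_", r), "gtr_rates", model$gtr$rates[[r]])
  }
  if ("gene_bl" %in% free) {
    for (k in seq_along(model$blocks)) {
      fe <- model$blocks[[k]]$free_edges
      for (j in seq_along(fe))
        add(paste0("gbl", k, "_e", j), "gene_bl",
            model$blocks[[k]]$tree$edge.length[fe[j]])
    }
  }
  if ("parental_bl" %in% free) {
    for (c in seq_len(model$n_classes)) {
      ne <- nrow(model$forest$trees[[c]]$edge)
      for (j in seq_len(ne))
        add(paste0("pbl", c, "_e", j), "parental_bl",
            model$forest$trees[[c]]$edge.length[j])
    }
  }
  do.call(rbind, rows)
}

# Apply one scalar to a model. Returns the updated model plus which caches
# the change invalidates: "trans" (transition structure), "emis_all",
# "emis_block" (with the block index), or "topo" (class topology table,
# which also implies "trans").
apply_param <- function(model, name, value) {
  if (name %in% c("gamma", "s1", "s2")) {
    model$hmm[[name]] <- value
    return(list(model = model, effect = "trans"))
  }
  if (grepl("^freq_v", name)) {
    v <- freqs_to_sticks(model$gtr$freqs)
    v[as.integer(sub("freq_v", "", name))] <- value
    model$gtr <- gtr_params(sticks_to_freqs(v), model$gtr$rates)
    return(list(model = model, effect = "emis_all"))
  }
  if (grepl("^exch_", name)) {
    r <- model$gtr$rates
    r[[sub("exch_", "", name)]] <- value
    model$gtr <- gtr_params(model$gtr$freqs, r)
    return(list(model = model, effect = "emis_all"))
  }
  if (grepl("^gbl", name)) {
    m <- regmatches(name, regexec("^gbl([0-9]+)_e([0-9]+)$", name))[[1]]
    k <- as.integer(m[2]); j <- as.integer(m[3])
    fe <- model$blocks[[k]]$free_edges
    model$blocks[[k]]$tree$edge.length[fe[j]] <- value
    return(list(model = model, effect = "emis_block", block = k))
  }
  if (grepl("^pbl", name)) {
    m <- regmatches(name, regexec("^pbl([0-9]+)_e([0-9]+)$", name))[[1]]
    c <- as.integer(m[2]); j <- as.integer(m[3])
    model$forest$trees[[c]]$edge.length[j] <- value
    model <- refresh_topology_probabilities(model, c)
    return(list(model = model, effect = "topo"))
  }
  stop("unknown parameter name: ", name, call. = FALSE)
}

refresh_topology_probabilities <- function(model, classes = seq_len(model$n_classes)) {
  for (c in classes) {
    tab <- topology_probability_table(model$forest$trees[[c]],
                                      model$forest$allele_map,
                                      model$topologies)
    model$P[c, ] <- tab$probability
  }
  model$Ptilde <- model$P / rowSums(model$P)
  model$pi0 <- start_distribution(model)
  model
}

#' Pack a model's free parameters into a bounded scalar vector
#'
#' @inheritParams param_table
#' @return Named numeric vector with attributes `lower`, `upper`, `group`.
#' @export
pack_parameters <- function(model, free = PARAM_GROUPS) {
  pt <- param_table(model, free)
  structure(setNames(pt$value, pt$name),
            lower = setNames(pt$lower, pt$name),
            upper = setNames(pt$upper, pt$name),
            group = setNames(pt$group, pt$name))
}

#' Write a packed parameter vector back into a model
#'
#' Out-of-bounds scalars are clamped to their bounds with a warning.
#' Topology-probability tables and the cached transition structure are
#' recomputed as needed.
#'
#' @param params Named vector as produced by [pack_parameters()].
#' @param model A `phmm_model`.
#' @return The updated model.
#' @export
unpack_parameters <- function(params, model) {
  pt <- param_table(model)
  pt <- pt[pt$name %in% names(params), , drop = FALSE]
  touched_topo <- FALSE
  for (i in seq_len(nrow(pt))) {
    nm <- pt$name[i]
    v <- params[[nm]]
    if (v < pt$lower[i] || v > pt$upper[i]) {
      warning("parameter ", nm, " = ", v, " clamped to [",
              pt$lower[i], ", ", pt$upper[i], "]")
      v <- min(max(v, pt$lower[i]), pt$upper[i])
    }
    if (grepl("^pbl", nm)) {
      # defer the expensive table refresh until all scalars are applied
      m <- regmatches(nm, regexec("^pbl([0-9]+)_e([0-9]+)$", nm))[[1]]
      model$forest$trees[[as.integer(m[2])]]$edge.length[as.integer(m[3])] <- v
      touched_topo <- TRUE
    } else {
      model <- apply_param(model, nm, v)$model
    }
  }
  if (touched_topo) model <- refresh_topology_probabilities(model)
  model
}

# Cached-likelihood environment used by the coordinate-ascent sweep: only
# the structures invalidated by the moved scalar are recomputed.
make_objective_env <- function(model, alignment) {
  env <- new.env(parent = emptyenv())
  env$model <- model
  ap <- alignment_patterns(model, alignment)
  env$patterns <- ap$patterns
  env$index0 <- ap$index - 1L
  env$logEb <- emission_tables(model, ap$patterns)$logE_block  # nblock x P
  env$loglik <- function() {
    logE <- env$logEb[env$model$states$block, , drop = FALSE]
    logEmax <- apply(logE, 2, max)
    E <- exp(sweep(logE, 2, logEmax, "-"))
    ts <- transition_struct(env$model)
    hmm_forward_cpp(env$model$pi0, ts$cls, ts$ptil, ts$svec, ts$D,
                    ts$gamma, ts$gammap, ts$K, E, logEmax, env$index0,
                    FALSE)$loglik
  }
  env$set <- function(name, value) {
    ch <- apply_param(env$model, name, value)
    env$model <- ch$model
    if (ch$effect == "emis_all") {
      env$logEb <- emission_tables(env$model, env$patterns)$logE_block
    } else if (ch$effect == "emis_block") {
      env$logEb[ch$block, ] <- tree_pattern_loglik(
        env$model$blocks[[ch$block]]$tree, env$model$gtr, env$patterns)
    }
    invisible(NULL)
  }
  env$eval <- function(name, value) {
    env$set(name, value)
    env$loglik()
  }
  env
}

#' Profile log-likelihood in one free scalar
#'
#' Evaluates the model log-likelihood with a single named parameter moved to
#' `value` and all other parameters fixed; this is the inner objective that
#' Brent's method optimizes during [fit_model()].
#'
#' @param model A `phmm_model`.
#' @param alignment A [site_alignment()].
#' @param name Parameter name (see [param_table()]).
#' @param value Scalar value within the parameter's bounds.
#' @return The log-likelihood.
#' @export
profile_objective <- function(model, alignment, name, value) {
  env <- make_objective_env(model, alignment)
  env$eval(name, value)
}

#' Training configuration
#'
#' @param tolerance Convergence tolerance on the per-round log-likelihood
#'   improvement (log-units).
#' @param max_rounds Maximum coordinate-ascent sweeps.
#' @param restarts Number of optimization starts; the first uses the
#'   supplied model's parameters, later ones draw uniformly within bounds.
#' @param seed Seed controlling restart draws.
#' @param free Parameter groups to optimize (see [param_table()]).
#' @param brent_rel_tol Relative tolerance of each univariate Brent search.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(tolerance = 1e-6, max_rounds = 100, restarts = 3,
                       seed = 1, free = PARAM_GROUPS,
                       brent_rel_tol = 1e-6) {
  stopifnot(tolerance > 0, max_rounds >= 1, restarts >= 1)
  structure(list(tolerance = tolerance, max_rounds = max_rounds,
                 restarts = restarts, seed = seed,
                 free = match.arg(free, PARAM_GROUPS, several.ok = TRUE),
                 brent_rel_tol = brent_rel_tol),
            class = "fit_config")
}

#' Fit a phylo-HMM model by maximum likelihood
#'
#' Coordinate-ascent hill climbing: each round sweeps every free scalar in a
#' fixed order (gamma, s1, s2; GTR frequencies; GTR exchangeabilities;
#' gene-tree branch-length blocks; parental branch lengths), optimizing each
#' on its profile log-likelihood with Brent's method over the scalar's bound
#' interval. The best final likelihood over restarts wins.
#'
#' @param model A `phmm_model` (its current parameters seed restart 1).
#' @param alignment A [site_alignment()].
#' @param config A [fit_config()].
#' @return An object of class `phmm_fit`: `model` (refitted),
#'   `log_likelihood`, `trace` (per-round log-likelihood of the winning
#'   restart), `rounds`, `converged`, `flat_profile` (all-missing-data
#'   guard), `params`, `restart_logliks`, `config`.
#' @export
fit_model <- function(model, alignment, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  if (alignment$L < 1) stop("alignment is empty", call. = FALSE)
  pt <- param_table(model, config$free)
  set.seed(config$seed)
  best <- NULL
  restart_ll <- numeric(0)
  # restarts redraw the probability-scale parameters uniformly over their
  # bounds; branch lengths keep their (data-seeded) starting values, since
  # uniform draws on a [1e-6, 10] substitution scale are not meaningful
  # starting points and defeat the purpose of multi-start robustness
  redraw <- pt$group %in% c("hmm", "gtr_freq", "gtr_rates")
  for (r in seq_len(config$restarts)) {
    m0 <- model
    if (r > 1 && any(redraw)) {
      for (attempt in 1:10) {
        draw <- runif(sum(redraw), pt$lower[redraw], pt$upper[redraw])
        m_try <- unpack_parameters(setNames(draw, pt$name[redraw]), model)
        env <- make_objective_env(m_try, alignment)
        if (is.finite(env$loglik())) { m0 <- m_try; break }
        if (attempt == 10)
          stop("non-finite objective after 10 restart draws", call. = FALSE)
      }
    }
    res <- ascend(m0, alignment, pt, config)
    restart_ll <- c(restart_ll, res$log_likelihood)
    if (is.null(best) || res$log_likelihood > best$log_likelihood) best <- res
  }
  best$restart_logliks <- restart_ll
  best$config <- config
  best$params <- pack_parameters(best$model, config$free)
  class(best) <- "phmm_fit"
  best
}

ascend <- function(model, alignment, pt, config) {
  env <- make_objective_env(model, alignment)
  ll <- env$loglik()
  if (!is.finite(ll)) stop("non-finite objective at the starting point",
                           call. = FALSE)
  trace <- ll
  converged <- FALSE
  any_movement <- FALSE
  for (round in seq_len(config$max_rounds)) {
    ll_start <- ll
    for (i in seq_len(nrow(pt))) {
      nm <- pt$name[i]
      cur <- current_value(env$model, nm)
      lo <- pt$lower[i]; hi <- pt$upper[i]
      f <- function(v) env$eval(nm, v)
      opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                             tol = config$brent_rel_tol * (hi - lo))
      cand <- env$eval(nm, opt$maximum)
      if (abs(cand - ll) > 1e-9) any_movement <- TRUE
      if (cand > ll) {
        ll <- cand
      } else {
        env$set(nm, cur)   # revert: Brent did not beat the current point
      }
    }
    trace <- c(trace, ll)
    if (round == 1 && !any_movement) {
      warning("flat likelihood profile in every parameter ",
              "(no informative sites?); parameters left at their ",
              "starting values")
      return(list(model = env$model, log_likelihood = ll, trace = trace,
                  rounds = round, converged = TRUE, flat_profile = TRUE))
    }
    if (ll - ll_start < config$tolerance) { converged <- TRUE; break }
  }
  list(model = env$model, log_likelihood = ll, trace = trace,
       rounds = length(trace) - 1L, converged = converged,
       flat_profile = FALSE)
}

current_value <- function(model, name) {
  if (name %in% c("gamma", "s1", "s2")) return(model$hmm[[name]])
  if (grepl("^freq_v", name))
    return(freqs_to_sticks(model$gtr$freqs)[as.integer(sub("freq_v", "", name))])
  if (grepl("^exch_", name)) return(model$gtr$rates[[sub("exch_", "", name)]])
  if (grepl("^gbl", name)) {
    m <- regmatches(name, regexec("^gbl([0-9]+)_e([0-9]+)$", name))[[1]]
    k <- as.integer(m[2])
    return(model$blocks[[k]]$tree$edge.length[model$blocks[[k]]$free_edges[as.integer(m[3])]])
  }
  if (grepl("^pbl", name)) {
    m <- regmatches(name, regexec("^pbl([0-9]+)_e([0-9]+)$", name))[[1]]
    return(model$forest$trees[[as.integer(m[2])]]$edge.length[as.integer(m[3])])
  }
  stop("unknown parameter name: ", name, call. = FALSE)
}

#' Read a training configuration from a JSON file
#'
#' Recognized fields are the arguments of [fit_config()]; absent fields
#' keep their defaults.
#'
#' @param path Path to a JSON file.
#' @return A [fit_config()].
#' @export
read_fit_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- obj[intersect(names(obj), names(formals(fit_config)))]
  do.call(fit_config, args)
}

#' Write a fit report
#'
#' Writes `<prefix>.report.txt` (final log-likelihood, rounds, convergence,
#' restart log-likelihoods, fitted parameters) and `<prefix>.trace.tsv`
#' (per-round log-likelihood trace of the winning restart).
#'
#' @param fit A `phmm_fit` from [fit_model()].
#' @param prefix Output path prefix.
#' @export
write_fit_report <- function(fit, prefix) {
  stopifnot(inherits(fit, "phmm_fit"))
  lines <- c(
    sprintf("log_likelihood\t%.10f", fit$log_likelihood),
    sprintf("rounds\t%d", fit$rounds),
    sprintf("converged\t%s", fit$converged),
    sprintf("flat_profile\t%s", isTRUE(fit$flat_profile)),
    sprintf("restart_logliks\t%s",
            paste(sprintf("%.10f", fit$restart_logliks), collapse = ",")),
    sprintf("tolerance\t%g", fit$config$tolerance),
    sprintf("seed\t%s", fit$config$seed),
    sprintf("free\t%s", paste(fit$config$free, collapse = ",")),
    sprintf("%s\t%.10g", names(fit$params), fit$params))
  writeLines(lines, paste0(prefix, ".report.txt"))
  utils::write.table(
    data.frame(round = seq_along(fit$trace) - 1L, log_likelihood = fit$trace),
    paste0(prefix, ".trace.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(prefix)
}

#' @export
print.phmm_fit <- function(x, ...) {
  cat("phylo-HMM fit: log-likelihood", format(x$log_likelihood, digits = 10),
      "after", x$rounds, "round(s);",
      if (x$converged) "converged" else "round limit reached", "\n")
  cat("  gamma =", signif(x$model$hmm$gamma, 4),
      " s1 =", signif(x$model$hmm$s1, 4),
      " s2 =", signif(x$model$hmm$s2, 4), "\n")
  cat("  restarts:", paste(signif(x$restart_logliks, 8), collapse = ", "), "\n")
  invisible(x)
}
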