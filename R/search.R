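#' Hyperparameter search space
#'
#' The default space mirrors the tuned search: batch size in {8, 16, 32},
#' dropout uniform on [0.2, 0.5], L2 coefficient log-uniform on
#' [1e-4, 1e-2], learning rate log-uniform on [1e-5, 1e-3], 20 trials.
#'
#' @param batch_size categorical values for the batch size.
#' @param dropout uniform bounds `c(lo, hi)`.
#' @param l2_coeff log-uniform bounds `c(lo, hi)`.
#' @param learning_rate log-uniform bounds `c(lo, hi)`.
#' @param n_trials number of optimization trials.
#' @return an object of class `search_space`.
#' @export
search_space <- function(batch_size = c(8L, 16L, 32L),
                         dropout = c(0.2, 0.5),
                         l2_coeff = c(1e-4, 1e-2),
                         learning_rate = c(1e-5, 1e-3),
                         n_trials = 20L) {
  if (n_trials < 1) stopf("n_trials must be >= 1")
  structure(list(
    params = list(
      batch_size = list(type = "categorical", values = batch_size),
      dropout = list(type = "uniform", bounds = dropout),
      l2_coeff = list(type = "loguniform", bounds = l2_coeff),
      learning_rate = list(type = "loguniform", bounds = learning_rate)
    ),
    n_trials = as.integer(n_trials)
  ), class = "search_space")
}

sample_param <- function(d) {
  switch(d$type,
         categorical = d$values[sample.int(length(d$values), 1L)],
         uniform = runif(1, d$bounds[1], d$bounds[2]),
         loguniform = exp(runif(1, log(d$bounds[1]), log(d$bounds[2]))))
}

# Parzen-window density of x under a set of observations: equal-weight
# Gaussian mixture with a bandwidth floor, plus one flat prior component
# over the bounds so unexplored regions keep non-zero mass.
parzen_pdf <- function(x, obs, lo, hi) {
  k <- length(obs)
  flat <- 1 / (hi - lo)
  if (k == 0) return(flat)
  bw <- max(1.06 * stats::sd(obs) * k^(-0.2), (hi - lo) / 20, 1e-12)
  mix <- rowMeans(outer(x, obs, function(a, b) dnorm(a, b, bw)))
  (k * mix + flat) / (k + 1)
}

parzen_draw <- function(obs, lo, hi) {
  k <- length(obs)
  if (k == 0 || runif(1) < 1 / (k + 1)) return(runif(1, lo, hi))
  bw <- max(1.06 * stats::sd(obs) * k^(-0.2), (hi - lo) / 20, 1e-12)
  clamp(rnorm(1, obs[sample.int(k, 1L)], bw), lo, hi)
}

tpe_propose <- function(space, trials, gamma = 0.25, n_candidates = 24L) {
  ok <- !is.na(trials$value)
  n_good <- max(1L, ceiling(gamma * sum(ok)))
  ord <- order(trials$value[ok], decreasing = TRUE)
  good_idx <- which(ok)[ord[seq_len(n_good)]]
  bad_idx <- setdiff(which(ok), good_idx)
  cfg <- list()
  for (nm in names(space$params)) {
    d <- space$params[[nm]]
    gobs <- trials[[nm]][good_idx]; bobs <- trials[[nm]][bad_idx]
    if (d$type == "categorical") {
      score <- vapply(d$values, function(v) {
        lg <- (sum(gobs == v) + 1) / (length(gobs) + length(d$values))
        lb <- (sum(bobs == v) + 1) / (length(bobs) + length(d$values))
        lg / lb
      }, numeric(1))
      cfg[[nm]] <- d$values[which.max(score)]
    } else {
      logscale <- d$type == "loguniform"
      tr <- if (logscale) log else identity
      lo <- tr(d$bounds[1]); hi <- tr(d$bounds[2])
      cand <- vapply(seq_len(n_candidates), function(i)
        parzen_draw(tr(gobs), lo, hi), numeric(1))
      score <- parzen_pdf(cand, tr(gobs), lo, hi) /
        parzen_pdf(cand, tr(bobs), lo, hi)
      best <- cand[which.max(score)]
      cfg[[nm]] <- if (logscale) exp(best) else best
    }
  }
  cfg
}

#' Tree-structured Parzen estimator hyperparameter search
#'
#' Maximizes `objective` over a [search_space()] with the TPE strategy:
#' an initial block of random trials, then candidates drawn from a Parzen
#' density fitted to the best-`gamma` fraction of finished trials and
#' ranked by the good/bad density ratio.  A trial whose objective errors
#' is marked failed and the search continues.
#'
#' @param space a [search_space()].
#' @param objective function taking a named list
#'   (`batch_size`, `dropout`, `l2_coeff`, `learning_rate`) and returning
#'   a scalar to maximize (e.g. validation accuracy).
#' @param n_trials number of trials; defaults to the space's `n_trials`.
#' @param seed integer seed for the sampler.
#' @param n_startup number of initial purely random trials.
#' @param gamma fraction of trials treated as "good".
#' @return list with `best_config` (named list), `best_value`, and
#'   `trials` (data frame of every trial's parameters and value; failed
#'   trials have `NA` value).
#' @export
hyperparameter_search <- function(space, objective, n_trials = NULL,
                                  seed = 1L, n_startup = 10L, gamma = 0.25) {
  stopifnot(inherits(space, "search_space"))
  n_trials <- n_trials %||% space$n_trials
  trials <- data.frame()
  withr::with_seed(seed, {
    for (i in seq_len(n_trials)) {
      cfg <- if (i <= n_startup || sum(!is.na(trials$value)) < 2) {
        lapply(space$params, sample_param)
      } else {
        tpe_propose(space, trials, gamma = gamma)
      }
      val <- tryCatch(objective(cfg), error = function(e) NA_real_)
      trials <- rbind(trials, data.frame(trial = i, as.data.frame(cfg),
                                         value = val))
    }
  })
  if (all(is.na(trials$value))) stopf("every trial failed")
  best <- which.max(trials$value)
  list(best_config = as.list(trials[best, names(space$params)]),
       best_value = trials$value[best],
       trials = trials)
}
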