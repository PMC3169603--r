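#' Initialize a grid QUEST staircase
#'
#' QUEST maintains a Bayesian posterior over the log10 contrast threshold
#' of an assumed Weibull psychometric function and, after each trial,
#' recommends testing near the current threshold estimate.  This is a grid
#' implementation: the posterior is a discrete probability mass over an
#' ordered support of candidate log10 thresholds, started from a Gaussian
#' prior.
#'
#' The assumed psychometric function, in log10 contrast units `x` with
#' threshold `t`, is
#' `p(x; t) = gamma + (1 - gamma - delta) * (1 - exp(-10^(beta * (x - t))))`,
#' so that `t` is the log10 of the Weibull scale `alpha`.
#'
#' @param prior_mean prior mean of the log10 threshold.
#' @param prior_sd prior standard deviation (> 0), log10 units.
#' @param grid_n number of grid points (default 201).
#' @param grid_span half-width of the grid in prior SDs (default 3).
#' @param beta assumed Weibull slope.
#' @param gamma guessing rate (chance performance).
#' @param delta assumed lapse rate.
#' @param criterion target proportion correct for threshold placement,
#'   strictly inside `(gamma, 1 - delta)` (default 0.75).
#' @return An object of class `quest_state` with fields `grid`, `posterior`
#'   (sums to 1), the psychometric parameters, `criterion` and an empty
#'   `history`.
#' @export
#' @examples
#' q <- quest_init(prior_mean = log10(0.05), prior_sd = 0.5)
#' quest_recommend(q)
quest_init <- function(prior_mean, prior_sd, grid_n = 201L, grid_span = 3,
                       beta = 3.5, gamma = 0.5, delta = 0.01,
                       criterion = 0.75) {
  if (!(prior_sd > 0)) stop("'prior_sd' must be > 0")
  if (!(criterion > gamma && criterion < 1 - delta)) {
    stop("'criterion' must lie strictly between gamma and 1 - delta")
  }
  grid <- seq(prior_mean - grid_span * prior_sd,
              prior_mean + grid_span * prior_sd, length.out = grid_n)
  post <- stats::dnorm(grid, prior_mean, prior_sd)
  post <- post / sum(post)
  structure(list(grid = grid, posterior = post,
                 beta = beta, gamma = gamma, delta = delta,
                 criterion = criterion,
                 history = list()),
            class = "quest_state")
}

# Assumed Weibull in log10 contrast units.
.quest_p <- function(x, t, beta, gamma, delta) {
  gamma + (1 - gamma - delta) * (1 - exp(-10^(beta * (x - t))))
}

#' Update the QUEST posterior with one trial outcome
#'
#' Multiplies the posterior by the Weibull likelihood of the observed
#' outcome at the tested contrast and renormalizes; the trial is appended
#' to the state's history.
#'
#' @param state a `quest_state` from [quest_init()].
#' @param tested_log_contrast log10 contrast actually shown.
#' @param correct logical outcome of the trial.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, tested_log_contrast, correct) {
  stopifnot(inherits(state, "quest_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  p <- .quest_p(tested_log_contrast, state$grid,
                state$beta, state$gamma, state$delta)
  lik <- if (correct) p else 1 - p
  post <- state$posterior * lik
  s <- sum(post)
  if (s <= 0) stop("degenerate posterior: all likelihoods zero")
  state$posterior <- post / s
  state$history[[length(state$history) + 1L]] <-
    list(log_contrast = tested_log_contrast, correct = correct,
         posterior_mode = quest_mode(state))
  state
}

#' Posterior-mode threshold estimate
#'
#' @param state a `quest_state`.
#' @return The grid value with maximal posterior mass (ties break toward
#'   the lower contrast).
#' @export
quest_mode <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  state$grid[which.max(state$posterior)]
}

#' Recommended test contrast for the next trial
#'
#' Mode-placement rule: the posterior-mode threshold is shifted to the
#' log10 contrast at which the assumed psychometric function equals the
#' criterion (e.g. 75 percent correct).
#'
#' @param state a `quest_state`.
#' @return Recommended log10 contrast.
#' @export
quest_recommend <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  k <- -log(1 - (state$criterion - state$gamma) /
              (1 - state$gamma - state$delta))
  quest_mode(state) + log10(k) / state$beta
}

#' @export
print.quest_state <- function(x, ...) {
  cat(sprintf(paste0("<quest_state> %d trials, mode %.4f, ",
                     "recommend %.4f (log10 contrast)\n"),
              length(x$history), quest_mode(x), quest_recommend(x)))
  invisible(x)
}

#' Run a QUEST staircase against a responder
#'
#' Repeatedly recommends a contrast, queries `respond` for a correct /
#' incorrect outcome, and updates the posterior.
#'
#' @param state a `quest_state` from [quest_init()].
#' @param respond function taking a log10 contrast and returning a logical
#'   outcome; see [weibull_responder()].
#' @param n_trials number of trials to run.
#' @param seed optional integer seed set before the first trial.
#' @return The final `quest_state`.
#' @export
#' @examples
#' q <- quest_init(log10(0.05), 0.5)
#' q <- quest_run(q, weibull_responder(log10(0.04)), 50, seed = 1)
#' quest_mode(q)
quest_run <- function(state, respond, n_trials, seed = NULL) {
  stopifnot(inherits(state, "quest_state"), is.function(respond),
            n_trials >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (i in seq_len(n_trials)) {
    x <- quest_recommend(state)
    state <- quest_update(state, x, isTRUE(respond(x)))
  }
  state
}

#' Weibull responder for staircase simulation
#'
#' Returns a closure simulating an observer whose accuracy follows the
#' Weibull psychometric function with true log10 threshold
#' `true_log_alpha`; each call draws one Bernoulli outcome from the R RNG
#' stream.
#'
#' @param true_log_alpha true log10 contrast threshold (Weibull scale).
#' @param beta,gamma,delta psychometric parameters of the simulated
#'   observer.
#' @return A function `f(log_contrast) -> logical`.
#' @export
weibull_responder <- function(true_log_alpha, beta = 3.5, gamma = 0.5,
                              delta = 0.01) {
  function(log_contrast) {
    stats::runif(1L) < .quest_p(log_contrast, true_log_alpha,
                                beta, gamma, delta)
  }
}

#' Staircase transcript
#'
#' @param state a `quest_state`.
#' @return data.frame with one row per trial: `trial`, `log_contrast`,
#'   `correct`, `posterior_mode` (the mode after that trial's update).
#' @export
quest_transcript <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  h <- state$history
  data.frame(trial = seq_along(h),
             log_contrast = vapply(h, `[[`, numeric(1L), "log_contrast"),
             correct = vapply(h, `[[`, logical(1L), "correct"),
             posterior_mode = vapply(h, `[[`, numeric(1L), "posterior_mode"))
}
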