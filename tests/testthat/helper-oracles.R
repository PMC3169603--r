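# Independent brute-force oracles used to cross-check the package's
# statistics. These are deliberately written from the textbook formulas,
# not by calling the code paths they verify.

# Classical paired t from first principles.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  md <- sum(d) / n
  s2 <- sum((d - md)^2) / (n - 1)
  t <- md / sqrt(s2 / n)
  list(statistic = t, df = n - 1,
       p = 2 * stats::pt(-abs(t), n - 1), mean_diff = md)
}

# Fully within-subject ANOVA by direct sum-of-squares partitioning over
# cell means, one observation per subject x cell.  Factors: subject (S)
# plus three within factors; each within effect is tested against its
# interaction with S.
#
# d: data.frame with columns observer, posture, distractor, location, y.
oracle_rm_anova <- function(d) {
  arr <- tapply(d$y, list(factor(d$observer), factor(d$posture),
                          factor(d$distractor), factor(d$location)), mean)
  dims <- dim(arr)

  # array of the marginal mean over `margins`, broadcast to full size
  expand_margin <- function(margins) {
    if (!length(margins)) return(array(mean(arr), dims))
    m <- apply(arr, margins, mean)
    others <- setdiff(seq_along(dims), margins)
    full <- array(rep(m, times = prod(dims[others])),
                  dim = c(dims[margins], dims[others]))
    aperm(full, order(c(margins, others)))
  }

  subsets_of <- function(set) {
    out <- list(integer(0))
    for (s in set) out <- c(out, lapply(out, function(u) c(u, s)))
    out
  }

  ss_effect <- function(T) {
    est <- array(0, dims)
    for (U in subsets_of(T)) {
      est <- est + (-1)^(length(T) - length(U)) * expand_margin(U)
    }
    sum(est^2)
  }
  df_effect <- function(T) prod(dims[T] - 1L)

  # within effects (2 = posture, 3 = distractor, 4 = location); subject = 1
  effects <- list(posture = 2L, distractor = 3L, location = 4L,
                  "posture:distractor" = c(2L, 3L),
                  "posture:location" = c(2L, 4L),
                  "distractor:location" = c(3L, 4L),
                  "posture:distractor:location" = c(2L, 3L, 4L))
  res <- lapply(names(effects), function(nm) {
    T <- effects[[nm]]
    Terr <- c(1L, T)
    ss_e <- ss_effect(T)
    ss_r <- ss_effect(Terr)
    df1 <- df_effect(T)
    df2 <- df_effect(Terr)
    F <- (ss_e / df1) / (ss_r / df2)
    data.frame(effect = nm, df1 = df1, df2 = df2, ss = ss_e,
               mse = ss_r / df2, F = F,
               p = stats::pf(F, df1, df2, lower.tail = FALSE),
               eta_p2 = ss_e / (ss_e + ss_r))
  })
  do.call(rbind, res)
}

# Direct (unnormalized-prior) recomputation of a grid QUEST posterior from
# the full trial history.
oracle_quest_posterior <- function(grid, prior_mean, prior_sd, history,
                                   beta, gamma, delta) {
  post <- stats::dnorm(grid, prior_mean, prior_sd)
  for (h in history) {
    p <- gamma + (1 - gamma - delta) *
      (1 - exp(-10^(beta * (h$log_contrast - grid))))
    post <- post * if (h$correct) p else 1 - p
  }
  post / sum(post)
}
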