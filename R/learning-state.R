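# Ideal-observer state-space estimate of learning.
#
# The latent learning state x_t follows a Gaussian random walk observed
# through binary outcomes via a logistic link anchored at chance:
# p_t = logistic(x_t + logit(chance)), x_0 = 0. The process-noise variance
# is estimated by EM; the E-step is the standard Gaussian-approximation
# forward filter / fixed-interval smoother for Bernoulli observations.

#' EM ideal-observer learning curve for one block
#'
#' Estimates the per-trial probability of a correct choice from a binary
#' outcome sequence, using all trials in the block, and derives the
#' statistically defined learning trial (see [detect_learning_trial()]).
#'
#' @param outcomes Binary outcome sequence (1 = correct), length >= 5.
#' @param chance Chance probability of a correct choice (0.5 for the
#'   two-alternative task).
#' @param tol EM convergence tolerance on the process variance.
#' @param max_iter Maximum EM iterations.
#' @param var_init Initial process-noise variance.
#' @param var_max Ceiling on the process-noise variance. On degenerate
#'   sequences (nearly all outcomes identical) the marginal likelihood of
#'   the variance has no interior maximum and EM diverges; the ceiling
#'   stabilises the estimate an order of magnitude above the values seen on
#'   informative blocks (typically 0.01-0.15).
#' @param conf Confidence level of the lower/upper bounds.
#' @param two_sided If `FALSE` (default) the bounds are one-sided
#'   confidence bounds (the 5th and 95th percentiles at `conf = 0.95`),
#'   the usual convention for the learning-trial rule; if `TRUE`, the
#'   2.5/97.5 two-sided quantiles are used.
#' @param track_loglik If `TRUE`, store the exact (dense-grid) data
#'   log-likelihood at each EM iterate (slower; used for diagnostics).
#' @return An object of class `em_learning`: a tibble with columns `trial`,
#'   `outcome`, `p_mode`, `p_lower95`, `p_upper95`, carrying attributes
#'   `process_variance`, `em_iterations`, `learning_trial`, `chance`. Use
#'   [tidy()] / [glance()] to extract them.
#' @examples
#' est <- em_learning_curve(c(0, 0, 1, 0, 1, 1, 1, 1, 1, 1, 1, 1))
#' glance(est)
#' @export
em_learning_curve <- function(outcomes, chance = 0.5, tol = 1e-8,
                              max_iter = 500, var_init = 0.005,
                              var_max = 0.3, conf = 0.95,
                              two_sided = FALSE, track_loglik = FALSE) {
  outcomes <- as.integer(outcomes)
  if (length(outcomes) < 5) {
    stop("need at least 5 trials to estimate a learning curve", call. = FALSE)
  }
  stopifnot(all(outcomes %in% c(0L, 1L)), chance > 0, chance < 1)
  mu <- qlogis(chance)
  n <- length(outcomes)
  sigma2 <- var_init
  ll_trace <- numeric(0)
  iter <- 0L
  x_lin <- rep(0, n)
  repeat {
    iter <- iter + 1L
    sm <- fs_smooth_pass(outcomes, sigma2, mu, x_lin)
    x_lin <- sm$x_smooth
    if (track_loglik) {
      ll_trace <- c(ll_trace,
                    grid_loglik(outcomes, sigma2, chance = chance))
    }
    # M-step: expected squared state increments, x_0 fixed at 0
    x <- c(0, sm$x_smooth)
    v <- c(0, sm$v_smooth)
    cross <- sm$cov_lag1 # entry t: cov(x_{t-1}, x_t | data); entry 1 is 0
    inc <- diff(x)^2 + v[-1] + v[-(n + 1)] - 2 * cross
    sigma2_new <- min(max(sum(inc) / n, 1e-12), var_max)
    if (abs(sigma2_new - sigma2) < tol || iter >= max_iter) {
      sigma2 <- sigma2_new
      break
    }
    sigma2 <- sigma2_new
  }
  # final E-step passes at the converged variance until the linearization
  # trajectory is self-consistent (joint posterior mode)
  for (i in 1:50) {
    sm <- fs_smooth_pass(outcomes, sigma2, mu, x_lin)
    delta <- max(abs(sm$x_smooth - x_lin))
    x_lin <- sm$x_smooth
    if (delta < 1e-9) break
  }
  sdv <- sqrt(pmax(sm$v_smooth, 0))
  z <- if (two_sided) stats::qnorm(1 - (1 - conf) / 2) else stats::qnorm(conf)
  out <- tibble::tibble(
    trial = seq_len(n),
    outcome = outcomes,
    p_mode = plogis(sm$x_smooth + mu),
    p_lower95 = plogis(sm$x_smooth - z * sdv + mu),
    p_upper95 = plogis(sm$x_smooth + z * sdv + mu)
  )
  est <- structure(
    out,
    process_variance = sigma2,
    em_iterations = iter,
    chance = chance,
    loglik_trace = if (track_loglik) ll_trace else NULL,
    class = c("em_learning", class(out))
  )
  attr(est, "learning_trial") <- detect_learning_trial(est, chance)
  est
}

# One Gaussian-approximation forward-filter / fixed-interval-smoother pass.
# The Bernoulli observations are replaced by their local quadratic
# (Laplace) approximation at the linearization trajectory `x_lin`:
# pseudo-observation z_t = x_lin_t + (y_t - p_t)/w_t with precision
# w_t = p_t (1 - p_t). Iterating passes with x_lin set to the previous
# smoothed trajectory converges to the joint posterior mode.
fs_smooth_pass <- function(outcomes, sigma2, mu, x_lin = NULL) {
  n <- length(outcomes)
  if (is.null(x_lin)) x_lin <- rep(0, n)
  p_lin <- plogis(x_lin + mu)
  w <- pmax(p_lin * (1 - p_lin), 1e-10)
  z <- x_lin + (outcomes - p_lin) / w
  x_post <- v_post <- x_pred <- v_pred <- numeric(n)
  x_prev <- 0
  v_prev <- 0
  for (t in seq_len(n)) {
    xp <- x_prev
    vp <- v_prev + sigma2
    k <- vp * w[t] / (vp * w[t] + 1)
    x <- xp + k * (z[t] - xp)
    x_pred[t] <- xp
    v_pred[t] <- vp
    x_post[t] <- x
    v_post[t] <- vp * (1 - k)
    x_prev <- x
    v_prev <- v_post[t]
  }
  x_smooth <- x_post
  v_smooth <- v_post
  a <- numeric(n)
  if (n > 1) {
    for (t in (n - 1):1) {
      a[t] <- v_post[t] / v_pred[t + 1]
      x_smooth[t] <- x_post[t] + a[t] * (x_smooth[t + 1] - x_pred[t + 1])
      v_smooth[t] <- v_post[t] + a[t]^2 * (v_smooth[t + 1] - v_pred[t + 1])
    }
  }
  # lag-one smoothed covariance cov(x_{t-1}, x_t | data), t = 2..n; entry 1
  # is cov(x_0, x_1) = 0 since x_0 is fixed.
  cov_lag1 <- c(0, a[seq_len(n - 1)] * v_smooth[-1])[seq_len(n)]
  list(x_smooth = x_smooth, v_smooth = v_smooth, cov_lag1 = cov_lag1,
       x_post = x_post, v_post = v_post, x_pred = x_pred, v_pred = v_pred)
}

# Per-(session, block) EM learning trials for a trial table; blocks too
# short for the state-space model (< 5 trials, e.g. truncated tails) get NA.
estimate_learning_trials <- function(trials) {
  trials |>
    dplyr::group_by(.data$session_id, .data$block_index) |>
    dplyr::summarise(
      learning_trial = if (dplyr::n() < 5) {
        NA_integer_
      } else {
        glance(em_learning_curve(.data$outcome))$learning_trial
      },
      .groups = "drop"
    )
}

#' Statistically defined learning trial
#'
#' The first trial at which the lower 95% confidence bound of the estimated
#' probability correct exceeds chance and never drops back to or below
#' chance for the remainder of the block.
#'
#' @param estimate An `em_learning` object, or any data frame with a
#'   `p_lower95` column.
#' @param chance Chance probability.
#' @return The 1-based learning trial, or `NA` if the bound never clears
#'   chance persistently.
#' @examples
#' detect_learning_trial(
#'   data.frame(p_lower95 = c(.3, .4, .6, .4, .6, .7, .8))
#' ) # 5
#' @export
detect_learning_trial <- function(estimate, chance = 0.5) {
  lower <- estimate$p_lower95
  stopifnot(!is.null(lower))
  above <- lower > chance
  if (!any(!above)) {
    return(if (length(above)) 1L else NA_integer_)
  }
  last_below <- max(which(!above))
  if (last_below == length(above)) NA_integer_ else last_below + 1L
}

#' Exact dense-grid smoother for the ideal-observer model
#'
#' Reference implementation: the latent random walk is discretised to a fine
#' grid and smoothed exactly by the forward-backward algorithm. Used to
#' validate the Gaussian-approximation smoother; too slow for routine use.
#'
#' @inheritParams em_learning_curve
#' @param process_variance Random-walk variance of the latent state.
#' @param n_bins Number of grid bins.
#' @param span Grid extent (latent-state units around 0).
#' @return A tibble with `trial`, the posterior mean, mode and median of
#'   the state (`x_mean`, `x_mode`, `x_median`) and their link-mapped
#'   probabilities (`p_mean`, `p_mode`, `p_median`). Because the link is
#'   monotone, `p_median` is also the posterior median of the probability
#'   itself, which is the quantity the Gaussian approximation's centre
#'   estimates.
#' @export
em_grid_smoother <- function(outcomes, process_variance, chance = 0.5,
                             n_bins = 400, span = 6) {
  outcomes <- as.integer(outcomes)
  mu <- qlogis(chance)
  grid <- seq(-span, span, length.out = n_bins)
  n <- length(outcomes)
  p_grid <- plogis(grid + mu)
  sdw <- sqrt(process_variance)
  # trans[i, j] = P(to = grid[i] | from = grid[j]); columns sum to 1
  raw <- outer(grid, grid, function(to, from) dnorm(to, from, sdw))
  trans <- t(t(raw) / colSums(raw))
  emit <- function(y) if (y == 1) p_grid else 1 - p_grid
  alpha <- matrix(0, n_bins, n)
  prior1 <- dnorm(grid, 0, sdw)
  prior1 <- prior1 / sum(prior1)
  alpha[, 1] <- prior1 * emit(outcomes[1])
  alpha[, 1] <- alpha[, 1] / sum(alpha[, 1])
  for (t in 2:n) {
    a <- as.vector(trans %*% alpha[, t - 1]) * emit(outcomes[t])
    alpha[, t] <- a / sum(a)
  }
  beta <- matrix(0, n_bins, n)
  beta[, n] <- 1
  for (t in (n - 1):1) {
    b <- as.vector(t(trans) %*% (emit(outcomes[t + 1]) * beta[, t + 1]))
    beta[, t] <- b / max(b)
  }
  gam <- alpha * beta
  gam <- sweep(gam, 2, colSums(gam), "/")
  x_mean <- as.vector(crossprod(gam, grid))
  x_mode <- grid[apply(gam, 2, which.max)]
  x_median <- apply(gam, 2, function(g) grid[which(cumsum(g) >= 0.5)[1]])
  tibble::tibble(
    trial = seq_len(n),
    x_mean = x_mean,
    x_mode = x_mode,
    x_median = x_median,
    p_mean = plogis(x_mean + mu),
    p_mode = plogis(x_mode + mu),
    p_median = plogis(x_median + mu)
  )
}

# Exact data log-likelihood of the discretised model (for EM diagnostics).
grid_loglik <- function(outcomes, process_variance, chance = 0.5,
                        n_bins = 400, span = 6) {
  outcomes <- as.integer(outcomes)
  mu <- qlogis(chance)
  grid <- seq(-span, span, length.out = n_bins)
  p_grid <- plogis(grid + mu)
  sdw <- sqrt(process_variance)
  raw <- outer(grid, grid, function(to, from) dnorm(to, from, sdw))
  trans <- t(t(raw) / colSums(raw))
  emit <- function(y) if (y == 1) p_grid else 1 - p_grid
  prior1 <- dnorm(grid, 0, sdw)
  prior1 <- prior1 / sum(prior1)
  ll <- 0
  a <- prior1 * emit(outcomes[1])
  ll <- ll + log(sum(a))
  a <- a / sum(a)
  for (t in seq_along(outcomes)[-1]) {
    a <- as.vector(trans %*% a) * emit(outcomes[t])
    ll <- ll + log(sum(a))
    a <- a / sum(a)
  }
  ll
}
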