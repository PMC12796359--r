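# Truncated-normal margins for the cohort generator.
#
# Cohort parameters live on physical ranges (fractions and normalized
# entropies in [0,1], velocities and variances >= 0, FD in [0,2]), so each
# margin is a normal distribution truncated to its range. Published group
# summaries are moments of the *observed* (i.e. truncated) values, so the
# parent mean/sd are solved numerically such that the truncated distribution
# reproduces the target mean and sd (moment matching), rather than plugging
# the targets in as parent parameters.

tnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  if (Z < .Machine$double.eps) {
    # numerically degenerate: all mass at the nearer bound
    edge <- if (a > 0) lower else upper
    return(list(mean = edge, sd = 0))
  }
  da <- dnorm(a); db <- dnorm(b)
  m <- mu + sigma * (da - db) / Z
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  v <- sigma^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# Parent mu such that the truncated mean equals `target_mean` for a given
# sigma. The truncated mean is strictly increasing in mu. The bracket keeps
# the parent in a numerically safe region (at least ~1e-8 of parent mass in
# [lower, upper]); a mean unreachable there raises an error, which the sd
# search treats as infeasible.
tnorm_solve_mu <- function(target_mean, sigma, lower, upper) {
  f <- function(mu) tnorm_moments(mu, sigma, lower, upper)$mean - target_mean
  lo <- if (is.finite(lower)) lower - 5.5 * sigma else target_mean - 50 * sigma
  hi <- if (is.finite(upper)) upper + 5.5 * sigma else target_mean + 50 * sigma
  if (f(lo) > 0 || f(hi) < 0) {
    stop("truncated mean unreachable in numerically safe region",
         call. = FALSE)
  }
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Solve parent parameters of a truncated-normal margin
#'
#' Finds parent `(mu, sigma)` of a normal distribution truncated to
#' `[lower, upper]` whose truncated mean equals `mean` exactly and whose
#' truncated sd is as close as possible to `sd` (equal whenever the target is
#' achievable within the family). Used by [cohort_calibration()] so that
#' sampled cohorts reproduce published group means/SDs after truncation.
#'
#' @param mean,sd Target moments of the truncated distribution (`sd > 0`).
#' @param lower,upper Truncation bounds (may be infinite).
#' @return List with `mu`, `sigma`, and `achieved_sd`.
#' @export
#' @examples
#' p <- tnorm_match_moments(0.922, 0.092, 0, 1)
#' # parent is shifted/widened so the truncated moments hit the target
#' tnorm_moments(p$mu, p$sigma, 0, 1)
tnorm_match_moments <- function(mean, sd, lower, upper) {
  if (!is.finite(mean) || mean <= lower || mean >= upper) {
    stop("target mean must lie strictly inside (lower, upper)", call. = FALSE)
  }
  stopifnot_scalar_pos(sd, "sd")
  sd_err <- function(log_sigma) {
    sigma <- exp(log_sigma)
    mu <- tryCatch(tnorm_solve_mu(mean, sigma, lower, upper),
                   error = function(e) NA_real_)
    if (!is.finite(mu)) return(1e12 * (1 + sigma))
    a <- (lower - mu) / sigma; b <- (upper - mu) / sigma
    if (pnorm(b) - pnorm(a) < 1e-8) return(1e12 * (1 + sigma))
    (tnorm_moments(mu, sigma, lower, upper)$sd - sd)^2
  }
  opt <- optimize(sd_err, c(log(sd / 50), log(sd * 50)), tol = 1e-10)
  sigma <- exp(opt$minimum)
  mu <- tnorm_solve_mu(mean, sigma, lower, upper)
  list(mu = mu, sigma = sigma,
       achieved_sd = tnorm_moments(mu, sigma, lower, upper)$sd)
}

# Quantile function of the truncated normal; `p` may be a vector.
tnorm_quantile <- function(p, mu, sigma, lower, upper) {
  pa <- pnorm(lower, mu, sigma)
  pb <- pnorm(upper, mu, sigma)
  q <- qnorm(pa + p * (pb - pa), mu, sigma)
  clamp(q, lower, upper)
}
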