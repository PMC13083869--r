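#' Mean-field parameters
#'
#' Scalar description of the community as an average background for a focal
#' species: mean growth rate `r`, per-link cost `delta`, mean interaction
#' strength `mu`, mean number of mutualistic links per species `k1`,
#' interspecific competition strength `k2`, mean intraspecific competition
#' `gamma`, and mutualistic handling time `h_m`.
#'
#' @param r,delta,mu,k1,k2,gamma,h_m Non-negative scalars.
#' @return An object of class `meanfield_params`.
#' @export
meanfield_params <- function(r = 0.1, delta = 0.01, mu = 0.2, k1 = 1,
                             k2 = 0, gamma = 1, h_m = 0.1) {
  stopifnot(r >= 0, delta >= 0, mu >= 0, k1 >= 0, k2 >= 0, gamma >= 0, h_m >= 0)
  structure(list(r = r, delta = delta, mu = mu, k1 = k1, k2 = k2,
                 gamma = gamma, h_m = h_m), class = "meanfield_params")
}

meanfield_residual <- function(x, p) {
  p$r - p$delta * p$k1 + p$k1 * p$mu * x / (1 + p$k1 * p$h_m * p$mu * x) -
    p$k2 * p$mu * x - p$gamma * x
}

#' Mean-field equilibrium abundance
#'
#' Solves the mean-field balance `0 = r - delta*k1 +
#' k1*mu*x / (1 + k1*h_m*mu*x) - k2*mu*x - gamma*x` for the background
#' abundance `x`. The equation can have several positive roots; the largest
#' is returned (the background attained when assembling from positive
#' abundance). The search brackets sign changes on a dense grid over
#' `[0, x_max]` and refines each with [stats::uniroot()]; `x_max` inflates
#' the no-interaction bound `r / gamma` by the saturated mutualistic gain
#' ceiling `1 / h_m` (and a factor 10), so every positive root is bracketed.
#'
#' @param p A [meanfield_params()] object.
#' @param n_grid Number of scan points.
#' @return The largest positive root, or `NA` if none exists.
#' @export
meanfield_equilibrium <- function(p, n_grid = 4000L) {
  if (p$gamma == 0 && p$k2 == 0) {
    if (p$r - p$delta * p$k1 > 0)
      stop("no self-limitation (gamma = k2 = 0) with net positive growth: unbounded", call. = FALSE)
  }
  gamma_eff <- if (p$gamma > 0) p$gamma else p$k2 * p$mu
  if (gamma_eff <= 0) return(NA_real_)
  if (p$h_m == 0 || p$k1 == 0 || p$mu == 0) {
    # linear in x: closed form
    slope <- p$k1 * p$mu - p$k2 * p$mu - p$gamma
    if (slope == 0) return(NA_real_)
    rt <- (p$r - p$delta * p$k1) / (-slope)
    return(if (rt > 0) rt else NA_real_)
  }
  gain_cap <- 1 / p$h_m
  x_max <- 10 * (max(p$r, 1e-8) + gain_cap) / gamma_eff
  xs <- seq(0, x_max, length.out = n_grid)
  fs <- meanfield_residual(xs, p)
  root <- NA_real_
  sgn <- sign(fs)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (k in flips) {
    rt <- uniroot(meanfield_residual, c(xs[k], xs[k + 1]), p = p,
                  tol = 1e-14)$root
    if (rt > 0) root <- max(root, rt, na.rm = TRUE)
  }
  exact <- which(fs == 0 & xs > 0)
  if (length(exact)) root <- max(root, xs[exact], na.rm = TRUE)
  root
}

#' Net benefit of acquiring one more mutualistic link
#'
#' Returns `mu*x / (1 + h_m*k1*mu*x) - delta`: the saturating per-link
#' benefit at background abundance `x` minus the per-link cost. A new
#' mutualistic link is selectively favourable when this is positive.
#'
#' @param p A [meanfield_params()] object.
#' @param x Background abundance (>= 0).
#' @return Net benefit (can be negative).
#' @export
link_benefit <- function(p, x) {
  stopifnot(all(x >= 0))
  p$mu * x / (1 + p$h_m * p$k1 * p$mu * x) - p$delta
}

#' Mutualistic-link threshold in k1
#'
#' Scans a grid of mean mutualistic degrees `k1`; for each, computes the
#' mean-field equilibrium and the net link benefit there. Returns the first
#' `k1` at which the benefit fails (benefit <= 0, or no positive
#' equilibrium), i.e. the degree beyond which additional mutualistic links
#' no longer pay for their cost.
#'
#' @param p A [meanfield_params()] object (its `k1` is ignored).
#' @param k1_grid Increasing grid of k1 values (default `1:50`).
#' @return List with `threshold` (`NA` if the benefit holds across the
#'   grid) and a tibble `profile` (`k1`, `x_eq`, `benefit`).
#' @export
k1_threshold <- function(p, k1_grid = 1:50) {
  stopifnot(length(k1_grid) >= 2, !is.unsorted(k1_grid))
  profile <- purrr::map_dfr(k1_grid, function(k1) {
    pk <- p
    pk$k1 <- k1
    xeq <- meanfield_equilibrium(pk)
    ben <- if (is.na(xeq)) NA_real_ else link_benefit(pk, xeq)
    tibble::tibble(k1 = k1, x_eq = xeq, benefit = ben)
  })
  fail <- which(is.na(profile$x_eq) | profile$benefit <= 0)
  list(threshold = if (length(fail)) profile$k1[fail[1]] else NA_real_,
       profile = profile)
}
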