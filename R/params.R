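#' Model parameters for the community dynamics
#'
#' Bundles every scalar parameter of the population dynamics and of the
#' numerical procedure used to relax a community to ecological equilibrium.
#' Defaults are the study conditions: per-link harvesting cost `delta`,
#' interaction-strength scale `sigma`, Type II handling times
#' `h_p` (consumers) and `h_m` (mutualists), growth-rate distribution
#' parameters `mu_r`, `sigma_r` (half-normal by default), lognormal
#' carrying-capacity parameters (`K_log_mu`, `K_log_sigma`), the extinction
#' threshold `x_ext`, the introduction abundance `x0_new`, and the
#' equilibrium criterion (relative change of every surviving species below
#' `eq_rel_tol` over `eq_window` consecutive steps of size `eq_dt`).
#'
#' @param delta Per-link cost subtracted from the intrinsic growth rate for
#'   every positive (mutualistic or consumer) interaction a species holds.
#' @param sigma Scale of the half-normal distribution new interaction
#'   strengths are drawn from.
#' @param h_p,h_m Handling times of the saturating functional responses for
#'   consumer-resource and mutualistic interactions.
#' @param mu_r,sigma_r Location and scale of the intrinsic growth-rate
#'   distribution.
#' @param growth_dist `"halfnormal"` (default) draws `|N(mu_r, sigma_r^2)|`,
#'   guaranteeing positivity; `"normal"` draws `N(mu_r, sigma_r^2)` and
#'   resamples non-positive values.
#' @param K_log_mu,K_log_sigma Parameters of the underlying normal of the
#'   lognormal carrying-capacity distribution.
#' @param x_ext Extinction threshold: a species whose abundance falls
#'   (strictly) below this value is removed from the community.
#' @param x0_new Introduction abundance of newly added species.
#' @param eq_rel_tol Equilibrium tolerance as a fraction (1e-4 = 0.01%).
#' @param eq_window Number of consecutive passing checks required.
#' @param eq_dt Spacing of the equilibrium checks, in model time units.
#' @param max_integration_time Safety cap per relaxation; non-convergence is
#'   reported, not an error.
#' @param rtol,atol Tolerances of the adaptive ODE stepper (must be tighter
#'   than the equilibrium criterion).
#' @return An object of class `model_params` (a named list).
#' @export
model_params <- function(delta = 0.01, sigma = 0.2,
                         h_p = 0.1, h_m = 0.1,
                         mu_r = 0.1, sigma_r = 0.1,
                         growth_dist = c("halfnormal", "normal"),
                         K_log_mu = -2.2, K_log_sigma = 0.5,
                         x_ext = 1e-6, x0_new = 1e-6,
                         eq_rel_tol = 1e-4, eq_window = 10L, eq_dt = 0.01,
                         max_integration_time = 5e4,
                         rtol = 1e-8, atol = 1e-10) {
  growth_dist <- match.arg(growth_dist)
  p <- list(delta = delta, sigma = sigma, h_p = h_p, h_m = h_m,
            mu_r = mu_r, sigma_r = sigma_r, growth_dist = growth_dist,
            K_log_mu = K_log_mu, K_log_sigma = K_log_sigma,
            x_ext = x_ext, x0_new = x0_new,
            eq_rel_tol = eq_rel_tol, eq_window = as.integer(eq_window),
            eq_dt = eq_dt, max_integration_time = max_integration_time,
            rtol = rtol, atol = atol)
  num <- p[setdiff(names(p), "growth_dist")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), logical(1))))
    stop("all model parameters must be finite scalars", call. = FALSE)
  stopifnot(delta >= 0, sigma > 0, h_p >= 0, h_m >= 0, mu_r > 0, sigma_r > 0,
            x_ext > 0, x0_new >= x_ext, eq_rel_tol > 0, p$eq_window >= 1L,
            eq_dt > 0, max_integration_time > 0, rtol > 0, atol > 0)
  structure(p, class = "model_params")
}

#' Configuration of an assembly run
#'
#' @param scenario Assembly mechanism: `"evo"` (speciation with inheritance),
#'   `"inv_rand"` (invasion, each link's role uniform over the four roles) or
#'   `"inv_prop"` (invasion, per-invader role proportions drawn uniformly on
#'   the simplex).
#' @param Delta Maximum number of pair-link changes between parent and
#'   offspring under speciation (small `Delta` = strong inheritance).
#' @param rho1,rho2 Bounds of the uniform interval the invader connectivity
#'   is drawn from.
#' @param n_events Number of assembly events (introductions).
#' @param n_init Number of unlinked founder species.
#' @param x_init_max Founder abundances are drawn uniformly on
#'   `[0, x_init_max]`.
#' @param isolated_removal_after Event index after which species with no
#'   interactions are purged following every event.
#' @param snapshot_every Snapshot recording cadence, in events.
#' @param evo_fraction Probability that an event is a speciation in mixed
#'   runs (1 = pure evolution when `scenario = "evo"`); only used for
#'   `scenario = "evo"` with `evo_fraction < 1`.
#' @param retry_failed If `TRUE`, an introduction whose newcomer goes
#'   extinct during relaxation does not consume an assembly event and is
#'   retried (up to 50 attempts per event); by default every introduction
#'   counts as an event and survival is merely logged.
#' @return An object of class `assembly_config`.
#' @export
assembly_config <- function(scenario = c("evo", "inv_rand", "inv_prop"),
                            Delta = 5L, rho1 = 0.01, rho2 = 0.5,
                            n_events = 500L, n_init = 5L, x_init_max = 0.02,
                            isolated_removal_after = 20L, snapshot_every = 50L,
                            evo_fraction = 1.0, retry_failed = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(Delta >= 1, rho1 > 0, rho1 <= rho2, rho2 <= 1, n_events >= 1,
            n_init >= 1, x_init_max > 0, snapshot_every >= 1,
            evo_fraction >= 0, evo_fraction <= 1, is.logical(retry_failed))
  structure(list(scenario = scenario, Delta = as.integer(Delta),
                 rho1 = rho1, rho2 = rho2, n_events = as.integer(n_events),
                 n_init = as.integer(n_init), x_init_max = x_init_max,
                 isolated_removal_after = as.integer(isolated_removal_after),
                 snapshot_every = as.integer(snapshot_every),
                 evo_fraction = evo_fraction, retry_failed = retry_failed),
            class = "assembly_config")
}

#' Configuration of the stochastic (Euler-Maruyama) abundance sampling
#'
#' @param sd Scale of the multiplicative environmental noise (the noise term
#'   is `sd * x_i * dW_i`).
#' @param dt Euler-Maruyama step size.
#' @param burn_in Time discarded before the first recorded sample.
#' @param spacing Time between recorded samples (non-overlapping intervals).
#' @param n_samples Number of samples recorded.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(sd = 0.1, dt = 1e-3, burn_in = 50, spacing = 1,
                         n_samples = 300L) {
  stopifnot(sd >= 0, dt > 0, burn_in >= 0, spacing >= dt, n_samples >= 2)
  structure(list(sd = sd, dt = dt, burn_in = burn_in, spacing = spacing,
                 n_samples = as.integer(n_samples)),
            class = "noise_config")
}

#' Read assembly configuration and model parameters from a YAML file
#'
#' The file may contain top-level blocks `params` (arguments of
#' [model_params()]) and `config` (arguments of [assembly_config()]); any
#' entries in `override` replace file values.
#'
#' @param path Path to a YAML file.
#' @param override Named list of overrides (e.g. from CLI flags).
#' @return A list with elements `params` and `config`.
#' @export
read_config_yaml <- function(path, override = list()) {
  raw <- yaml::read_yaml(path)
  pargs <- modifyList(raw$params %||% list(), override$params %||% list())
  cargs <- modifyList(raw$config %||% list(), override$config %||% list())
  list(params = do.call(model_params, pargs),
       config = do.call(assembly_config, cargs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
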