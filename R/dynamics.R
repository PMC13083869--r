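#' Per-capita growth rates
#'
#' Evaluates the per-capita growth of every species: baseline reproduction
#' minus the per-link harvesting cost (`r_i - n_plus_i * delta`), minus
#' intraspecific (`s_i x_i`) and interspecific competition, minus losses to
#' consumers (saturating over each consumer's own resources), plus
#' Type II-saturating consumer and mutualistic gains.
#'
#' @param comm A [community()].
#' @param x Abundance vector aligned with the roster.
#' @param params A [model_params()] object.
#' @return Numeric vector of per-capita growth rates.
#' @export
percapita_rhs <- function(comm, x, params) {
  if (length(x) != n_species(comm))
    stop("abundance vector length does not match the roster", call. = FALSE)
  rhs_percapita_cpp(as.numeric(x), comm$species$r, comm$species$s,
                    comm$M, comm$Pplus, comm$Pminus, comm$Cmat,
                    params$delta, params$h_p, params$h_m)
}

#' Relax a community to ecological equilibrium
#'
#' Integrates `dx_i/dt = x_i g_i(x)` with an adaptive Dormand-Prince 4(5)
#' stepper until the relative change of every surviving species' abundance
#' stays below `eq_rel_tol` over `eq_window` consecutive steps of size
#' `eq_dt` (relative change uses `|dx| / max(x, x_ext)` so near-zero
#' abundances do not inflate the criterion). A species whose abundance
#' falls below `x_ext` at a checkpoint is removed from the system
#' immediately: its abundance is set to zero, its partners' positive-link
#' cost counts are updated, and the equilibrium window restarts. If
#' `max_integration_time` is reached the state is returned as-is with
#' `converged = FALSE`.
#'
#' @param comm A [community()].
#' @param x Initial abundances aligned with the roster.
#' @param params A [model_params()] object.
#' @return List with `comm` (pruned roster), `state` (list `x`, `t` on the
#'   pruned roster), `converged`, and `extinct_ids`.
#' @export
integrate_to_equilibrium <- function(comm, x, params) {
  stopifnot(length(x) == n_species(comm), all(x >= 0))
  if (n_species(comm) == 0)
    return(list(comm = comm, state = list(x = numeric(0), t = 0),
                converged = TRUE, extinct_ids = integer(0)))
  res <- integrate_equilibrium_cpp(as.numeric(x), comm$species$r, comm$species$s,
                                   comm$M, comm$Pplus, comm$Pminus, comm$Cmat,
                                   params$delta, params$h_p, params$h_m,
                                   params$x_ext, params$eq_rel_tol,
                                   params$eq_window, params$eq_dt,
                                   params$max_integration_time,
                                   params$rtol, params$atol)
  dead <- res$x == 0
  extinct_ids <- comm$species$id[dead]
  if (any(dead)) comm <- prune_species(comm, extinct_ids)
  list(comm = comm, state = list(x = res$x[!dead], t = res$t),
       converged = res$converged, extinct_ids = extinct_ids)
}
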