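#' Derive per-replicate seeds from a master seed
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds.
#' @return Integer vector of distinct seeds (recorded in experiment
#'   outputs so any replicate can be re-run in isolation).
#' @export
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Heatmap sweep over cost and interaction strength
#'
#' For each `(delta, sigma)` grid cell, runs `replicates` evolutionary
#' (`Delta = 5`) assembly simulations and averages the final community
#' properties. The study-scale grid is
#' `delta = c(0.005, 0.01, 0.015, 0.02, 0.025, 0.03)`,
#' `sigma = c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25)` with 15 replicates of 500
#' events; smaller grids/replicates/events give desk-scale runs.
#'
#' @param delta_grid,sigma_grid Numeric grids.
#' @param replicates Replicates per cell.
#' @param n_events Assembly events per run.
#' @param Delta Inheritance bound for the speciation scenario.
#' @param seed Master seed (replicate seeds derived from it).
#' @param params Baseline [model_params()]; `delta`/`sigma` are overwritten
#'   per cell.
#' @param config Baseline [assembly_config()]; `n_events`/`Delta`
#'   overwritten.
#' @return Tibble, one row per cell: mean final `S`, `connectance`,
#'   `complexity`, type proportions, plus `n_ok` and `n_failed`.
#' @export
run_heatmap <- function(delta_grid = c(0.005, 0.01, 0.015, 0.02, 0.025, 0.03),
                        sigma_grid = c(0.01, 0.05, 0.1, 0.15, 0.2, 0.25),
                        replicates = 15L, n_events = 500L, Delta = 5L,
                        seed = 1L, params = model_params(),
                        config = assembly_config("evo")) {
  grid <- tidyr::expand_grid(delta = delta_grid, sigma = sigma_grid)
  config$n_events <- as.integer(n_events)
  config$Delta <- as.integer(Delta)
  config$scenario <- "evo"
  seeds <- matrix(derive_seeds(seed, nrow(grid) * replicates), nrow(grid))
  purrr::pmap_dfr(list(grid$delta, grid$sigma, seq_len(nrow(grid))),
    function(d, s, cell) {
      p <- params
      p$delta <- d
      p$sigma <- s
      finals <- purrr::map(seq_len(replicates), function(rep) {
        tryCatch(glance(run_assembly(config, p, seed = seeds[cell, rep])),
                 error = function(e) NULL)
      })
      failed <- vapply(finals, is.null, logical(1))
      ok <- dplyr::bind_rows(finals[!failed])
      summ <- dplyr::summarise(ok, dplyr::across(
        c("S", "connectance", "complexity", "prop_m", "prop_c", "prop_cr"),
        ~ mean(.x, na.rm = TRUE)))
      dplyr::bind_cols(tibble::tibble(delta = d, sigma = s), summ,
                       tibble::tibble(n_ok = sum(!failed), n_failed = sum(failed),
                                      seeds = list(seeds[cell, ])))
    })
}

#' Scenario trajectories with replicate summaries
#'
#' Runs `replicates` assemblies per scenario and summarises each snapshot
#' across replicates (mean and standard error `sd / sqrt(n)`). The standard
#' scenario set crosses community type T1 (`delta = 0.025, sigma = 0.05`,
#' weak benefits) and T2 (`delta = 0.01, sigma = 0.2`, strong benefits)
#' with four assembly mechanisms: evolution with strong (`Delta = 5`) and
#' weak (`Delta = 30`) inheritance, and the two invasion flavours.
#'
#' @param scenarios Tibble with columns `label`, `scenario`, `Delta`,
#'   `delta`, `sigma` (default: the eight-scenario set).
#' @param replicates Replicates per scenario.
#' @param n_events Assembly events per run.
#' @param snapshot_every Recording cadence.
#' @param seed Master seed.
#' @param params,config Baselines, overwritten per scenario.
#' @return List with `summary` (per scenario x snapshot means and standard
#'   errors), `finals` (per-replicate final-state rows) and `seeds`.
#' @export
run_trajectory <- function(scenarios = scenario_grid(),
                           replicates = 20L, n_events = 500L,
                           snapshot_every = 50L, seed = 1L,
                           params = model_params(),
                           config = assembly_config("evo")) {
  seeds <- matrix(derive_seeds(seed, nrow(scenarios) * replicates),
                  nrow(scenarios))
  config$n_events <- as.integer(n_events)
  config$snapshot_every <- as.integer(snapshot_every)
  rows <- list(); finals <- list()
  for (sc in seq_len(nrow(scenarios))) {
    cfg <- config
    cfg$scenario <- scenarios$scenario[sc]
    cfg$Delta <- as.integer(scenarios$Delta[sc])
    p <- params
    p$delta <- scenarios$delta[sc]
    p$sigma <- scenarios$sigma[sc]
    for (rep in seq_len(replicates)) {
      tr <- tryCatch(run_assembly(cfg, p, seed = seeds[sc, rep]),
                     error = function(e) NULL)
      if (is.null(tr)) next
      snaps <- tr$snapshots
      snaps$label <- scenarios$label[sc]
      snaps$replicate <- rep
      rows[[length(rows) + 1L]] <- snaps
      fin <- glance(tr)
      fin$label <- scenarios$label[sc]
      fin$replicate <- rep
      finals[[length(finals) + 1L]] <- fin
    }
  }
  all_snaps <- dplyr::bind_rows(rows)
  summary <- all_snaps |>
    dplyr::group_by(.data$label, .data$event) |>
    dplyr::summarise(dplyr::across(
      c("S", "connectance", "complexity", "prop_m", "prop_c", "prop_cr"),
      list(mean = ~ mean(.x, na.rm = TRUE),
           se = ~ sd(.x, na.rm = TRUE) / sqrt(sum(!is.na(.x))))),
      n = dplyr::n(), .groups = "drop")
  list(summary = summary, finals = dplyr::bind_rows(finals), seeds = seeds,
       snapshots = all_snaps)
}

#' The eight standard assembly scenarios
#'
#' Crosses community types T1 (weak benefits: `delta = 0.025`,
#' `sigma = 0.05`) and T2 (strong benefits: `delta = 0.01`, `sigma = 0.2`)
#' with four assembly mechanisms.
#'
#' @return Tibble with columns `label`, `scenario`, `Delta`, `delta`,
#'   `sigma`, `type`.
#' @export
scenario_grid <- function() {
  mech <- tibble::tibble(
    mech_label = c("evo_d5", "evo_d30", "inv_rand", "inv_prop"),
    scenario = c("evo", "evo", "inv_rand", "inv_prop"),
    Delta = c(5L, 30L, 5L, 5L))
  types <- tibble::tibble(type = c("T1", "T2"),
                          delta = c(0.025, 0.01), sigma = c(0.05, 0.2))
  out <- tidyr::expand_grid(types, mech)
  out$label <- paste(out$type, out$mech_label, sep = "_")
  out[, c("label", "scenario", "Delta", "delta", "sigma", "type")]
}

#' Macroecology comparison pipeline
#'
#' Chains assembly, stochastic (Euler-Maruyama) sampling of each final
#' community and of its no-interaction logistic null, the macroecological
#' statistics (MAD, pairwise correlations), and the relative Wasserstein
#' distance score against reference tables (empirical files or synthetic
#' fixtures).
#'
#' @param trajectories List of `assembly_trajectory` objects (or `NULL` to
#'   run `replicates` fresh assemblies with `config`/`params`).
#' @param reference_tables List of [abundance_table()] count tables (>= 2).
#' @param noise A [noise_config()].
#' @param config,params Used when `trajectories` is `NULL`.
#' @param replicates Number of fresh assemblies when `trajectories` is
#'   `NULL`.
#' @param seed Master seed.
#' @return List with `score` (interacting communities), `score_null`
#'   (logistic nulls), `per_community` tibble, and the correlation value
#'   lists.
#' @export
run_macroeco <- function(trajectories = NULL, reference_tables,
                         noise = noise_config(), config = assembly_config("evo"),
                         params = model_params(), replicates = 5L, seed = 1L) {
  stopifnot(length(reference_tables) >= 2)
  n_runs <- if (is.null(trajectories)) replicates else length(trajectories)
  seeds <- derive_seeds(seed, 2L * n_runs + n_runs)
  if (is.null(trajectories)) {
    trajectories <- purrr::map(seq_len(replicates), function(rep)
      run_assembly(config, params, seed = seeds[2L * n_runs + rep]))
  }
  emp_cors <- purrr::map(reference_tables, function(tt)
    correlation_distribution(to_relative(tt))$values)
  sim_cors <- list(); null_cors <- list(); rows <- list()
  for (k in seq_along(trajectories)) {
    tr <- trajectories[[k]]
    comm <- tr$final$comm
    x_eq <- tr$final$state$x
    if (n_species(comm) < 2) next
    sim <- simulate_em(comm, x_eq, noise, tr$params, seed = seeds[2L * k - 1L])
    nul <- simulate_logistic_null(comm, x_eq, noise, tr$params, seed = seeds[2L * k])
    sim_c <- tryCatch(correlation_distribution(to_relative(sim))$values,
                      error = function(e) NULL)
    nul_c <- tryCatch(correlation_distribution(to_relative(nul))$values,
                      error = function(e) NULL)
    if (is.null(sim_c) || is.null(nul_c)) next
    sim_cors[[length(sim_cors) + 1L]] <- sim_c
    null_cors[[length(null_cors) + 1L]] <- nul_c
    rows[[length(rows) + 1L]] <- tibble::tibble(
      community = k, S = n_species(comm),
      W_se = mean(purrr::map_dbl(emp_cors, ~ wasserstein1d(sim_c, .x))),
      W_se_null = mean(purrr::map_dbl(emp_cors, ~ wasserstein1d(nul_c, .x))))
  }
  if (!length(sim_cors)) stop("no community produced a valid correlation distribution", call. = FALSE)
  list(score = relative_distance_score(sim_cors, emp_cors),
       score_null = relative_distance_score(null_cors, emp_cors),
       per_community = dplyr::bind_rows(rows),
       sim_correlations = sim_cors, null_correlations = null_cors,
       empirical_correlations = emp_cors)
}
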