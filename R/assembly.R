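#' Generate an offspring species by speciation
#'
#' A uniformly chosen parent's pair-links are copied (types preserved,
#' strengths perturbed by [mutate_strength()]), then `d` modifications are
#' applied, with `d` drawn by [draw_change_budget()]: `n_destroy` inherited
#' links are removed and `n_create` new links are added to uniformly chosen
#' residents not already linked to the offspring (the parent is a possible
#' new partner). Destructions that are impossible (not enough inherited
#' links) convert to creations one-for-one and vice versa; if the roster
#' cannot host the creation quota the budget is truncated. The offspring's
#' `r` and `s` are freshly sampled, not inherited.
#'
#' @param comm A non-empty [community()].
#' @param config An [assembly_config()] (uses `Delta`).
#' @param params A [model_params()] object.
#' @return A candidate species: list with `r`, `s`, `parent_id`, and a
#'   `links` tibble (`partner_id`, `type`, `role`, `w_cand`, `w_partner`).
#' @export
speciate <- function(comm, config, params) {
  S <- n_species(comm)
  stopifnot(S >= 1)
  ids <- comm$species$id
  parent_pos <- sample.int(S, 1)
  parent_id <- ids[parent_pos]

  links <- inherited_links(comm, parent_pos)
  inherited_ids <- links$partner_id
  budget <- draw_change_budget(config$Delta)
  n_inherited <- nrow(links)
  # residents not linked to the offspring (parent included); destroyed pairs
  # are not re-created, so capacity is independent of the destructions
  capacity <- S - n_inherited

  n_destroy <- budget$n_destroy
  n_create <- budget$n_create
  if (n_destroy > n_inherited) {
    n_create <- n_create + (n_destroy - n_inherited)
    n_destroy <- n_inherited
  }
  if (n_create > capacity) {
    n_destroy <- min(n_inherited, n_destroy + (n_create - capacity))
    n_create <- capacity
  }
  if (n_destroy > 0)
    links <- links[-sample.int(nrow(links), n_destroy), , drop = FALSE]
  if (n_create > 0) {
    free <- setdiff(ids, inherited_ids)
    partners <- free[sample.int(length(free), n_create)]
    links <- dplyr::bind_rows(links, new_links(partners, params$sigma))
  }
  list(r = sample_growth_rate(params), s = NA_real_, parent_id = parent_id,
       links = links) |> finish_candidate(params)
}

# pair-links of the species at roster position `pos`, from its perspective
inherited_links <- function(comm, pos) {
  ids <- comm$species$id
  rows <- list()
  add <- function(partner_pos, type, role, w_cand, w_partner) {
    tibble::tibble(partner_id = ids[partner_pos], type = type, role = role,
                   w_cand = w_cand, w_partner = w_partner)
  }
  out <- list()
  mj <- which(comm$M[pos, ] > 0)
  if (length(mj))
    out$M <- add(mj, "M", "mutualist",
                 mutate_strength(comm$M[pos, mj]), mutate_strength(comm$M[mj, pos]))
  cj <- which(comm$Cmat[pos, ] > 0)
  if (length(cj))
    out$C <- add(cj, "C", "competitor",
                 mutate_strength(comm$Cmat[pos, cj]), mutate_strength(comm$Cmat[cj, pos]))
  pj <- which(comm$Pplus[pos, ] > 0) # pos consumes j
  if (length(pj)) {
    gain <- mutate_strength(comm$Pplus[pos, pj])
    loss <- mutate_strength(comm$Pminus[pj, pos])
    out$cons <- add(pj, "CR", "consumer", pmin(gain, loss), loss)
  }
  rj <- which(comm$Pminus[pos, ] > 0) # pos consumed by j
  if (length(rj)) {
    loss <- mutate_strength(comm$Pminus[pos, rj])
    gain <- mutate_strength(comm$Pplus[rj, pos])
    out$res <- add(rj, "CR", "resource", loss, pmin(gain, loss))
  }
  if (!length(out))
    return(tibble::tibble(partner_id = integer(), type = character(),
                          role = character(), w_cand = double(), w_partner = double()))
  dplyr::bind_rows(out)
}

new_links <- function(partners, sigma) {
  purrr::map_dfr(partners, function(p) {
    lk <- sample_link_type_and_strengths(sigma)
    role <- switch(lk$type, M = "mutualist", C = "competitor",
                   CR = if (isTRUE(lk$a_is_consumer)) "consumer" else "resource")
    tibble::tibble(partner_id = p, type = lk$type, role = role,
                   w_cand = lk$w_a, w_partner = lk$w_b)
  })
}

finish_candidate <- function(cand, params) {
  cand$s <- sample_self_regulation(cand$r, params)
  cand
}

#' Generate an invading species
#'
#' The invader's connectivity `rho` is drawn uniformly from
#' `[rho1, rho2]` and a link to each resident forms independently with
#' probability `rho`. Under `inv_rand` each realized link takes one of the
#' four roles (mutualist, competitor, consumer, resource) with probability
#' 1/4; under `inv_prop` a per-invader role-proportion vector is drawn
#' uniformly on the simplex (flat Dirichlet) and roles are sampled from it.
#' Strengths are half-normal with the consumer-gain cap.
#'
#' @param comm A [community()].
#' @param config An [assembly_config()] with scenario `inv_rand` or
#'   `inv_prop`.
#' @param params A [model_params()] object.
#' @return A candidate species (see [speciate()]); carries the drawn
#'   connectivity as `rho`.
#' @export
invade <- function(comm, config, params) {
  stopifnot(config$scenario %in% c("inv_rand", "inv_prop"))
  S <- n_species(comm)
  rho <- runif(1, config$rho1, config$rho2)
  linked <- runif(S) < rho
  partners <- comm$species$id[linked]
  roles <- c("mutualist", "competitor", "consumer", "resource")
  prob <- if (config$scenario == "inv_rand") rep(0.25, 4) else {
    g <- stats::rgamma(4, 1); g / sum(g) # flat Dirichlet on the simplex
  }
  n_link <- length(partners)
  role <- if (n_link > 0) sample(roles, n_link, replace = TRUE, prob = prob) else character(0)
  w_cand <- abs(rnorm(n_link, 0, params$sigma))
  w_partner <- abs(rnorm(n_link, 0, params$sigma))
  cons <- role == "consumer"
  reso <- role == "resource"
  w_cand[cons] <- pmin(w_cand[cons], w_partner[cons])
  w_partner[reso] <- pmin(w_partner[reso], w_cand[reso])
  links <- tibble::tibble(
    partner_id = partners,
    type = dplyr::case_match(role, "mutualist" ~ "M", "competitor" ~ "C",
                             .default = "CR"),
    role = role, w_cand = w_cand, w_partner = w_partner)
  cand <- list(r = sample_growth_rate(params), s = NA_real_,
               parent_id = NA_integer_, links = links, rho = rho)
  finish_candidate(cand, params)
}

#' Add a candidate species to a community
#'
#' Appends the newcomer to the roster and extends the interaction matrices,
#' preserving all pair invariants; the community is re-validated and the
#' candidate rejected (error) on violation.
#'
#' @param comm A [community()].
#' @param cand A candidate from [speciate()] or [invade()].
#' @param id Id for the new species (default: one past the maximum).
#' @param born_event Assembly-event index recorded in the roster.
#' @return The extended `community` (the newcomer is the last row).
#' @export
introduce <- function(comm, cand, id = NULL, born_event = 0L) {
  n <- n_species(comm)
  ids <- comm$species$id
  if (!all(cand$links$partner_id %in% ids))
    stop("candidate links reference unknown residents", call. = FALSE)
  if (is.null(id)) id <- if (n == 0) 1L else max(ids) + 1L
  grow <- function(A) {
    if (n == 0) return(matrix(0, 1, 1))
    rbind(cbind(A, 0), 0)
  }
  M <- grow(comm$M); Pp <- grow(comm$Pplus); Pm <- grow(comm$Pminus); Cm <- grow(comm$Cmat)
  k <- n + 1L
  lk <- cand$links
  for (row in seq_len(nrow(lk))) {
    j <- match(lk$partner_id[row], ids)
    switch(lk$role[row],
      mutualist = { M[k, j] <- lk$w_cand[row]; M[j, k] <- lk$w_partner[row] },
      competitor = { Cm[k, j] <- lk$w_cand[row]; Cm[j, k] <- lk$w_partner[row] },
      consumer = { Pp[k, j] <- lk$w_cand[row]; Pm[j, k] <- lk$w_partner[row] },
      resource = { Pm[k, j] <- lk$w_cand[row]; Pp[j, k] <- lk$w_partner[row] })
  }
  species <- dplyr::bind_rows(comm$species,
    tibble::tibble(id = as.integer(id), r = cand$r, s = cand$s,
                   parent_id = cand$parent_id %||% NA_integer_,
                   born_event = as.integer(born_event)))
  community(species, M, Pp, Pm, Cm, validate = TRUE)
}

#' Remove species with no interactions
#'
#' @param comm A [community()].
#' @return The community restricted to species holding at least one link;
#'   a fully unlinked community becomes empty.
#' @export
remove_isolated <- function(comm) {
  if (n_species(comm) == 0) return(comm)
  deg <- rowSums(comm$M > 0) + rowSums(comm$Cmat > 0) +
    rowSums(comm$Pplus > 0) + rowSums(comm$Pminus > 0)
  prune_species(comm, comm$species$id[deg == 0])
}

#' Run a full step-wise assembly simulation
#'
#' Starts from `n_init` non-interacting founder species with abundances
#' uniform on `[0, x_init_max]`, relaxes to equilibrium, then repeats for
#' `n_events` assembly events: generate a candidate (speciation or invasion
#' according to the scenario), introduce it at abundance `x0_new`, relax to
#' the new equilibrium (pruning extinctions), and after the first
#' `isolated_removal_after` events purge isolated species after every
#' event. Every introduction counts as one event whether or not the
#' newcomer survives (the survival flag is logged). Snapshots (community
#' copy plus structural metrics) are recorded every `snapshot_every` events
#' and at the final event.
#'
#' @param config An [assembly_config()].
#' @param params A [model_params()] object.
#' @param seed Optional RNG seed; runs with the same seed are identical.
#' @return An object of class `assembly_trajectory`: list with `snapshots`
#'   (tibble of structural metrics per snapshot), `communities` (list of
#'   community objects per snapshot), `events` (per-event log tibble),
#'   `final` (list `comm`, `state`), `config`, `params`, `seed`,
#'   `n_nonconverged`.
#' @export
run_assembly <- function(config, params = model_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  founders <- tibble::tibble(id = seq_len(config$n_init),
                             r = sample_growth_rate(params, config$n_init))
  founders$s <- sample_self_regulation(founders$r, params)
  founders$parent_id <- NA_integer_
  founders$born_event <- 0L
  comm <- community(founders)
  x <- runif(config$n_init, 0, config$x_init_max)
  rel <- integrate_to_equilibrium(comm, x, params)
  comm <- rel$comm; x <- rel$state$x
  next_id <- config$n_init + 1L
  n_nonconverged <- if (rel$converged) 0L else 1L

  events <- list()
  snaps <- list(); snap_comms <- list(); snap_states <- list()
  retry <- isTRUE(config$retry_failed)
  ev <- 1L
  attempt <- 1L

  while (ev <= config$n_events) {
    mech <- if (config$scenario == "evo") {
      if (config$evo_fraction >= 1 || runif(1) < config$evo_fraction) "evo" else "inv_rand"
    } else config$scenario
    if (n_species(comm) == 0) {
      # community went fully extinct: seed a fresh unlinked species
      cand <- list(r = sample_growth_rate(params), s = NA_real_,
                   parent_id = NA_integer_,
                   links = tibble::tibble(partner_id = integer(), type = character(),
                                          role = character(), w_cand = double(),
                                          w_partner = double()))
      cand <- finish_candidate(cand, params)
    } else if (mech == "evo") {
      cand <- speciate(comm, config, params)
    } else {
      cfg_inv <- config
      cfg_inv$scenario <- mech
      cand <- invade(comm, cfg_inv, params)
    }
    comm <- introduce(comm, cand, id = next_id, born_event = ev)
    new_id <- next_id
    next_id <- next_id + 1L
    x <- c(x, params$x0_new)
    rel <- integrate_to_equilibrium(comm, x, params)
    comm <- rel$comm; x <- rel$state$x
    if (!rel$converged) n_nonconverged <- n_nonconverged + 1L
    if (ev > config$isolated_removal_after) {
      pruned <- remove_isolated(comm)
      if (n_species(pruned) < n_species(comm)) {
        x <- x[comm$species$id %in% pruned$species$id]
        comm <- pruned
      }
    }
    survived <- new_id %in% comm$species$id
    events[[length(events) + 1L]] <- tibble::tibble(
      event = ev, attempt = attempt, mechanism = mech,
      parent_id = cand$parent_id %||% NA_integer_,
      rho = cand$rho %||% NA_real_,
      survived = survived,
      n_extinct = length(setdiff(rel$extinct_ids, new_id)),
      converged = rel$converged, S_after = n_species(comm))
    if (survived || !retry || attempt >= 50L) {
      if (ev %% config$snapshot_every == 0 || ev == config$n_events) {
        key <- as.character(ev)
        snaps[[key]] <- snapshot_metrics(comm, ev)
        snap_comms[[key]] <- comm
        snap_states[[key]] <- list(x = x, t = rel$state$t)
      }
      ev <- ev + 1L
      attempt <- 1L
    } else {
      attempt <- attempt + 1L
    }
  }

  structure(list(snapshots = dplyr::bind_rows(snaps),
                 communities = snap_comms, states = snap_states,
                 events = dplyr::bind_rows(events),
                 final = list(comm = comm, state = list(x = x)),
                 config = config, params = params, seed = seed,
                 n_nonconverged = n_nonconverged),
            class = "assembly_trajectory")
}

snapshot_metrics <- function(comm, ev) {
  S <- n_species(comm)
  lk <- community_links(comm)
  L <- 2L * nrow(lk)
  C <- if (S > 0) L / S^2 else NA_real_
  pr <- if (nrow(lk) > 0) interaction_type_proportions(comm) else
    c(M = NA_real_, C = NA_real_, CR = NA_real_)
  tibble::tibble(event = ev, S = S, L = L, connectance = C,
                 complexity = S * C, prop_m = pr[["M"]], prop_c = pr[["C"]],
                 prop_cr = pr[["CR"]])
}

#' @export
print.assembly_trajectory <- function(x, ...) {
  cat("<assembly_trajectory> scenario ", x$config$scenario, ", ",
      x$config$n_events, " events\n", sep = "")
  print(utils::tail(x$snapshots, 3))
  invisible(x)
}
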