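# Shared fixtures and independent oracles for the test suite.

# Random valid community: each unordered pair gets one interaction type
# (or none) with the structural invariants enforced by construction.
random_community <- function(S, p_link = 0.5, sigma = 0.2) {
  sp <- tibble::tibble(id = seq_len(S),
                       r = abs(rnorm(S, 0.1, 0.1)) + 1e-3,
                       s = abs(rnorm(S, 1, 0.3)) + 1e-3)
  M <- Pp <- Pm <- Cm <- matrix(0, S, S)
  if (S >= 2) {
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      if (runif(1) >= p_link) next
      w1 <- abs(rnorm(1, 0, sigma)) + 1e-6
      w2 <- abs(rnorm(1, 0, sigma)) + 1e-6
      type <- sample(c("M", "C", "CRij", "CRji"), 1)
      if (type == "M") { M[i, j] <- w1; M[j, i] <- w2 }
      else if (type == "C") { Cm[i, j] <- w1; Cm[j, i] <- w2 }
      else if (type == "CRij") { Pp[i, j] <- min(w1, w2); Pm[j, i] <- w2 }
      else { Pp[j, i] <- min(w1, w2); Pm[i, j] <- w2 }
    }
  }
  community(sp, M, Pp, Pm, Cm)
}

# Brute-force scalar oracle for the per-capita growth rates: plain triple
# loop over the model terms, written independently of the package's
# vectorised/compiled implementation.
rhs_oracle <- function(comm, x, params) {
  S <- n_species(comm)
  r <- comm$species$r; s <- comm$species$s
  M <- comm$M; Pp <- comm$Pplus; Pm <- comm$Pminus; Cm <- comm$Cmat
  g <- numeric(S)
  for (i in seq_len(S)) {
    nplus <- 0
    for (j in seq_len(S)) if (j != i && (M[i, j] > 0 || Pp[i, j] > 0)) nplus <- nplus + 1
    acc <- r[i] - nplus * params$delta - s[i] * x[i]
    for (j in seq_len(S)) acc <- acc - Cm[i, j] * x[j]
    for (j in seq_len(S)) {
      if (Pm[i, j] > 0) {
        den <- 1
        for (k in seq_len(S)) den <- den + params$h_p * Pp[j, k] * x[k]
        acc <- acc - Pm[i, j] * x[j] / den
      }
    }
    for (j in seq_len(S)) {
      if (Pp[i, j] > 0) {
        den <- 1
        for (k in seq_len(S)) den <- den + params$h_p * Pp[i, k] * x[k]
        acc <- acc + Pp[i, j] * x[j] / den
      }
    }
    for (j in seq_len(S)) {
      if (M[i, j] > 0) {
        den <- 1
        for (k in seq_len(S)) den <- den + params$h_m * M[i, k] * x[k]
        acc <- acc + M[i, j] * x[j] / den
      }
    }
    g[i] <- acc
  }
  g
}

# deSolve-based reference relaxation (independent integration route; no
# extinction handling, suitable for smooth test systems).
desolve_relax <- function(comm, x0, params, t_end = 2000) {
  f <- function(t, y, parms) list(y * percapita_rhs(comm, y, params))
  out <- deSolve::ode(y = x0, times = c(0, t_end), func = f, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  as.numeric(out[nrow(out), -1])
}

# Circulant mutualistic community: every species linked to its
# `half_degree` nearest neighbours on each side (degree = 2 * half_degree).
circulant_community <- function(S, half_degree) {
  sp <- tibble::tibble(id = seq_len(S), r = 0.1, s = 1)
  M <- matrix(0, S, S)
  for (i in seq_len(S)) for (off in seq_len(half_degree)) {
    j <- ((i + off - 1) %% S) + 1
    M[i, j] <- M[j, i] <- 0.1
  }
  community(sp, M = M)
}

# Symmetric difference between parent and offspring pair-link partner sets.
sym_diff_size <- function(comm, parent_id, cand) {
  pos <- match(parent_id, comm$species$id)
  deg <- (comm$M[pos, ] > 0) | (comm$Cmat[pos, ] > 0) |
    (comm$Pplus[pos, ] > 0) | (comm$Pminus[pos, ] > 0)
  parent_partners <- comm$species$id[deg]
  length(setdiff(parent_partners, cand$links$partner_id)) +
    length(setdiff(cand$links$partner_id, parent_partners))
}

# Undirected graph of two disjoint complete graphs K_n (modularity oracle).
two_cliques <- function(n) {
  g1 <- igraph::make_full_graph(n)
  igraph::disjoint_union(g1, g1)
}

# Small T1/T2 evolutionary runs shared between acceptance-style tests.
scaled_run <- function(delta, sigma, seed, n_events = 150L, Delta = 5L,
                       scenario = "evo") {
  cfg <- assembly_config(scenario, Delta = Delta, n_events = n_events)
  p <- model_params(delta = delta, sigma = sigma)
  run_assembly(cfg, p, seed = seed)
}
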