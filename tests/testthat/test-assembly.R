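test_that("offspring differ from a 20-link parent by a uniform number of links", {
  # circulant mutualistic network: every species has exactly 20 links, so
  # every speciation draws a 20-link parent
  comm <- circulant_community(41, half_degree = 10)
  cfg <- assembly_config("evo", Delta = 5L)
  params <- model_params(sigma = 0.2)
  set.seed(42)
  diffs <- replicate(2000, {
    cand <- speciate(comm, cfg, params)
    sym_diff_size(comm, cand$parent_id, cand)
  })
  expect_true(all(diffs >= 1 & diffs <= 5))
  chi <- suppressWarnings(stats::chisq.test(table(factor(diffs, levels = 1:5))))
  expect_gt(chi$p.value, 0.001)
})

test_that("isolated parents still yield offspring with links", {
  sp <- tibble::tibble(id = 1:5, r = 0.1, s = 1)
  comm <- community(sp)
  cfg <- assembly_config("evo", Delta = 5L)
  params <- model_params()
  set.seed(9)
  for (k in 1:50) {
    cand <- speciate(comm, cfg, params)
    expect_gte(nrow(cand$links), 1)
    expect_lte(nrow(cand$links), 5)
    expect_false(anyDuplicated(cand$links$partner_id) > 0)
  }
})

test_that("speciated candidates always satisfy the trophic constraint", {
  set.seed(13)
  cfg <- assembly_config("evo", Delta = 5L)
  params <- model_params(sigma = 0.3)
  for (k in 1:40) {
    comm <- random_community(8, p_link = 0.6)
    cand <- speciate(comm, cfg, params)
    cr <- cand$links[cand$links$type == "CR", ]
    if (nrow(cr)) {
      gain <- ifelse(cr$role == "consumer", cr$w_cand, cr$w_partner)
      loss <- ifelse(cr$role == "consumer", cr$w_partner, cr$w_cand)
      expect_true(all(gain <= loss))
    }
    expect_true(all(cand$links$w_cand >= 0 & cand$links$w_partner >= 0))
    expect_gt(cand$r, 0)
    expect_gt(cand$s, 0)
  }
})

test_that("invaders connect at the drawn connectivity with the right roles", {
  sp <- tibble::tibble(id = 1:10, r = 0.1, s = 1)
  comm <- community(sp)
  params <- model_params()
  # certain connection: rho1 = rho2 = 1 gives exactly S links
  cfg <- assembly_config("inv_rand", rho1 = 1 - 1e-12, rho2 = 1)
  set.seed(31)
  cand <- invade(comm, cfg, params)
  expect_identical(nrow(cand$links), 10L)
  # role frequencies ~ 1/4 each under inv_rand
  cfg <- assembly_config("inv_rand", rho1 = 0.999999, rho2 = 1)
  roles <- unlist(replicate(800, invade(comm, cfg, params)$links$role))
  freq <- table(roles) / length(roles)
  expect_equal(unname(freq[c("mutualist", "competitor", "consumer", "resource")]),
               rep(0.25, 4), tolerance = 0.08, ignore_attr = TRUE)
})

test_that("inv_prop role proportions have the flat-simplex variance", {
  sp <- tibble::tibble(id = seq_len(40), r = 0.1, s = 1)
  comm <- community(sp)
  cfg <- assembly_config("inv_prop", rho1 = 0.999999, rho2 = 1)
  params <- model_params()
  set.seed(77)
  prop_mut <- replicate(2000, {
    cand <- invade(comm, cfg, params)
    mean(cand$links$role == "mutualist")
  })
  # Dirichlet(1,1,1,1) marginal is Beta(1,3): var = 3/80; the per-link
  # multinomial sampling adds p(1-p)/n averaging to E[p(1-p)]/40
  extra <- (0.25 - (3 / 80 + 1 / 16)) / 40
  expect_equal(var(prop_mut), 3 / 80 + extra, tolerance = 0.08)
  expect_equal(mean(prop_mut), 0.25, tolerance = 0.03)
})

test_that("introduction extends the community and rejects bad candidates", {
  sp <- tibble::tibble(id = 1:3, r = 0.1, s = 1)
  comm <- community(sp)
  cand <- list(r = 0.1, s = 1, parent_id = NA_integer_,
               links = tibble::tibble(partner_id = 2L, type = "CR",
                                      role = "consumer", w_cand = 0.1,
                                      w_partner = 0.3))
  out <- introduce(comm, cand, born_event = 7L)
  expect_identical(n_species(out), 4L)
  k <- 4; j <- 2
  expect_equal(out$Pplus[k, j], 0.1)
  expect_equal(out$Pminus[j, k], 0.3)
  expect_identical(out$species$born_event[4], 7L)
  # violated efficiency constraint is rejected
  bad <- cand
  bad$links$w_cand <- 0.5
  expect_error(introduce(comm, bad), "efficiency")
  # unknown partner is rejected
  bad2 <- cand
  bad2$links$partner_id <- 99L
  expect_error(introduce(comm, bad2), "unknown residents")
  # empty community accepts an unlinked founder
  empty <- prune_species(comm, 1:3)
  cand0 <- list(r = 0.1, s = 1, parent_id = NA_integer_,
                links = cand$links[0, ])
  expect_identical(n_species(introduce(empty, cand0)), 1L)
})

test_that("isolated species are purged, linked ones kept", {
  set.seed(15)
  comm <- random_community(6, p_link = 1) # fully connected
  expect_identical(remove_isolated(comm)$species$id, comm$species$id)
  lonely <- community(tibble::tibble(id = 1:5, r = 0.1, s = 1))
  expect_identical(n_species(remove_isolated(lonely)), 0L)
  # mixed: add two isolated species to a linked pair
  sp <- tibble::tibble(id = 1:4, r = 0.1, s = 1)
  M <- matrix(0, 4, 4); M[1, 2] <- M[2, 1] <- 0.1
  mixed <- community(sp, M = M)
  expect_identical(remove_isolated(mixed)$species$id, 1:2)
})

test_that("assembly trajectories are reproducible and structurally valid", {
  cfg <- assembly_config("inv_rand", n_events = 25L, snapshot_every = 5L)
  params <- model_params(delta = 0.01, sigma = 0.2)
  tr1 <- run_assembly(cfg, params, seed = 123)
  tr2 <- run_assembly(cfg, params, seed = 123)
  expect_identical(tr1$snapshots, tr2$snapshots)
  expect_identical(tr1$events, tr2$events)
  expect_identical(tr1$final$state$x, tr2$final$state$x)
  # snapshot indices strictly increasing; invariants hold in every snapshot
  expect_true(all(diff(tr1$snapshots$event) > 0))
  for (cm in tr1$communities) expect_silent(validate_community(cm))
  # event log is complete
  expect_identical(nrow(tr1$events), 25L)
  expect_true(all(tr1$events$mechanism == "inv_rand"))
  expect_true(all(!is.na(tr1$events$rho)))
})

test_that("a single evolutionary event descends from a founder", {
  cfg <- assembly_config("evo", Delta = 5L, n_events = 1L)
  params <- model_params()
  tr <- run_assembly(cfg, params, seed = 99)
  ev <- tr$events
  expect_identical(nrow(ev), 1L)
  expect_true(ev$parent_id %in% 1:5)
  expect_identical(ev$mechanism, "evo")
})
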