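test_that("noise-free stochastic integration stays at the ODE equilibrium", {
  comm <- community(tibble::tibble(id = 1L, r = 0.1, s = 1))
  params <- model_params()
  # at the exact fixed point K = r/s the drift vanishes identically
  cfg <- noise_config(sd = 0, dt = 1e-3, burn_in = 5, spacing = 0.5, n_samples = 20)
  tab <- simulate_em(comm, 0.1, cfg, params)
  expect_true(all(abs(tab$values - 0.1) < 1e-9))
  # Euler error shrinks with dt (Richardson-style check at t = 1)
  x0 <- 0.08
  ref <- desolve_relax(comm, x0, params, t_end = 1)
  drift_at <- function(dt) {
    cfg <- noise_config(sd = 0, dt = dt, burn_in = 0, spacing = 0.5, n_samples = 2)
    abs(simulate_em(comm, x0, cfg, params)$values[2, 1] - ref)
  }
  expect_lt(drift_at(5e-4), drift_at(1e-2))
})

test_that("noisy logistic species fluctuates around its carrying capacity", {
  comm <- community(tibble::tibble(id = 1L, r = 0.1, s = 1))
  params <- model_params()
  cfg <- noise_config(sd = 0.05, dt = 1e-3, burn_in = 20, spacing = 0.5,
                      n_samples = 2000)
  tab <- simulate_em(comm, 0.1, cfg, params, seed = 42)
  expect_lt(abs(mean(tab$values) - 0.1) / 0.1, 0.05)
  # fixed seed reproduces the table exactly
  tab2 <- simulate_em(comm, 0.1, cfg, params, seed = 42)
  expect_identical(tab$values, tab2$values)
})

test_that("the logistic null removes interactions and correlations", {
  set.seed(61)
  sp <- tibble::tibble(id = 1:6, r = runif(6, 0.1, 0.2), s = runif(6, 0.8, 1.5))
  M <- matrix(0, 6, 6); M[1, 2] <- M[2, 1] <- 0.1; M[3, 4] <- M[4, 3] <- 0.1
  comm <- community(sp, M = M)
  params <- model_params(delta = 0.005)
  x_eq <- comm$species$r / comm$species$s
  # sample spacing well above the relaxation time 1/r so records decorrelate
  cfg <- noise_config(sd = 0.1, dt = 1e-3, burn_in = 30, spacing = 10,
                      n_samples = 300)
  nul <- simulate_logistic_null(comm, x_eq, cfg, params, seed = 7)
  # species means near their K_i, allowing the multiplicative-noise
  # depression of the stationary mean (~ K (1 - sd^2 / 2r))
  K <- comm$species$r / comm$species$s
  expect_true(all(abs(colMeans(nul$values) - K) / K < 0.12))
  # correlations on the absolute trajectories concentrate near zero
  cors <- cor(nul$values)[upper.tri(diag(6))]
  expect_lt(mean(abs(cors)), 0.1)
  # with no links the null equals the interacting simulation
  lonely <- community(tibble::tibble(id = 1:3, r = 0.1, s = 1))
  a <- simulate_em(lonely, rep(0.1, 3), cfg, params, seed = 5)
  b <- simulate_logistic_null(lonely, rep(0.1, 3), cfg, params, seed = 5)
  expect_identical(a$values, b$values)
})

test_that("relative abundance conversion normalises rows", {
  tab <- abundance_table(matrix(c(1, 3, 2, 2), 2, 2, byrow = TRUE))
  rel <- to_relative(tab)
  expect_equal(rel$values[1, ], c(t1 = 0.25, t2 = 0.75))
  expect_equal(unname(rowSums(rel$values)), c(1, 1))
  expect_true(rel$is_relative)
  one <- to_relative(abundance_table(matrix(5, 3, 1)))
  expect_true(all(one$values == 1))
  bad <- abundance_table(matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE))
  expect_error(to_relative(bad), "zero total")
})

test_that("standardised MAD of a lognormal fixture is standard normal", {
  tab <- generate_fixture_table(500, 40, reads_per_sample = 2e4, sdlog = 2,
                                seed = 31)
  mad <- mad_standardized(to_relative(tab))
  expect_equal(mean(mad$values), 0, tolerance = 1e-8)
  expect_equal(sd(mad$values), 1, tolerance = 1e-8)
  ks <- suppressWarnings(stats::ks.test(mad$values, "pnorm"))
  expect_gt(ks$p.value, 0.001)
  # density integrates to ~1
  expect_equal(sum(mad$density) * mad$bin_width, 1, tolerance = 0.01)
  # an extra all-zero taxon raises the exclusion count by exactly one
  base_excl <- mad$n_excluded
  vals <- to_relative(tab)$values
  vals2 <- cbind(vals, 0) / rowSums(cbind(vals, 0))
  tab2 <- abundance_table(vals2, is_relative = TRUE)
  expect_identical(mad_standardized(tab2)$n_excluded, base_excl + 1L)
  # degenerate: identical means signalled
  flat <- abundance_table(matrix(0.25, 4, 4), is_relative = TRUE)
  expect_error(mad_standardized(flat), "zero-variance")
})

test_that("pairwise correlation distribution behaves on known inputs", {
  # proportional taxa stay proportional after row normalisation: rho = 1
  set.seed(70)
  base <- runif(10, 1, 5)
  v <- cbind(base, 2 * base, runif(10, 1, 5))
  cd <- correlation_distribution(abundance_table(v))
  expect_identical(length(cd$values), 3L)
  pair12 <- cor(v[, 1] / rowSums(v), v[, 2] / rowSums(v))
  expect_equal(pair12, 1)
  expect_true(any(abs(cd$values - 1) < 1e-12))
  # independent noise: distribution centred at zero
  set.seed(71)
  big <- abundance_table(matrix(rlnorm(200 * 50, 0, 0.3), 200, 50))
  cd2 <- correlation_distribution(big)
  expect_identical(length(cd2$values), as.integer(choose(50, 2)))
  se <- sd(cd2$values) / sqrt(length(cd2$values))
  expect_lt(abs(mean(cd2$values)), max(3 * se, 0.03))
})

test_that("wasserstein distance matches hand computations and metric axioms", {
  expect_equal(wasserstein1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein1d(0, 2.5), 2.5)
  expect_equal(wasserstein1d(c(0, 0, 1), c(1, 1, 1)), 2 / 3)
  # translation moves mass by the shift
  expect_equal(wasserstein1d(c(0, 1), c(5, 6)), 5)
  set.seed(81)
  for (k in 1:25) {
    a <- rnorm(sample(2:30, 1)); b <- rnorm(sample(2:30, 1)); c <- rnorm(sample(2:30, 1))
    dab <- wasserstein1d(a, b); dba <- wasserstein1d(b, a)
    expect_equal(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dab, wasserstein1d(a, c) + wasserstein1d(c, b) + 1e-12)
    expect_equal(wasserstein1d(a, a), 0)
  }
})

test_that("relative distance score compares simulated and empirical sets", {
  # constructed point masses: W_ee = 1 (distances |0-1|), W_se = 2
  emp <- list(rep(0, 5), rep(1, 5))
  sim <- list(rep(-1.5, 5), rep(2.5, 5))
  sc <- relative_distance_score(sim, emp)
  expect_equal(sc$W_ee, 1)
  expect_equal(sc$W_se, 2)
  expect_equal(sc$score, 1)
  # identical lists: W_ee = 0 signalled
  expect_error(relative_distance_score(sim, list(rep(0, 3), rep(0, 3))), "zero")
  # score bounded below by -1
  sc2 <- relative_distance_score(list(rep(0.5, 4)), emp)
  expect_gte(sc2$score, -1)
})

test_that("abundance tables round-trip and filter shallow samples", {
  tab <- generate_fixture_table(30, 8, reads_per_sample = 12000, seed = 91)
  expect_identical(dim(tab$values), c(8L, 30L))
  expect_true(all(rowSums(tab$values) == 12000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, path)
  back <- load_abundance_table(path, min_reads = 0, orientation = "samples_by_taxa")
  expect_equal(unname(back$values), unname(tab$values))
  # a shallow sample is dropped at the default threshold
  vals <- tab$values
  vals[3, ] <- round(vals[3, ] * 9999 / 12000)
  shallow <- abundance_table(vals)
  write_abundance_table(shallow, path)
  filt <- load_abundance_table(path, min_reads = 10000, orientation = "samples_by_taxa")
  expect_identical(attr(filt, "n_dropped"), 1L)
  expect_identical(nrow(filt$values), 7L)
  expect_error(load_abundance_table(path, min_reads = 1e9), "no samples")
  # taxa-by-samples orientation auto-detected when taxa outnumber samples
  t_path <- withr::local_tempfile(fileext = ".tsv")
  df <- tibble::as_tibble(t(tab$values))
  df <- dplyr::bind_cols(tibble::tibble(taxon = tab$taxa_ids), df)
  readr::write_tsv(df, t_path)
  auto <- load_abundance_table(t_path, min_reads = 0)
  expect_identical(dim(auto$values), dim(tab$values))
  expect_equal(unname(auto$values), unname(tab$values))
})
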