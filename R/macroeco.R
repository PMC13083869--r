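#' Abundance table constructor
#'
#' Samples-by-taxa non-negative matrix with ids, used both for simulated
#' time series and for empirical count tables.
#'
#' @param values Numeric matrix, samples in rows.
#' @param taxa_ids,sample_ids Optional identifiers.
#' @param is_relative Are rows normalised to sum to one?
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, taxa_ids = NULL, sample_ids = NULL,
                            is_relative = FALSE) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("abundance values must be non-negative", call. = FALSE)
  if (is.null(taxa_ids)) taxa_ids <- colnames(values) %||% paste0("t", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  if (is_relative) {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9)) stop("relative table rows must sum to 1", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, taxa_ids)
  structure(list(values = values, taxa_ids = as.character(taxa_ids),
                 sample_ids = as.character(sample_ids), is_relative = is_relative),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " taxa", if (x$is_relative) " (relative)", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.abundance_table <- function(x, ...) as.data.frame(x$values)

#' Stochastic abundance time series around an equilibrium
#'
#' Integrates `dx_i = x_i g_i(x) dt + sd * x_i dW_i` with the
#' Euler-Maruyama scheme starting from the community equilibrium: Gaussian
#' environmental noise applied independently to each species, proportional
#' to its abundance. Negative excursions are clipped to 0 (absorbing, as
#' both terms are proportional to abundance). Samples are recorded at
#' evenly spaced non-overlapping intervals after a burn-in; recorded values
#' below the extinction threshold appear as 0, but no species is pruned.
#'
#' @param comm A [community()].
#' @param x_eq Equilibrium abundances aligned with the roster.
#' @param cfg A [noise_config()].
#' @param params A [model_params()] object.
#' @param seed Optional RNG seed.
#' @return An [abundance_table()] (counts are continuous abundances).
#' @export
simulate_em <- function(comm, x_eq, cfg = noise_config(), params = model_params(),
                        seed = NULL) {
  stopifnot(length(x_eq) == n_species(comm))
  if (!is.null(seed)) set.seed(seed)
  vals <- em_simulate_cpp(as.numeric(x_eq), comm$species$r, comm$species$s,
                          comm$M, comm$Pplus, comm$Pminus, comm$Cmat,
                          params$delta, params$h_p, params$h_m,
                          cfg$sd, cfg$dt, cfg$burn_in, cfg$spacing,
                          cfg$n_samples, params$x_ext)
  abundance_table(vals, taxa_ids = as.character(comm$species$id))
}

#' No-interaction (logistic) stochastic null
#'
#' Same stochastic integration as [simulate_em()] but with every
#' interspecific interaction removed, keeping only intrinsic growth and
#' intraspecific competition. Surviving species are first placed at their
#' logistic equilibrium `K_i = r_i / s_i` (the exact no-interaction fixed
#' point) before the stochastic burn-in, so sampling starts from the new
#' equilibrium.
#'
#' @inheritParams simulate_em
#' @return An [abundance_table()].
#' @export
simulate_logistic_null <- function(comm, x_eq, cfg = noise_config(),
                                   params = model_params(), seed = NULL) {
  stopifnot(length(x_eq) == n_species(comm))
  null_comm <- comm
  n <- n_species(comm)
  null_comm$M <- null_comm$Pplus <- null_comm$Pminus <- null_comm$Cmat <- matrix(0, n, n)
  x0 <- ifelse(x_eq > 0, comm$species$r / comm$species$s, 0)
  simulate_em(null_comm, x0, cfg, params, seed = seed)
}

#' Convert counts to relative abundances
#'
#' @param tab An [abundance_table()] with positive row sums.
#' @return The row-normalised [abundance_table()] (`is_relative = TRUE`).
#' @export
to_relative <- function(tab) {
  rs <- rowSums(tab$values)
  if (any(rs <= 0)) stop("cannot normalise samples with zero total abundance", call. = FALSE)
  abundance_table(tab$values / rs, tab$taxa_ids, tab$sample_ids, is_relative = TRUE)
}

#' Standardised log-mean abundance distribution (MAD)
#'
#' Per-taxon mean relative abundance across samples, log-transformed and
#' z-scored across taxa; taxa with zero mean abundance are excluded (and
#' counted). The density is a normalised histogram with Freedman-Diaconis
#' bins; the raw standardised values are retained.
#'
#' @param tab A relative [abundance_table()] with at least 2 taxa of
#'   non-zero mean.
#' @return A `dist_summary`: list with `values`, `grid` (bin midpoints),
#'   `density`, and `n_excluded`.
#' @export
mad_standardized <- function(tab) {
  if (!tab$is_relative) stop("MAD requires a relative abundance table", call. = FALSE)
  mu <- colMeans(tab$values)
  excl <- sum(mu == 0)
  mu <- mu[mu > 0]
  if (length(mu) < 2) stop("need at least 2 taxa with non-zero mean abundance", call. = FALSE)
  lv <- log(mu)
  if (sd(lv) == 0) stop("all taxa have identical mean abundance: zero-variance MAD", call. = FALSE)
  z <- (lv - mean(lv)) / sd(lv)
  dist_summary(z, n_excluded = excl)
}

#' Distribution of pairwise abundance correlations
#'
#' Pearson correlation of relative abundances for every unordered taxon
#' pair; pairs involving a zero-variance taxon are excluded.
#'
#' @param tab An [abundance_table()] with >= 2 taxa and >= 3 samples
#'   (converted to relative abundances if not already).
#' @param method Correlation estimator passed to [stats::cor()].
#' @return A `dist_summary` over the correlation coefficients.
#' @export
correlation_distribution <- function(tab, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!tab$is_relative) tab <- to_relative(tab)
  v <- tab$values
  stopifnot(ncol(v) >= 2, nrow(v) >= 3)
  keep <- apply(v, 2, sd) > 0
  v <- v[, keep, drop = FALSE]
  if (ncol(v) < 2) stop("fewer than 2 taxa with non-zero variance", call. = FALSE)
  cm <- cor(v, method = method)
  vals <- cm[upper.tri(cm)]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 1) stop("no valid taxon pairs", call. = FALSE)
  dist_summary(vals, n_excluded = sum(!keep))
}

# density summary: normalised Freedman-Diaconis histogram + raw values
dist_summary <- function(values, n_excluded = 0L) {
  h <- graphics::hist(values, breaks = "FD", plot = FALSE)
  structure(list(values = values, grid = h$mids, density = h$density,
                 bin_width = diff(h$breaks)[1], n_excluded = n_excluded),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat("<dist_summary> n = ", length(x$values), ", mean = ",
      signif(mean(x$values), 4), ", sd = ", signif(sd(x$values), 4),
      if (x$n_excluded > 0) paste0(" (", x$n_excluded, " taxa excluded)"),
      "\n", sep = "")
  invisible(x)
}

#' 1-D Wasserstein distance between two empirical distributions
#'
#' The 1-Wasserstein (earth mover's) distance: the L1 distance between the
#' two empirical quantile functions, i.e. the total probability mass
#' displacement needed to match the distributions.
#'
#' @param a,b Non-empty numeric vectors of samples.
#' @return Non-negative distance.
#' @export
wasserstein1d <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  a <- sort(a); b <- sort(b)
  all_v <- sort(c(a, b))
  if (length(all_v) < 2) return(0)
  dx <- diff(all_v)
  grid <- all_v[-length(all_v)]
  cdf_a <- findInterval(grid, a) / length(a)
  cdf_b <- findInterval(grid, b) / length(b)
  sum(abs(cdf_a - cdf_b) * dx)
}

#' Relative simulated-vs-empirical distance score
#'
#' `(W_se - W_ee) / W_ee`, where `W_se` is the mean Wasserstein distance
#' over all simulated x empirical pairs of correlation (or MAD) value
#' lists, and `W_ee` the mean over all distinct empirical pairs. 1 means
#' the typical simulated-empirical distance is twice the typical
#' empirical-empirical distance; 0 means simulations are as close to the
#' data as the data are to themselves.
#'
#' @param sim_lists List (>= 1) of numeric value vectors from simulations.
#' @param emp_lists List (>= 2) of numeric value vectors from empirical
#'   samples.
#' @return List with `score`, `W_se`, `W_ee`.
#' @export
relative_distance_score <- function(sim_lists, emp_lists) {
  stopifnot(length(sim_lists) >= 1, length(emp_lists) >= 2)
  W_se <- mean(unlist(purrr::map(sim_lists, function(sv)
    purrr::map_dbl(emp_lists, ~ wasserstein1d(sv, .x)))))
  ee <- utils::combn(length(emp_lists), 2)
  W_ee <- mean(apply(ee, 2, function(ij)
    wasserstein1d(emp_lists[[ij[1]]], emp_lists[[ij[2]]])))
  if (W_ee == 0) stop("empirical-empirical mean distance is zero; score undefined", call. = FALSE)
  list(score = (W_se - W_ee) / W_ee, W_se = W_se, W_ee = W_ee)
}

#' Load a taxon-abundance count table
#'
#' Reads a TSV/CSV table (delimiter chosen by extension), auto-detecting
#' orientation: if the first column is non-numeric it is taken as ids; a
#' table with more rows than columns is assumed taxa-by-samples (the OTU
#' convention) and transposed, otherwise rows are samples. Samples with
#' fewer than `min_reads` total reads are dropped.
#'
#' @param path File path.
#' @param min_reads Minimum per-sample read total (default 10000).
#' @param orientation `"auto"`, `"samples_by_taxa"` or `"taxa_by_samples"`.
#' @return An [abundance_table()] of counts, with attributes `n_kept` and
#'   `n_dropped`.
#' @export
load_abundance_table <- function(path, min_reads = 10000,
                                 orientation = c("auto", "samples_by_taxa",
                                                 "taxa_by_samples")) {
  orientation <- match.arg(orientation)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) stop("empty abundance table: ", path, call. = FALSE)
  first_numeric <- is.numeric(df[[1]])
  row_ids <- if (!first_numeric) as.character(df[[1]]) else paste0("r", seq_len(nrow(df)))
  if (!first_numeric) df <- df[, -1, drop = FALSE]
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("abundance table has non-numeric count columns", call. = FALSE)
  m <- as.matrix(df)
  rownames(m) <- row_ids
  if (orientation == "auto")
    orientation <- if (nrow(m) > ncol(m)) "taxa_by_samples" else "samples_by_taxa"
  if (orientation == "taxa_by_samples") m <- t(m)
  totals <- rowSums(m)
  keep <- totals >= min_reads
  if (!any(keep)) stop("no samples with at least ", min_reads, " reads", call. = FALSE)
  tab <- abundance_table(m[keep, , drop = FALSE])
  attr(tab, "n_kept") <- sum(keep)
  attr(tab, "n_dropped") <- sum(!keep)
  tab
}

#' Write an abundance table to TSV
#'
#' Samples-by-taxa orientation with a leading `sample_id` column;
#' round-trips exactly through [load_abundance_table()] (with
#' `orientation = "samples_by_taxa"` when taxa outnumber samples).
#'
#' @param tab An [abundance_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(tab, path) {
  df <- tibble::as_tibble(tab$values)
  df <- dplyr::bind_cols(tibble::tibble(sample_id = tab$sample_ids), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Generate a synthetic microbiome-like count table
#'
#' Statistical stand-in for an OTU table: per-taxon mean abundances drawn
#' from a lognormal, optional per-sample multiplicative lognormal
#' fluctuations, and per-sample multinomial sampling at fixed read depth.
#' Emulates the lognormal-ish abundance spectrum and fixed sequencing
#' depth of real tables so the empirical-facing statistics can be exercised
#' offline; it has no true ecological interactions.
#'
#' @param n_taxa,n_samples,reads_per_sample Table dimensions and depth.
#' @param meanlog,sdlog Lognormal parameters of the taxon means.
#' @param fluct_sdlog Sd (log scale) of per-sample, per-taxon multiplicative
#'   fluctuations (0 = none).
#' @param seed Optional RNG seed.
#' @return An [abundance_table()] of integer counts.
#' @export
generate_fixture_table <- function(n_taxa, n_samples, reads_per_sample = 10000,
                                   meanlog = 0, sdlog = 2, fluct_sdlog = 0,
                                   seed = NULL) {
  stopifnot(n_taxa >= 1, n_samples >= 1, reads_per_sample >= 1)
  if (!is.null(seed)) set.seed(seed)
  lambda <- rlnorm(n_taxa, meanlog, sdlog)
  counts <- matrix(0L, n_samples, n_taxa)
  for (smp in seq_len(n_samples)) {
    lam <- lambda
    if (fluct_sdlog > 0) lam <- lam * rlnorm(n_taxa, 0, fluct_sdlog)
    counts[smp, ] <- as.integer(rmultinom(1, reads_per_sample, lam / sum(lam)))
  }
  abundance_table(counts)
}
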