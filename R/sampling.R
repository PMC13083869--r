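#' Draw an intrinsic growth rate
#'
#' By default draws from the half-normal `|N(mu_r, sigma_r^2)|`, which
#' guarantees the positivity the dynamics require; with
#' `growth_dist = "normal"` a plain normal is drawn and non-positive values
#' are resampled.
#'
#' @param params A [model_params()] object.
#' @param n Number of draws.
#' @return Strictly positive growth rate(s).
#' @export
sample_growth_rate <- function(params, n = 1) {
  draw <- function(m) {
    z <- rnorm(m, params$mu_r, params$sigma_r)
    if (params$growth_dist == "halfnormal") abs(z) else z
  }
  r <- draw(n)
  bad <- which(r <= 0)
  while (length(bad)) {
    r[bad] <- draw(length(bad))
    bad <- which(r <= 0)
  }
  r
}

#' Draw an intraspecific competition coefficient
#'
#' The coefficient is set so that the carrying capacity `K = r / s` follows
#' a lognormal distribution with underlying parameters `K_log_mu`,
#' `K_log_sigma`.
#'
#' @param r Intrinsic growth rate(s), positive.
#' @param params A [model_params()] object.
#' @return Positive coefficient(s) `s = r / K`.
#' @export
sample_self_regulation <- function(r, params) {
  stopifnot(all(r > 0))
  K <- rlnorm(length(r), params$K_log_mu, params$K_log_sigma)
  r / K
}

#' Draw the interaction type and both directed strengths for a new link
#'
#' The sign of each directed effect is chosen independently with
#' probability 1/2: (+,+) gives mutualism, (-,-) competition, and mixed
#' signs a consumer-resource link (the endpoint receiving the positive
#' effect is the consumer). Strengths are independent draws from the
#' half-normal `|N(0, sigma^2)|`; for consumer-resource links the consumer
#' gain is capped at the resource loss (trophic inefficiency).
#'
#' @param sigma Interaction-strength scale.
#' @return List with `type` (`"M"`, `"C"`, `"CR"`), `w_a`, `w_b` (the
#'   directed strengths experienced by endpoints a and b: entries of the
#'   a-row and b-row of the relevant matrix), and for CR links
#'   `a_is_consumer`.
#' @export
sample_link_type_and_strengths <- function(sigma) {
  signs <- runif(2) < 0.5 # TRUE = positive effect received by that endpoint
  w <- abs(rnorm(2, 0, sigma))
  if (signs[1] && signs[2]) {
    list(type = "M", w_a = w[1], w_b = w[2], a_is_consumer = NA)
  } else if (!signs[1] && !signs[2]) {
    list(type = "C", w_a = w[1], w_b = w[2], a_is_consumer = NA)
  } else {
    a_cons <- signs[1]
    gain <- w[1]; loss <- w[2]
    if (!a_cons) { gain <- w[2]; loss <- w[1] }
    if (gain > loss) gain <- loss
    if (a_cons) list(type = "CR", w_a = gain, w_b = loss, a_is_consumer = TRUE)
    else        list(type = "CR", w_a = loss, w_b = gain, a_is_consumer = FALSE)
  }
}

#' Mutate an inherited interaction strength
#'
#' Offspring strength is `w * |1 + e|` with `e ~ N(0, (0.05 w)^2)`: small
#' multiplicative variation around the parent's value; zero stays zero.
#'
#' @param w Parent strength(s), non-negative.
#' @return Mutated strength(s), non-negative.
#' @export
mutate_strength <- function(w) {
  stopifnot(all(w >= 0))
  w * abs(1 + rnorm(length(w), 0, 0.05 * w))
}

#' Draw the interaction-change budget for a speciation event
#'
#' The total number of pair-link modifications `d` is uniform on
#' `{1, ..., Delta}`; the number created is uniform on `{1, ..., d}` and the
#' rest are destructions.
#'
#' @param Delta Maximum number of changes.
#' @return List with `d`, `n_create` (>= 1) and `n_destroy`.
#' @export
draw_change_budget <- function(Delta) {
  stopifnot(Delta >= 1)
  d <- sample.int(Delta, 1)
  n_create <- sample.int(d, 1)
  list(d = d, n_create = n_create, n_destroy = d - n_create)
}
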