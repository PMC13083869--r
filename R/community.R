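#' Create a community
#'
#' A community holds the species roster (a tibble with columns `id`, `r`,
#' `s`, `parent_id`, `born_event`) and four directed interaction-strength
#' matrices aligned with it: `M` (mutualism, `M[i, j]` = benefit of `j` to
#' `i`), `Pplus` (consumer gains, `Pplus[i, j] > 0` when `i` consumes `j`),
#' `Pminus` (resource losses, `Pminus[i, j] > 0` when `i` is consumed by
#' `j`) and `Cmat` (interspecific competition). Each unordered species pair
#' carries at most one interaction type; consumer-resource pairs satisfy the
#' trophic-inefficiency constraint `Pplus[i, j] <= Pminus[j, i]`.
#'
#' @param species Tibble with columns `id` (unique integers), `r`, `s` and
#'   optionally `parent_id`, `born_event`.
#' @param M,Pplus,Pminus,Cmat Square non-negative matrices with zero
#'   diagonals; defaults are all-zero matrices (no interactions).
#' @param validate Check the structural invariants (default `TRUE`).
#' @return An object of class `community`.
#' @export
community <- function(species, M = NULL, Pplus = NULL, Pminus = NULL,
                      Cmat = NULL, validate = TRUE) {
  species <- tibble::as_tibble(species)
  if (!all(c("id", "r", "s") %in% names(species)))
    stop("`species` needs columns id, r, s", call. = FALSE)
  if (!"parent_id" %in% names(species)) species$parent_id <- NA_integer_
  if (!"born_event" %in% names(species)) species$born_event <- 0L
  species$id <- as.integer(species$id)
  n <- nrow(species)
  zmat <- function(A) {
    if (is.null(A)) A <- matrix(0, n, n)
    stopifnot(is.matrix(A), nrow(A) == n, ncol(A) == n)
    unname(A)
  }
  comm <- structure(list(species = species, M = zmat(M), Pplus = zmat(Pplus),
                         Pminus = zmat(Pminus), Cmat = zmat(Cmat)),
                    class = "community")
  if (validate) validate_community(comm)
  comm
}

#' Number of species in a community
#' @param comm A `community`.
#' @return Integer species richness.
#' @export
n_species <- function(comm) nrow(comm$species)

#' Validate the structural invariants of a community
#'
#' Checks non-negativity, zero diagonals, symmetric support of the
#' mutualism and competition matrices, consumer-resource pairing
#' (`Pplus[i, j] > 0` iff `Pminus[j, i] > 0`) with the efficiency constraint
#' `Pplus[i, j] <= Pminus[j, i]`, at most one interaction type per unordered
#' pair, and uniqueness/positivity of the roster columns.
#'
#' @param comm A `community`.
#' @return `comm`, invisibly; errors if an invariant is violated.
#' @export
validate_community <- function(comm) {
  sp <- comm$species
  if (anyDuplicated(sp$id)) stop("species ids must be unique", call. = FALSE)
  if (any(sp$r <= 0) || any(sp$s <= 0)) stop("r and s must be positive", call. = FALSE)
  n <- nrow(sp)
  for (nm in c("M", "Pplus", "Pminus", "Cmat")) {
    A <- comm[[nm]]
    if (any(A < 0)) stop(nm, " has negative entries", call. = FALSE)
    if (n > 0 && any(diag(A) != 0)) stop(nm, " has nonzero diagonal", call. = FALSE)
  }
  if (any((comm$M > 0) != t(comm$M > 0))) stop("M support not symmetric", call. = FALSE)
  if (any((comm$Cmat > 0) != t(comm$Cmat > 0))) stop("Cmat support not symmetric", call. = FALSE)
  if (any((comm$Pplus > 0) != t(comm$Pminus > 0)))
    stop("consumer-resource pairing broken (Pplus[i,j] > 0 iff Pminus[j,i] > 0)", call. = FALSE)
  if (any(comm$Pplus > t(comm$Pminus) + 1e-12))
    stop("efficiency constraint violated: consumer gain exceeds resource loss", call. = FALSE)
  pair_support <- (comm$M > 0) + (comm$Cmat > 0) + (comm$Pplus > 0 | comm$Pminus > 0)
  if (any(pair_support > 1)) stop("a species pair has more than one interaction type", call. = FALSE)
  invisible(comm)
}

#' Remove species from a community
#'
#' Drops the given species and their matrix rows/columns; all pair
#' invariants are preserved by construction.
#'
#' @param comm A `community`.
#' @param ids Integer ids of the species to remove.
#' @return The pruned `community` (possibly empty).
#' @export
prune_species <- function(comm, ids) {
  if (length(ids) == 0) return(comm)
  ids <- as.integer(ids)
  unknown <- setdiff(ids, comm$species$id)
  if (length(unknown)) stop("unknown species id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  keep <- !(comm$species$id %in% ids)
  community(comm$species[keep, , drop = FALSE],
            comm$M[keep, keep, drop = FALSE],
            comm$Pplus[keep, keep, drop = FALSE],
            comm$Pminus[keep, keep, drop = FALSE],
            comm$Cmat[keep, keep, drop = FALSE],
            validate = FALSE)
}

#' Pair-link table of a community
#'
#' One row per interacting unordered species pair. For consumer-resource
#' pairs `i` is the consumer (`w_ij` = consumer gain, `w_ji` = resource
#' loss); for mutualism and competition `i < j` positionally and `w_ij` is
#' the effect of `j` on `i`.
#'
#' @param comm A `community`.
#' @return Tibble with columns `i`, `j` (species ids), `type` (`"M"`, `"C"`
#'   or `"CR"`), `w_ij`, `w_ji`.
#' @export
community_links <- function(comm) {
  n <- n_species(comm)
  ids <- comm$species$id
  out <- list()
  if (n >= 2) {
    up <- upper.tri(matrix(0, n, n))
    idx <- which((comm$M > 0) & up, arr.ind = TRUE)
    if (nrow(idx))
      out$M <- tibble::tibble(i = ids[idx[, 1]], j = ids[idx[, 2]], type = "M",
                              w_ij = comm$M[idx], w_ji = comm$M[idx[, c(2, 1), drop = FALSE]])
    idx <- which((comm$Cmat > 0) & up, arr.ind = TRUE)
    if (nrow(idx))
      out$C <- tibble::tibble(i = ids[idx[, 1]], j = ids[idx[, 2]], type = "C",
                              w_ij = comm$Cmat[idx], w_ji = comm$Cmat[idx[, c(2, 1), drop = FALSE]])
    idx <- which(comm$Pplus > 0, arr.ind = TRUE) # i consumes j
    if (nrow(idx))
      out$CR <- tibble::tibble(i = ids[idx[, 1]], j = ids[idx[, 2]], type = "CR",
                               w_ij = comm$Pplus[idx], w_ji = comm$Pminus[idx[, c(2, 1), drop = FALSE]])
  }
  if (!length(out))
    return(tibble::tibble(i = integer(), j = integer(), type = character(),
                          w_ij = double(), w_ji = double()))
  dplyr::arrange(dplyr::bind_rows(out), .data$i, .data$j)
}

#' Count of positive interactions per species
#'
#' `n_plus[i]` counts the interactions in which species `i` is a mutualist
#' or a consumer; each such link costs `delta` in baseline reproduction.
#'
#' @param comm A `community`.
#' @return Integer vector aligned with the roster.
#' @export
n_positive_links <- function(comm) {
  as.integer(rowSums(comm$M > 0) + rowSums(comm$Pplus > 0))
}

#' Proportions of interaction types
#'
#' Counts unordered interacting pairs by type.
#'
#' @param comm A `community` with at least one link.
#' @return Named numeric vector `c(M = , C = , CR = )` summing to 1.
#' @export
interaction_type_proportions <- function(comm) {
  lk <- community_links(comm)
  if (nrow(lk) == 0) stop("community has no links; type proportions undefined", call. = FALSE)
  tab <- table(factor(lk$type, levels = c("M", "C", "CR")))
  as.vector(tab / sum(tab)) |> setNames(c("M", "C", "CR"))
}

#' @export
print.community <- function(x, ...) {
  n <- n_species(x)
  lk <- community_links(x)
  cat("<community> ", n, " species, ", nrow(lk), " pair-links", sep = "")
  if (nrow(lk) > 0) {
    pr <- interaction_type_proportions(x)
    cat(sprintf(" (M %.2f, C %.2f, CR %.2f)", pr["M"], pr["C"], pr["CR"]))
  }
  cat("\n")
  invisible(x)
}

#' Serialize a community to JSON
#'
#' Writes `{species: [...], links: [...]}` where each link records the pair,
#' its type, and both directed strengths (`i` is the consumer for CR links).
#'
#' @param comm A `community`.
#' @param path Output file; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_community_json <- function(comm, path = NULL) {
  doc <- list(species = comm$species, links = community_links(comm))
  js <- jsonlite::toJSON(doc, dataframe = "rows", digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a community from JSON
#'
#' @param path File written by [write_community_json()] (or a JSON string).
#' @return A `community`.
#' @export
read_community_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  sp <- tibble::as_tibble(doc$species)
  sp$parent_id <- suppressWarnings(as.integer(sp$parent_id))
  n <- nrow(sp)
  M <- Pp <- Pm <- Cm <- matrix(0, n, n)
  lk <- doc$links
  if (!is.null(lk) && NROW(lk) > 0) {
    lk <- tibble::as_tibble(lk)
    pos <- match(lk$i, sp$id); posj <- match(lk$j, sp$id)
    for (k in seq_len(nrow(lk))) {
      i <- pos[k]; j <- posj[k]
      switch(lk$type[k],
        M = { M[i, j] <- lk$w_ij[k]; M[j, i] <- lk$w_ji[k] },
        C = { Cm[i, j] <- lk$w_ij[k]; Cm[j, i] <- lk$w_ji[k] },
        CR = { Pp[i, j] <- lk$w_ij[k]; Pm[j, i] <- lk$w_ji[k] })
    }
  }
  community(sp, M, Pp, Pm, Cm)
}

#' Export the four interaction matrices as CSV files
#'
#' One file per matrix (`M.csv`, `Pplus.csv`, `Pminus.csv`, `Cmat.csv`),
#' with species ids as header and row names.
#'
#' @param comm A `community`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_community_matrices <- function(comm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- as.character(comm$species$id)
  for (nm in c("M", "Pplus", "Pminus", "Cmat")) {
    A <- comm[[nm]]
    dimnames(A) <- list(ids, ids)
    utils::write.csv(A, file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Export an abundance state as CSV
#'
#' @param comm A `community`.
#' @param state List with elements `x` (abundances aligned to the roster)
#'   and `t` (model time).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(comm, state, path) {
  readr::write_csv(tibble::tibble(id = comm$species$id, abundance = state$x,
                                  time = state$t), path)
  invisible(path)
}
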