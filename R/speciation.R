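#' Zinc-buffering species distribution
#'
#' Fractions of each partially metalated protein species `Zn0 ... Znn` as a
#' function of free zinc, from the stepwise binding polynomial. The weight
#' of the `j`-loaded species relative to the metal-free protein (thionein)
#' is the product of `z / kd_i` over the `j` tightest stepwise constants;
#' adjacent species are equimolar exactly where `z` equals the
#' corresponding stepwise constant. This is the buffering picture in which
#' differently loaded species dominate as cellular free zinc moves through
#' the ~1e-8 to 1e-11 M range.
#'
#' @param affinities A [stepwise_affinities()] object.
#' @param free_zn_grid Positive, sorted vector of free zinc levels (M).
#'   Defaults to 200 log-spaced points over 1e-13..1e-7 M.
#' @return An object of class `species_distribution`: `free_zn_grid` and
#'   `fractions`, a matrix with one row per grid point and columns
#'   `Zn0 ... Znn`, each row summing to 1.
#' @examples
#' sd <- species_distribution(mt2_affinities())
#' head(sd$fractions)
#' @export
species_distribution <- function(affinities,
                                 free_zn_grid = 10^seq(-13, -7, length.out = 200)) {
  stopifnot(inherits(affinities, "stepwise_affinities"))
  if (any(!is.finite(free_zn_grid)) || any(free_zn_grid <= 0) ||
      is.unsorted(free_zn_grid)) {
    stop("`free_zn_grid` must be positive, finite and sorted", call. = FALSE)
  }
  n <- affinities$n_sites
  fr <- t(vapply(free_zn_grid, .species_fractions_at, numeric(n + 1L),
                 kds = affinities$kds))
  colnames(fr) <- paste0("Zn", 0:n)
  structure(list(free_zn_grid = free_zn_grid, fractions = fr,
                 affinities = affinities),
            class = "species_distribution")
}

#' @export
print.species_distribution <- function(x, ...) {
  cat(sprintf("Species distribution: %d species over %d free-Zn points (%.1e..%.1e M)\n",
              ncol(x$fractions), length(x$free_zn_grid),
              min(x$free_zn_grid), max(x$free_zn_grid)))
  invisible(x)
}

#' Dominant protein species at a free-zinc level
#'
#' @param affinities A [stepwise_affinities()] object.
#' @param free_zn Single positive free zinc concentration (M).
#' @return The label (`"Zn0"` ... `"Znn"`) of the most abundant species;
#'   exact ties resolve toward the higher loading.
#' @examples
#' dominant_species(mt2_affinities(), 1e-9)  # "Zn6"
#' @export
dominant_species <- function(affinities, free_zn) {
  stopifnot(inherits(affinities, "stepwise_affinities"))
  if (!is.numeric(free_zn) || length(free_zn) != 1L || free_zn <= 0) {
    stop("`free_zn` must be a single positive concentration (M)", call. = FALSE)
  }
  fr <- .species_fractions_at(free_zn, affinities$kds)
  # ties toward higher loading: scan from the top
  j <- length(fr) - which.max(rev(fr))
  paste0("Zn", j)
}
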