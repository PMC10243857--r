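#' Stepwise affinity set of a multi-site metalloprotein
#'
#' Ordered macroscopic stepwise dissociation constants, indexed from the
#' weakest site (the first to dissociate, `kd1`) to the tightest. For human
#' metallothionein-2 the literature values are one nanomolar-range site
#' (`Kd1 ~ 1e-8` M), two moderate sites (`Kd2-3 ~ 1e-10` M) and four tight
#' sites (`Kd4-7 ~ 1e-12` M).
#'
#' @param kds Numeric vector of stepwise dissociation constants in M,
#'   weakest first. Must be positive and (unless `allow_unordered = TRUE`)
#'   non-increasing, since later dissociation events are tighter.
#' @param allow_unordered Set `TRUE` to accept a non-monotone sequence
#'   (e.g. experimentally derived constants with inversions).
#' @return An object of class `stepwise_affinities` with fields `kds` and
#'   `n_sites`.
#' @examples
#' mt2_affinities()
#' stepwise_affinities(c(1e-8, 1e-10, 1e-10, 1e-12, 1e-12, 1e-12, 1e-12))
#' @export
stepwise_affinities <- function(kds, allow_unordered = FALSE) {
  if (!is.numeric(kds) || length(kds) < 1L || any(!is.finite(kds)) || any(kds <= 0)) {
    stop("`kds` must be a non-empty vector of positive dissociation constants (M)",
         call. = FALSE)
  }
  if (!allow_unordered && any(diff(kds) > 0)) {
    stop("`kds` must be non-increasing (weakest site first); ",
         "use allow_unordered = TRUE to override", call. = FALSE)
  }
  structure(list(kds = as.numeric(kds), n_sites = length(kds)),
            class = "stepwise_affinities")
}

#' @export
print.stepwise_affinities <- function(x, ...) {
  cat(sprintf("Stepwise affinities: %d site(s), -logKd = %s (weakest first)\n",
              x$n_sites, paste(sprintf("%.2f", -log10(x$kds)), collapse = ", ")))
  invisible(x)
}

#' Literature affinity set for Zn7-metallothionein-2
#'
#' Convenience constructor with the order-of-magnitude stepwise constants of
#' human MT2: `Kd1 = 1e-8`, `Kd2 = Kd3 = 1e-10`, `Kd4..7 = 1e-12` M.
#'
#' @return A [stepwise_affinities()] object with seven sites.
#' @export
mt2_affinities <- function() {
  stepwise_affinities(c(1e-8, 1e-10, 1e-10, 1e-12, 1e-12, 1e-12, 1e-12))
}

#' Chelating-probe binding model
#'
#' Describes a chromogenic or fluorogenic zinc chelator: how many probe
#' molecules bind one metal (2 for PAR forming Zn(PAR)2, 1 for ZnAF-2F),
#' the cumulative dissociation constant of the complex, and the molar
#' absorptivity used to convert signal to concentration.
#'
#' @param name Probe label.
#' @param ligands_per_metal 1 or 2 probe molecules per metal ion.
#' @param kd_cumulative Cumulative dissociation constant of the complex, in
#'   M (1:1 probe) or M^2 (1:2 probe).
#' @param epsilon Molar absorptivity in M^-1 cm^-1 at `wavelength` (may be
#'   `NA` for fluorescent probes).
#' @param wavelength Detection wavelength in nm.
#' @return An object of class `probe_model`.
#' @examples
#' par_probe()
#' probe_model("ZnAF-2F", 1, 2.7e-9, NA, 516)
#' @export
probe_model <- function(name, ligands_per_metal, kd_cumulative,
                        epsilon = NA_real_, wavelength = NA_real_) {
  if (!ligands_per_metal %in% c(1L, 2L)) {
    stop("`ligands_per_metal` must be 1 or 2", call. = FALSE)
  }
  if (!is.numeric(kd_cumulative) || length(kd_cumulative) != 1L ||
      !is.finite(kd_cumulative) || kd_cumulative <= 0) {
    stop("`kd_cumulative` must be a single positive number", call. = FALSE)
  }
  if (!is.na(epsilon) && epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  structure(list(name = as.character(name),
                 ligands_per_metal = as.integer(ligands_per_metal),
                 kd_cumulative = kd_cumulative,
                 epsilon = epsilon, wavelength = wavelength),
            class = "probe_model")
}

#' @export
print.probe_model <- function(x, ...) {
  cat(sprintf("Probe %s: %d ligand(s)/metal, Kd = %.3e M^%d", x$name,
              x$ligands_per_metal, x$kd_cumulative, x$ligands_per_metal))
  if (!is.na(x$epsilon)) cat(sprintf(", eps = %g M-1cm-1 @ %g nm", x$epsilon, x$wavelength))
  cat("\n")
  invisible(x)
}

#' PAR probe with published constants
#'
#' 4-(2-pyridylazo)resorcinol forms a 1:2 Zn(PAR)2 complex detected at
#' 492 nm with molar absorptivity 71500 M^-1 cm^-1 and cumulative
#' dissociation constant 7.1e-13 M^2.
#'
#' @return A [probe_model()].
#' @export
par_probe <- function() {
  probe_model("PAR", 2L, 7.1e-13, epsilon = 71500, wavelength = 492)
}

#' Total concentrations of one competition mixture
#'
#' @param protein_total Total protein concentration (M).
#' @param probe_total Total probe concentration (M).
#' @param zinc_total Total zinc concentration (M); for a holo-protein
#'   competition this is loading x protein_total, for a titration it is the
#'   added zinc.
#' @return An object of class `mixture_totals`.
#' @examples
#' mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6)
#' @export
mixture_totals <- function(protein_total, probe_total, zinc_total) {
  vals <- c(protein_total, probe_total, zinc_total)
  if (!is.numeric(vals) || length(vals) != 3L || any(!is.finite(vals)) || any(vals < 0)) {
    stop("all totals must be finite and non-negative (M)", call. = FALSE)
  }
  structure(list(protein_total = protein_total, probe_total = probe_total,
                 zinc_total = zinc_total),
            class = "mixture_totals")
}

# Probe complex concentration at a given free-zinc level, with probe
# depletion eliminated analytically. For a 1:2 probe the mass balance is a
# quadratic in the complex; the numerically stable smaller root is taken.
.probe_complex_at <- function(z, probe_total, probe) {
  if (probe_total <= 0 || z <= 0) return(0)
  K <- probe$kd_cumulative
  if (probe$ligands_per_metal == 1L) {
    # C = z * (L - C) / K
    z * probe_total / (K + z)
  } else {
    L <- probe_total
    b <- 4 * z * L + K
    disc <- b^2 - 16 * z^2 * L^2
    disc <- max(disc, 0)
    2 * z * L^2 / (b + sqrt(disc))
  }
}

# Per-loading protein species fractions at free zinc z, via the stepwise
# binding polynomial in log space (weights can span hundreds of decades).
# Loading j consumes the j tightest constants: kd[n], kd[n-1], ..., kd[n-j+1].
.species_fractions_at <- function(z, kds) {
  n <- length(kds)
  if (z <= 0) return(c(1, rep(0, n)))
  lw <- c(0, cumsum(log(z) - log(rev(kds))))  # log weights for j = 0..n
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Solve the probe-competition speciation equilibrium
#'
#' Finds the unique chemically feasible equilibrium of a mixture of a
#' multi-site zinc protein, a chelating probe and zinc, by a monotone
#' one-dimensional root search on log10 of free zinc. At each candidate
#' free-zinc level the protein species follow the stepwise binding
#' polynomial and the probe complex is eliminated analytically from its own
#' mass balance; the remaining zinc-conservation residual is driven to zero.
#'
#' @param affinities A [stepwise_affinities()] object.
#' @param probe A [probe_model()].
#' @param totals A [mixture_totals()].
#' @param tol Relative tolerance on the zinc mass balance.
#' @return An object of class `equilibrium_state` with fields `free_zn`,
#'   `free_probe`, `probe_complex` (all M) and `protein_species`, a named
#'   vector of per-loading concentrations `Zn0 ... Znn` (M).
#' @examples
#' st <- solve_equilibrium(mt2_affinities(), par_probe(),
#'                         mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6))
#' transferred_equivalents(st, mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6))
#' @export
solve_equilibrium <- function(affinities, probe, totals, tol = 1e-12) {
  stopifnot(inherits(affinities, "stepwise_affinities"),
            inherits(probe, "probe_model"),
            inherits(totals, "mixture_totals"))
  P <- totals$protein_total
  L <- totals$probe_total
  Zt <- totals$zinc_total
  kds <- affinities$kds
  n <- affinities$n_sites
  s <- probe$ligands_per_metal

  make_state <- function(z) {
    C <- .probe_complex_at(z, L, probe)
    fr <- if (P > 0) .species_fractions_at(z, kds) else c(1, rep(0, n))
    species <- P * fr
    names(species) <- paste0("Zn", 0:n)
    structure(list(free_zn = z,
                   free_probe = L - s * C,
                   probe_complex = C,
                   protein_species = species,
                   totals = totals),
              class = "equilibrium_state")
  }

  if (Zt == 0) return(make_state(0))

  residual <- function(log10z) {
    z <- 10^log10z
    C <- .probe_complex_at(z, L, probe)
    bound <- if (P > 0) {
      fr <- .species_fractions_at(z, kds)
      P * sum((0:n) * fr)
    } else 0
    z + C + bound - Zt
  }

  lo <- min(-20, log10(Zt) - 10)
  hi <- log10(Zt) + 0.5        # free zinc cannot exceed total zinc
  if (residual(lo) > 0) lo <- lo - 20
  root <- stats::uniroot(residual, c(lo, hi), tol = 1e-14, maxiter = 2000L)
  st <- make_state(10^root$root)

  res <- abs(st$free_zn + st$probe_complex +
               sum((0:n) * st$protein_species) - Zt)
  if (res > max(tol, 1e-9) * Zt) {
    stop(sprintf("equilibrium solver did not converge: residual %.3e (rel %.3e)",
                 res, res / Zt), call. = FALSE)
  }
  st
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("Equilibrium state: free Zn %.3e M, probe complex %.3e M, free probe %.3e M\n",
              x$free_zn, x$probe_complex, x$free_probe))
  dominant <- names(x$protein_species)[which.max(x$protein_species)]
  cat(sprintf("  protein species (M): dominant %s\n", dominant))
  print(signif(x$protein_species, 4))
  invisible(x)
}

#' Probe-bound zinc expressed as protein mole equivalents
#'
#' @param state An `equilibrium_state` from [solve_equilibrium()].
#' @param totals The [mixture_totals()] of the mixture (protein total > 0).
#' @return Transferred zinc in mole equivalents per protein.
#' @export
transferred_equivalents <- function(state, totals) {
  stopifnot(inherits(state, "equilibrium_state"), inherits(totals, "mixture_totals"))
  if (totals$protein_total <= 0) {
    stop("`protein_total` must be positive to express transfer in equivalents",
         call. = FALSE)
  }
  state$probe_complex / totals$protein_total
}

# Width of the hysteresis band around 1.0 eq used when deciding between the
# one-site and two-site exchange models.
.TRANSFER_HYSTERESIS <- 0.02

#' Invert a one-site probe competition to Kd1
#'
#' Applies the simplified two-species exchange partition for proteins that
#' transfer up to one zinc equivalent: the protein is taken to exist only as
#' the fully loaded form and the form lacking one zinc, the latter equal to
#' the observed probe-complex concentration. The exchange constant
#' `Kex1 = C^2 / ((P - C) * PARfree^s)` multiplied by the probe constant
#' gives the dissociation constant of the weakest site.
#'
#' @param probe_complex_obs Observed probe-complex concentration (M).
#' @param totals A [mixture_totals()].
#' @param probe A [probe_model()].
#' @param loading Metal loading of the intact protein (site count labelling
#'   the substrate species, e.g. 7 for Zn7MT2); informational.
#' @return A list with `kd1` (M), `kex1`, `neg_log_kd1`, `transfer` (eq) and
#'   the species concentrations used.
#' @examples
#' tot <- mixture_totals(1.7e-6, 200e-6, 4 * 1.7e-6)
#' st <- solve_equilibrium(stepwise_affinities(c(10^-12.19, rep(1e-14, 3))),
#'                         par_probe(), tot)
#' invert_one_site(st$probe_complex, tot, par_probe(), loading = 4)$neg_log_kd1
#' @export
invert_one_site <- function(probe_complex_obs, totals, probe, loading = NULL) {
  stopifnot(inherits(totals, "mixture_totals"), inherits(probe, "probe_model"))
  P <- totals$protein_total
  L <- totals$probe_total
  s <- probe$ligands_per_metal
  C <- probe_complex_obs
  if (!is.numeric(C) || length(C) != 1L || C <= 0 || C >= L / s) {
    stop("`probe_complex_obs` must lie in (0, probe_total/s)", call. = FALSE)
  }
  transfer <- C / P
  if (transfer >= 1) {
    stop(sprintf(paste0("transfer of %.2f eq reaches 1 Zn eq: the one-site model does ",
                        "not apply, use invert_two_site()"), transfer), call. = FALSE)
  }
  depleted <- C            # protein lacking one zinc
  intact <- P - C          # fully loaded protein
  free_probe <- L - s * C
  kex1 <- (C * depleted) / (intact * free_probe^s)
  kd1 <- kex1 * probe$kd_cumulative
  list(kd1 = kd1, kex1 = kex1, neg_log_kd1 = -log10(kd1),
       transfer = transfer, loading = loading,
       species = c(intact = intact, depleted = depleted, free_probe = free_probe))
}

#' Invert a two-site probe competition to Kd12 and its average
#'
#' For proteins transferring between one and two zinc equivalents the
#' exchange is modelled as the loss of the two weakest zincs at once; the
#' singly depleted intermediate is deliberately omitted because its
#' concentration is not observable in an endpoint assay. The substrate and
#' product concentrations are `P - C/2` and `C/2`, giving
#' `Kex12 = (C/2) * C^2 / ((P - C/2) * PARfree^(2s))`,
#' `Kd12 = Kex12 * Kdprobe^2` (M^2) and `Kd12av = sqrt(Kd12)` (M).
#'
#' @inheritParams invert_one_site
#' @return A list with `kd12` (M^2), `kd12av` (M), `kex12`,
#'   `neg_log_kd12av`, `transfer` and the species concentrations used.
#' @examples
#' tot <- mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6)
#' invert_two_site(1.03 * 1.7e-6, tot, par_probe(), loading = 7)$neg_log_kd12av
#' @export
invert_two_site <- function(probe_complex_obs, totals, probe, loading = NULL) {
  stopifnot(inherits(totals, "mixture_totals"), inherits(probe, "probe_model"))
  P <- totals$protein_total
  L <- totals$probe_total
  s <- probe$ligands_per_metal
  C <- probe_complex_obs
  if (!is.numeric(C) || length(C) != 1L || C <= 0 || C >= L / s) {
    stop("`probe_complex_obs` must lie in (0, probe_total/s)", call. = FALSE)
  }
  transfer <- C / P
  if (transfer <= 1 - .TRANSFER_HYSTERESIS) {
    stop(sprintf(paste0("transfer of %.2f eq is below 1 Zn eq: use the one-site ",
                        "model invert_one_site()"), transfer), call. = FALSE)
  }
  if (transfer > 2) {
    stop(sprintf("transfer of %.2f eq exceeds 2 Zn eq: no supported exchange model",
                 transfer), call. = FALSE)
  }
  product <- C / 2             # protein lacking two zincs
  substrate <- P - C / 2       # fully loaded protein
  if (substrate <= 0) {
    stop("transfer of exactly 2 eq leaves no intact protein; model is singular",
         call. = FALSE)
  }
  free_probe <- L - s * C
  kex12 <- (product * C^2) / (substrate * free_probe^(2 * s))
  kd12 <- kex12 * probe$kd_cumulative^2
  kd12av <- kd12av_from_kd12(kd12)
  list(kd12 = kd12, kd12av = kd12av, kex12 = kex12,
       neg_log_kd12av = -log10(kd12av), transfer = transfer, loading = loading,
       species = c(substrate = substrate, product = product, free_probe = free_probe))
}

#' Forward prediction under the simplified exchange partitions
#'
#' Exact inverses of [invert_one_site()] and [invert_two_site()]: given the
#' generating dissociation constant, predict the probe-complex concentration
#' under the same two-species partition those inversions assume. Useful for
#' round-trip validation and as a diagnostic against the full mass-balance
#' solver ([solve_equilibrium()]), which additionally carries free zinc and
#' all intermediate loadings.
#'
#' @param kd Generating constant: `Kd1` (M) for `model = "one-site"`,
#'   cumulative `Kd12` (M^2) for `model = "two-site"`.
#' @param totals A [mixture_totals()].
#' @param probe A [probe_model()].
#' @param model `"one-site"` or `"two-site"`.
#' @return Predicted probe-complex concentration (M).
#' @export
forward_exchange <- function(kd, totals, probe, model = c("one-site", "two-site")) {
  model <- match.arg(model)
  stopifnot(inherits(totals, "mixture_totals"), inherits(probe, "probe_model"))
  P <- totals$protein_total
  L <- totals$probe_total
  s <- probe$ligands_per_metal
  if (kd <= 0 || P <= 0 || L <= 0) stop("inputs must be positive", call. = FALSE)
  if (model == "one-site") {
    kex <- kd / probe$kd_cumulative
    f <- function(C) C^2 / ((P - C) * (L - s * C)^s) - kex
    upper <- min(P, L / s) * (1 - 1e-12)
  } else {
    kex <- kd / probe$kd_cumulative^2
    f <- function(C) (C / 2) * C^2 / ((P - C / 2) * (L - s * C)^(2 * s)) - kex
    upper <- min(2 * P, L / s) * (1 - 1e-12)
  }
  stats::uniroot(f, c(upper * 1e-15, upper), tol = 1e-18, maxiter = 2000L)$root
}

#' Simulate a zinc titration read out by probe competition
#'
#' Solves the full competition equilibrium at each point of a grid of added
#' zinc, reproducing a titration in which metal-free protein is mixed with
#' increasing ZnSO4 and then challenged with the probe. With
#' `protein_total = 0` the run is the protein-free control in which
#' essentially all added zinc appears as probe complex.
#'
#' @param affinities A [stepwise_affinities()] object (ignored when
#'   `protein_total = 0`).
#' @param probe A [probe_model()].
#' @param protein_total Total protein concentration (M), may be 0.
#' @param zn_added_grid Non-negative, non-decreasing vector of added zinc (M).
#' @param probe_total Total probe concentration (M); the assays use a large
#'   200 uM excess by default.
#' @return A list with `states` (one `equilibrium_state` per grid point) and
#'   a `summary` data frame (zn_added, free_zn, probe_complex,
#'   transferred_eq).
#' @export
simulate_titration <- function(affinities, probe, protein_total, zn_added_grid,
                               probe_total = 200e-6) {
  stopifnot(inherits(probe, "probe_model"))
  if (any(zn_added_grid < 0) || is.unsorted(zn_added_grid)) {
    stop("`zn_added_grid` must be non-negative and non-decreasing", call. = FALSE)
  }
  if (protein_total > 0) stopifnot(inherits(affinities, "stepwise_affinities"))
  aff <- if (protein_total > 0) affinities else stepwise_affinities(1)
  states <- vector("list", length(zn_added_grid))
  for (i in seq_along(zn_added_grid)) {
    tot <- mixture_totals(protein_total, probe_total, zn_added_grid[i])
    states[[i]] <- tryCatch(
      solve_equilibrium(aff, probe, tot),
      error = function(e) stop(sprintf("titration point %d (Zn = %.3e M): %s",
                                       i, zn_added_grid[i], conditionMessage(e)),
                               call. = FALSE))
  }
  smry <- data.frame(
    zn_added = zn_added_grid,
    free_zn = vapply(states, function(s) s$free_zn, numeric(1)),
    probe_complex = vapply(states, function(s) s$probe_complex, numeric(1))
  )
  smry$transferred_eq <- if (protein_total > 0) smry$probe_complex / protein_total else NA_real_
  list(states = states, summary = smry)
}
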