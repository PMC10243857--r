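#' Noise specification for synthetic data
#'
#' @param kind `"multiplicative-gaussian"` (sigma is a fractional error) or
#'   `"additive-gaussian"` (sigma in signal units).
#' @param sigma Non-negative noise magnitude; 0 disables noise.
#' @param seed Integer RNG seed; every generator is a pure function of its
#'   parameters and this seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("multiplicative-gaussian", "additive-gaussian"),
                       sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

.apply_noise <- function(y, noise) {
  if (is.null(noise) || noise$sigma == 0) return(y)
  eps <- stats::rnorm(length(y), 0, noise$sigma)
  switch(noise$kind,
         "multiplicative-gaussian" = y * (1 + eps),
         "additive-gaussian" = y + eps)
}

# Run `expr` under a seeded RNG without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic chromogenic-probe competition experiment
#'
#' Generates an endpoint and a kinetic approach trace for a holo-protein
#' incubated with a chromogenic probe: the endpoint comes from the full
#' mass-balance solver, is converted to absorbance through the probe's
#' molar absorptivity, and the approach to equilibrium is rendered as a
#' first-order relaxation. The generating truth travels with the output.
#'
#' @param true_affinities A [stepwise_affinities()] object (generating truth).
#' @param probe A [probe_model()] with a molar absorptivity.
#' @param totals A [mixture_totals()].
#' @param noise A [noise_spec()]; the default adds 1 percent multiplicative
#'   absorbance noise.
#' @param rate_per_min First-order rate of the approach to equilibrium.
#' @param duration_min,n_points Trace length and sampling.
#' @param path Optical path length (cm).
#' @return A list with `trace` (data frame `time_min`, `a492`),
#'   `endpoint_absorbance`, `endpoint_state` and `truth` metadata.
#' @export
gen_par_competition <- function(true_affinities, probe, totals,
                                noise = noise_spec("multiplicative-gaussian", 0.01),
                                rate_per_min = 0.15, duration_min = 30,
                                n_points = 61L, path = 1) {
  stopifnot(inherits(probe, "probe_model"))
  if (is.na(probe$epsilon)) stop("probe needs a molar absorptivity", call. = FALSE)
  st <- solve_equilibrium(true_affinities, probe, totals)
  a_end <- st$probe_complex * probe$epsilon * path
  tt <- seq(0, duration_min, length.out = n_points)
  a <- a_end * (1 - exp(-rate_per_min * tt))
  a <- .with_seed(noise$seed, .apply_noise(a, noise))
  list(trace = data.frame(time_min = tt, a492 = a),
       endpoint_absorbance = a_end,
       endpoint_state = st,
       truth = list(neg_log_kds = -log10(true_affinities$kds),
                    probe = probe$name, rate_per_min = rate_per_min,
                    totals = unclass(totals), noise = unclass(noise)))
}

#' Synthetic fluorogenic 1:1 probe competition series
#'
#' For each probe concentration, solves the scalar zinc balance in which
#' the protein surrenders zinc according to a Hill law of the free-zinc
#' level, `transfer = e_max * kd1^n / (kd1^n + z^n)`, and the released
#' metal distributes between the free pool and the 1:1 probe complex.
#' Fluorescence is rendered between the calibration extremes with the same
#' convention the calibration equation assumes
#' (`f = (Kd * f_max + z * f_min) / (z + Kd)`), so the series is exactly
#' invertible through [free_zn_from_fluorescence()] and fittable by
#' [fit_hill()].
#'
#' @param true_kd1 Dissociation constant of the weakest site (M).
#' @param hill_n Hill coefficient of the transfer curve.
#' @param probe_kd Probe dissociation constant (M).
#' @param probe_grid Positive vector of total probe concentrations (M).
#' @param protein_total Total protein concentration (M).
#' @param noise A [noise_spec()]; the default adds 2 percent multiplicative
#'   fluorescence noise.
#' @param e_max Transfer ceiling in equivalents.
#' @param f_min,f_max Calibration fluorescence extremes.
#' @return A list with `series` (data frame `probe_total`, `fluorescence`,
#'   plus noise-free `free_zn` and `transferred_eq` columns from the
#'   generator), `calibration` and `truth` metadata.
#' @export
gen_znaf_series <- function(true_kd1, hill_n, probe_kd, probe_grid,
                            protein_total,
                            noise = noise_spec("multiplicative-gaussian", 0.02),
                            e_max = 1, f_min = 100, f_max = 1100) {
  if (any(probe_grid < 0)) stop("`probe_grid` must be non-negative", call. = FALSE)
  if (true_kd1 <= 0 || probe_kd <= 0 || hill_n <= 0 || protein_total <= 0) {
    stop("parameters must be positive", call. = FALSE)
  }
  solve_z <- function(L) {
    bal <- function(z) {
      released <- e_max * protein_total * true_kd1^hill_n /
        (true_kd1^hill_n + z^hill_n)
      released - z - L * z / (z + probe_kd)
    }
    stats::uniroot(bal, c(1e-18, 1), tol = 1e-18, maxiter = 2000L)$root
  }
  z <- vapply(probe_grid, solve_z, numeric(1))
  # rendering convention of the calibration equation: f_max at vanishing
  # free zinc, f_min at saturating free zinc
  f_clean <- (probe_kd * f_max + z * f_min) / (z + probe_kd)
  f <- .with_seed(noise$seed, .apply_noise(f_clean, noise))
  transferred <- e_max * true_kd1^hill_n / (true_kd1^hill_n + z^hill_n)
  list(series = data.frame(probe_total = probe_grid, fluorescence = f,
                           free_zn = z, transferred_eq = transferred),
       calibration = fluorescence_calibration(f_min, f_max, probe_kd),
       truth = list(neg_log_kd1 = -log10(true_kd1), hill_n = hill_n,
                    e_max = e_max, probe_kd = probe_kd,
                    protein_total = protein_total, noise = unclass(noise)))
}

#' Synthetic thiolate-oxidation progress curve
#'
#' Monophasic first-order absorbance rise, with an optional biphasic mode
#' (a second, slower exponential component) for exercising the
#' lack-of-fit diagnostic of [fit_first_order()].
#'
#' @param kobs First-order rate constant (per minute).
#' @param amplitude,baseline Curve amplitude and offset (absorbance units).
#' @param duration_min,n_points Trace length and sampling.
#' @param noise A [noise_spec()]; the default adds 1 percent multiplicative
#'   noise.
#' @param biphasic If `TRUE`, generate a two-exponential curve.
#' @param kobs2,frac2 Rate and amplitude fraction of the second phase.
#' @return A list with `trace` (data frame `time_min`, `a412`) and `truth`.
#' @export
gen_dtnb_trace <- function(kobs, amplitude, baseline, duration_min = 100,
                           n_points = 60L,
                           noise = noise_spec("multiplicative-gaussian", 0.01),
                           biphasic = FALSE, kobs2 = kobs / 10, frac2 = 0.5) {
  if (kobs <= 0 || duration_min <= 0 || n_points < 2L) {
    stop("invalid trace parameters", call. = FALSE)
  }
  tt <- seq(0, duration_min, length.out = n_points)
  a <- if (biphasic) {
    baseline + amplitude * ((1 - frac2) * (1 - exp(-kobs * tt)) +
                              frac2 * (1 - exp(-kobs2 * tt)))
  } else {
    baseline + amplitude * (1 - exp(-kobs * tt))
  }
  a <- .with_seed(noise$seed, .apply_noise(a, noise))
  list(trace = data.frame(time_min = tt, a412 = a),
       truth = list(kobs = kobs, amplitude = amplitude, baseline = baseline,
                    biphasic = biphasic,
                    kobs2 = if (biphasic) kobs2 else NA_real_,
                    noise = unclass(noise)))
}

#' Synthetic steered-MD pulling trajectory
#'
#' Builds a constant-speed pulling replica with a prescribed Zn-S bond
#' break order: each coordinating cysteine's distance sits at a bonded
#' baseline until its break point on the pulling coordinate, then ramps
#' outward; the applied force follows a sawtooth that peaks at each break.
#' Break points are snapped to the coordinate grid so the trapezoid
#' integral of the noiseless force law is exact; that integral is reported
#' as the ground-truth total work.
#'
#' @param break_order Character vector of cysteine labels in break order.
#' @param break_cvs Strictly increasing break positions on the pulling
#'   coordinate (Angstrom), one per label.
#' @param peak_forces Sawtooth peak force at each break
#'   (kcal mol^-1 A^-1).
#' @param p A [switching_params()] (recorded in the truth metadata).
#' @param n_frames Number of frames.
#' @param noise A [noise_spec()] applied additively to the force.
#' @param cv_max Final pulling-coordinate value (Angstrom).
#' @param base_distance Bonded Zn-S distance (Angstrom).
#' @param base_force Inter-event baseline force.
#' @param distance_slope Outward distance ramp per unit coordinate after a
#'   break.
#' @param replica_id Optional identifier.
#' @return A list with `trajectory` (a [pulling_trajectory()]) and `truth`
#'   metadata including `total_work`.
#' @export
gen_pulling_trajectory <- function(break_order, break_cvs, peak_forces,
                                   p = switching_params(), n_frames = 1351L,
                                   noise = noise_spec("additive-gaussian", 0),
                                   cv_max = 27, base_distance = 2.3,
                                   base_force = 2, distance_slope = 1,
                                   replica_id = NA) {
  k <- length(break_order)
  if (length(break_cvs) != k || length(peak_forces) != k) {
    stop("`break_order`, `break_cvs` and `peak_forces` must have equal length",
         call. = FALSE)
  }
  if (k > 0 && (is.unsorted(break_cvs, strictly = TRUE) || any(break_cvs <= 0) ||
                any(break_cvs >= cv_max))) {
    stop("`break_cvs` must be strictly increasing inside (0, cv_max)", call. = FALSE)
  }
  cv <- seq(0, cv_max, length.out = n_frames)
  time <- seq(0, 270, length.out = n_frames)   # ps, constant-speed pull
  # snap break points to the coordinate grid
  idx <- vapply(break_cvs, function(b) which.min(abs(cv - b)), integer(1))
  snapped <- cv[idx]

  dist <- matrix(base_distance, nrow = n_frames, ncol = k)
  colnames(dist) <- break_order
  for (j in seq_len(k)) {
    after <- cv > snapped[j]
    dist[after, j] <- base_distance + distance_slope * (cv[after] - snapped[j])
  }

  force <- rep(base_force, n_frames)
  prev <- 1L
  for (j in seq_len(k)) {
    if (idx[j] <= prev) {
      stop("break points closer than the frame spacing after snapping", call. = FALSE)
    }
    seg <- prev:idx[j]
    force[seg] <- base_force + (peak_forces[j] - base_force) *
      (cv[seg] - cv[prev]) / (cv[idx[j]] - cv[prev])
    prev <- idx[j] + 1L   # drop back to baseline over one frame
  }
  total_work <- pracma::trapz(cv, force)
  force_noisy <- .with_seed(noise$seed, .apply_noise(force, noise))

  traj <- pulling_trajectory(time, cv, force_noisy, as.data.frame(dist),
                             replica_id = replica_id)
  list(trajectory = traj,
       truth = list(break_order = break_order, break_cvs = snapped,
                    peak_forces = peak_forces, total_work = total_work,
                    switching = unclass(p), noise = unclass(noise)))
}
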