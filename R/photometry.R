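#' Beer-Lambert conversion of absorbance to concentration
#'
#' @param a Absorbance (blank-subtracted), dimensionless.
#' @param epsilon Molar absorptivity in M^-1 cm^-1.
#' @param path Optical path length in cm.
#' @param strict If `TRUE`, negative absorbances are an error; otherwise
#'   they are clamped to zero and flagged.
#' @return Concentration(s) in M, with attribute `clamped` marking values
#'   clamped from negative inputs when `strict = FALSE`.
#' @examples
#' absorbance_to_concentration(0.1252, 71500)  # 1.751e-6 M
#' @export
absorbance_to_concentration <- function(a, epsilon, path = 1, strict = FALSE) {
  if (!is.numeric(epsilon) || epsilon <= 0 || !is.numeric(path) || path <= 0) {
    stop("`epsilon` and `path` must be positive", call. = FALSE)
  }
  if (any(!is.finite(a))) stop("`a` must be finite", call. = FALSE)
  neg <- a < 0
  if (any(neg)) {
    if (strict) stop("negative absorbance after blank subtraction", call. = FALSE)
    warning(sprintf("%d negative absorbance value(s) clamped to zero", sum(neg)),
            call. = FALSE)
    a[neg] <- 0
  }
  out <- a / (epsilon * path)
  attr(out, "clamped") <- neg
  out
}

#' Fluorescence calibration of a 1:1 zinc probe
#'
#' Holds the fluorescence extremes of a probe titration: `f_max` measured
#' with saturating zinc, `f_min` after stripping zinc with excess EDTA, and
#' the probe's dissociation constant.
#'
#' @param f_min,f_max Minimum/maximum fluorescence (arbitrary units),
#'   `f_max > f_min`.
#' @param probe_kd Probe dissociation constant (M), positive.
#' @return An object of class `fluorescence_calibration`.
#' @export
fluorescence_calibration <- function(f_min, f_max, probe_kd) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_max <= f_min) {
    stop("`f_max` must exceed `f_min`", call. = FALSE)
  }
  if (!is.numeric(probe_kd) || probe_kd <= 0) {
    stop("`probe_kd` must be positive (M)", call. = FALSE)
  }
  structure(list(f_min = f_min, f_max = f_max, probe_kd = probe_kd),
            class = "fluorescence_calibration")
}

#' Free zinc from probe fluorescence
#'
#' Inverts the 1:1 probe binding isotherm:
#' `[Zn]free = Kd * (Fmax - F) / (F - Fmin)`.
#'
#' @param f Fluorescence value(s), strictly inside `(f_min, f_max)`.
#' @param cal A [fluorescence_calibration()].
#' @return Free zinc concentration(s) in M.
#' @examples
#' cal <- fluorescence_calibration(100, 1100, 1e-9)
#' free_zn_from_fluorescence(350, cal)  # 3e-9 M
#' @export
free_zn_from_fluorescence <- function(f, cal) {
  stopifnot(inherits(cal, "fluorescence_calibration"))
  if (any(f <= cal$f_min) || any(f >= cal$f_max)) {
    stop("fluorescence outside the open calibration range (f_min, f_max)",
         call. = FALSE)
  }
  cal$probe_kd * (cal$f_max - f) / (f - cal$f_min)
}

#' Zinc mole equivalents from a total-release calibration
#'
#' Linear map of a fluorescence reading onto zinc mole equivalents, anchored
#' at the probe baseline and at the fluorescence after complete oxidative
#' zinc release from the protein.
#'
#' @param f Fluorescence reading(s).
#' @param f_baseline Fluorescence with no zinc released.
#' @param f_total_release Fluorescence after total zinc release
#'   (must exceed `f_baseline`).
#' @param total_eq Zinc equivalents corresponding to total release.
#' @return Zinc mole equivalents.
#' @export
equivalents_from_release_calibration <- function(f, f_baseline, f_total_release,
                                                 total_eq) {
  if (f_total_release <= f_baseline) {
    stop("degenerate calibration: `f_total_release` must exceed `f_baseline`",
         call. = FALSE)
  }
  (f - f_baseline) / (f_total_release - f_baseline) * total_eq
}

#' Hill fit of zinc transfer versus free zinc
#'
#' Fits `transferred = e_max * kd1^n / (kd1^n + z^n)` to transfer data as a
#' function of free zinc `z`: transfer rises as the free-zinc level imposed
#' by the probe falls below the weakest site's dissociation constant. The
#' fit is performed on `log10(z)` with `kd1` parameterised in log space
#' (bounds -14..-6) and the Hill coefficient bounded in 0.2..4, from five
#' deterministic starting points.
#'
#' @param free_zn Free zinc concentrations (M), at least 4 points spanning
#'   at least one decade.
#' @param transferred Transferred zinc in mole equivalents.
#' @param e_max Fixed transfer ceiling in equivalents (default 1, the single
#'   weakest site), or `NULL` to fit it freely.
#' @return An object of class `hill_fit`: `kd1` (M), `hill_n`, `e_max`,
#'   `residual_norm`, `fitted`.
#' @examples
#' z <- 10^seq(-10, -7, length.out = 12)
#' tr <- 1 * (10^-8.4)^1.1 / ((10^-8.4)^1.1 + z^1.1)
#' fit_hill(z, tr)
#' @export
fit_hill <- function(free_zn, transferred, e_max = 1) {
  if (length(free_zn) < 4L || length(free_zn) != length(transferred)) {
    stop("need >= 4 matched (free_zn, transferred) points", call. = FALSE)
  }
  if (any(free_zn <= 0)) stop("`free_zn` must be positive", call. = FALSE)
  if (diff(range(log10(free_zn))) < 1) {
    stop("free-zinc span too narrow: need at least one decade", call. = FALSE)
  }
  if (all(transferred <= 0) || stats::sd(transferred) == 0) {
    stop("no transfer signal to fit", call. = FALSE)
  }
  lz <- log10(free_zn)
  fit_emax <- is.null(e_max)
  model <- function(p, lz) {
    em <- if (fit_emax) p[["emax"]] else e_max
    lkd <- p[["lkd"]]
    n <- p[["n"]]
    em / (1 + 10^(n * (lz - lkd)))
  }
  resid_fn <- function(p) model(p, lz) - transferred

  starts <- lapply(seq(-12.5, -7.5, length.out = 5), function(lkd0) {
    p <- c(lkd = lkd0, n = 1)
    if (fit_emax) p <- c(p, emax = max(transferred))
    p
  })
  lower <- c(lkd = -14, n = 0.2); upper <- c(lkd = -6, n = 4)
  if (fit_emax) {
    lower <- c(lower, emax = 1e-6); upper <- c(upper, emax = 10)
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("Hill fit did not converge from any start", call. = FALSE)
  p <- best$par
  structure(list(kd1 = 10^p[["lkd"]],
                 neg_log_kd1 = -p[["lkd"]],
                 hill_n = p[["n"]],
                 e_max = if (fit_emax) p[["emax"]] else e_max,
                 residual_norm = sqrt(best$deviance),
                 fitted = model(p, lz),
                 data = data.frame(free_zn = free_zn, transferred = transferred)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: -logKd1 = %.3f, n = %.3f, e_max = %.3f eq (residual norm %.3e)\n",
              x$neg_log_kd1, x$hill_n, x$e_max, x$residual_norm))
  invisible(x)
}

#' Zinc-to-protein stoichiometry from thiol titration
#'
#' Protein concentration is obtained from the total thiol(ate)
#' concentration divided by the cysteine count, and the zinc-to-protein
#' ratio follows.
#'
#' @param zn_conc Total zinc concentration (M).
#' @param thiol_conc Total thiol(ate) concentration (M), positive.
#' @param n_cys Number of cysteines per protein, positive integer.
#' @return Zinc ions per protein (dimensionless).
#' @examples
#' zn_per_protein_ratio(14e-6, 40e-6, 20)  # 7.0
#' @export
zn_per_protein_ratio <- function(zn_conc, thiol_conc, n_cys) {
  if (thiol_conc <= 0 || n_cys <= 0) {
    stop("`thiol_conc` and `n_cys` must be positive", call. = FALSE)
  }
  zn_conc / (thiol_conc / n_cys)
}

#' Saturation breakpoint of a metal titration
#'
#' Locates the metal-to-protein ratio at which a titration signal stops
#' rising, by continuous two-segment piecewise-linear least squares over a
#' dense candidate-knot grid. If allowing a knot barely improves on a single
#' straight line the signal is judged non-plateauing and flagged.
#'
#' @param mol_eq Metal-to-protein mole ratios (increasing), >= 6 points.
#' @param signal Titration signal (e.g. absorbance at an LMCT band).
#' @param n_candidates Number of candidate knots scanned between the second
#'   and the penultimate abscissa.
#' @param min_improvement Minimum fractional SSE reduction relative to the
#'   single-line fit for a breakpoint to be accepted.
#' @return A list with `breakpoint` (equivalents, `NA` when flagged),
#'   `found` (logical), `sse`, `slopes` (pre/post), `sse_line`.
#' @export
find_saturation_breakpoint <- function(mol_eq, signal, n_candidates = 201L,
                                       min_improvement = 0.5) {
  if (length(mol_eq) < 6L || length(mol_eq) != length(signal)) {
    stop("need >= 6 matched (mol_eq, signal) points", call. = FALSE)
  }
  if (is.unsorted(mol_eq, strictly = TRUE)) {
    stop("`mol_eq` must be strictly increasing", call. = FALSE)
  }
  line <- stats::lm(signal ~ mol_eq)
  sse_line <- sum(stats::residuals(line)^2)

  cand <- seq(mol_eq[2], mol_eq[length(mol_eq) - 1L], length.out = n_candidates)
  # interior abscissae are natural knot candidates (exact corner recovery)
  cand <- sort(unique(c(cand, mol_eq[2:(length(mol_eq) - 1L)])))
  best <- list(sse = Inf, knot = NA_real_, fit = NULL)
  for (c0 in cand) {
    hinge <- pmax(mol_eq - c0, 0)
    fit <- stats::lm(signal ~ mol_eq + hinge)
    sse <- sum(stats::residuals(fit)^2)
    if (sse < best$sse) best <- list(sse = sse, knot = c0, fit = fit)
  }
  scale2 <- sum((signal - mean(signal))^2)
  improvement <- if (sse_line <= 1e-12 * max(scale2, .Machine$double.eps)) 0 else
    1 - best$sse / sse_line
  co <- stats::coef(best$fit)
  found <- improvement >= min_improvement
  list(breakpoint = if (found) best$knot else NA_real_,
       found = found,
       sse = best$sse,
       sse_line = sse_line,
       slopes = c(pre = unname(co["mol_eq"]),
                  post = unname(co["mol_eq"] + co["hinge"])))
}
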