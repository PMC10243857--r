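#' Thermodynamic context
#'
#' Bundles the temperature and the gas constant used by all free-energy
#' conversions in the package. Competition and kinetic assays are run at
#' 25 degrees C, so the default temperature is 298.15 K.
#'
#' @param temperature Absolute temperature in kelvin. Must be positive.
#' @return An object of class `thermo_context` with elements `temperature`
#'   (K) and `gas_constant` (kcal mol^-1 K^-1).
#' @examples
#' ctx <- thermo_context()
#' ctx$gas_constant * ctx$temperature * log(10)  # kcal/mol per order of magnitude
#' @export
thermo_context <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L || !is.finite(temperature) ||
      temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)", call. = FALSE)
  }
  structure(
    list(temperature = temperature,
         gas_constant = 1.98720425864083e-3),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("Thermodynamic context: T = %.2f K, R = %.6e kcal/(mol K)\n",
              x$temperature, x$gas_constant))
  invisible(x)
}

#' Free-energy difference for an affinity ratio
#'
#' Converts a difference in binding affinity, expressed in orders of magnitude
#' of the dissociation constant, into a standard free-energy difference
#' `R * T * ln(10) * orders`. Four orders of magnitude at 298.15 K amount to
#' about 5.5 kcal/mol -- the energetic span separating the weakest and the
#' tightest zinc sites of metallothionein-2.
#'
#' @param orders_of_magnitude Non-negative affinity ratio in log10 units.
#' @param ctx A [thermo_context()].
#' @return Free-energy difference in kcal/mol.
#' @examples
#' delta_g_from_affinity_ratio(4)  # ~5.45 kcal/mol
#' @export
delta_g_from_affinity_ratio <- function(orders_of_magnitude, ctx = thermo_context()) {
  if (!inherits(ctx, "thermo_context")) stop("`ctx` must be a thermo_context", call. = FALSE)
  if (!is.numeric(orders_of_magnitude) || any(!is.finite(orders_of_magnitude)) ||
      any(orders_of_magnitude < 0)) {
    stop("`orders_of_magnitude` must be finite and non-negative", call. = FALSE)
  }
  ctx$gas_constant * ctx$temperature * log(10) * orders_of_magnitude
}

#' Average per-event constant from a cumulative two-event constant
#'
#' A cumulative dissociation constant of two sequential metal-loss events has
#' units of M^2; its square root is the geometric-mean single-event constant
#' (units M), the quantity reported as `-log Kd12^av`.
#'
#' @param kd12 Cumulative two-event dissociation constant (M^2), positive.
#' @return The average constant `sqrt(kd12)` in M.
#' @examples
#' -log10(kd12av_from_kd12(1.101e-21))  # 10.479
#' @export
kd12av_from_kd12 <- function(kd12) {
  if (!is.numeric(kd12) || any(!is.finite(kd12)) || any(kd12 <= 0)) {
    stop("`kd12` must be positive and finite (M^2)", call. = FALSE)
  }
  sqrt(kd12)
}
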