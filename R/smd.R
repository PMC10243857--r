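#' Switching-function parameters for Zn-S contacts
#'
#' Rational switching function used to turn a Zn-S distance into a smooth
#' bond-presence indicator: `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` with
#' defaults `r0 = 2.8` Angstrom (contact cut-off), `n = 8`, `m = 12`.
#'
#' @param r0 Cut-off distance in Angstrom, positive.
#' @param n,m Steepness exponents, integers with `m > n > 0`.
#' @return An object of class `switching_params`.
#' @export
switching_params <- function(r0 = 2.8, n = 8L, m = 12L) {
  if (!is.numeric(r0) || r0 <= 0) stop("`r0` must be positive", call. = FALSE)
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || is.na(m) || n <= 0L || m <= n) {
    stop("exponents must satisfy m > n > 0", call. = FALSE)
  }
  structure(list(r0 = r0, n = n, m = m), class = "switching_params")
}

#' Evaluate the rational switching function
#'
#' Continuous and strictly decreasing for `r > 0`, with `s(0) = 1` and the
#' removable singularity at `r = r0` evaluated as `n/m`.
#'
#' @param r Distance(s) in Angstrom, non-negative.
#' @param p A [switching_params()].
#' @return Switching value(s) in (0, 1].
#' @examples
#' switching_value(c(0, 2.8, 5.6))  # 1, 2/3, 0.06227
#' @export
switching_value <- function(r, p = switching_params()) {
  stopifnot(inherits(p, "switching_params"))
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  x <- r / p$r0
  out <- numeric(length(x))
  at_pole <- abs(x - 1) < 1e-9
  out[at_pole] <- p$n / p$m
  ok <- !at_pole
  out[ok] <- (1 - x[ok]^p$n) / (1 - x[ok]^p$m)
  out
}

#' Contact number of a zinc ion over its coordinating sulfurs
#'
#' Sum of switching-function values over the Zn-S pair distances of one
#' frame: a smooth coordination count between 0 and the number of pairs.
#'
#' @param pair_distances Named or unnamed vector of Zn-S distances
#'   (Angstrom) at one frame, length >= 1.
#' @param p A [switching_params()].
#' @return A list with `cn` (the summed contact number) and `per_pair`
#'   (individual switching values).
#' @examples
#' contact_number(c(Cys5 = 2.3, Cys7 = 2.3, Cys21 = 2.3, Cys24 = 8.0))
#' @export
contact_number <- function(pair_distances, p = switching_params()) {
  if (length(pair_distances) < 1L) stop("need at least one Zn-S pair", call. = FALSE)
  sv <- switching_value(pair_distances, p)
  names(sv) <- names(pair_distances)
  list(cn = sum(sv), per_pair = sv)
}

#' Pulling trajectory of one steered-MD replica
#'
#' @param time Time in ps, strictly increasing.
#' @param cv Pulling collective variable in Angstrom (Zn to Cys
#'   center-of-mass distance), expected within 0..30.
#' @param force Applied force in kcal mol^-1 A^-1.
#' @param pair_distances Data frame or matrix of per-frame Zn-S distances
#'   (Angstrom), one uniquely named column per coordinating cysteine.
#' @param replica_id Optional identifier.
#' @return An object of class `pulling_trajectory`.
#' @export
pulling_trajectory <- function(time, cv, force, pair_distances, replica_id = NA) {
  nfr <- length(time)
  pair_distances <- as.data.frame(pair_distances)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (length(cv) != nfr || length(force) != nfr || nrow(pair_distances) != nfr) {
    stop("time, cv, force and pair_distances must have matching lengths", call. = FALSE)
  }
  if (any(cv < 0) || any(cv > 30)) {
    stop("`cv` outside the supported 0..30 Angstrom pulling range", call. = FALSE)
  }
  if (anyDuplicated(colnames(pair_distances))) {
    stop("pair labels must be unique", call. = FALSE)
  }
  structure(list(time = as.numeric(time), cv = as.numeric(cv),
                 force = as.numeric(force), pair_distances = pair_distances,
                 replica_id = replica_id),
            class = "pulling_trajectory")
}

#' @export
print.pulling_trajectory <- function(x, ...) {
  cat(sprintf("Pulling trajectory%s: %d frames, cv %.2f..%.2f A, pairs: %s\n",
              if (is.na(x$replica_id)) "" else paste0(" ", x$replica_id),
              length(x$time), min(x$cv), max(x$cv),
              paste(colnames(x$pair_distances), collapse = ", ")))
  invisible(x)
}

#' Extract the Zn-S dissociation pathway from a pulling trajectory
#'
#' A Zn-S contact is declared broken at the first frame where its switching
#' value falls below `threshold` and stays below for `dwell` consecutive
#' frames. Events are ordered by break time; simultaneous breaks are
#' ordered by the larger distance in the final frame (the pair that ends up
#' farther ruptured ranks first), which is deterministic. Each event is
#' assigned a rupture force: the maximum applied force within a lookback
#' window of `lookback` frames ending at the break frame.
#'
#' @param traj A [pulling_trajectory()].
#' @param p A [switching_params()].
#' @param threshold Switching-value threshold below which a contact counts
#'   as broken (default 0.5).
#' @param dwell Number of consecutive sub-threshold frames required
#'   (default 10).
#' @param lookback Rupture-force window length in frames (default 200).
#' @return An object of class `pathway_result`: `ordered_breaks` (data
#'   frame with pair, break_time, break_cv, rupture_force),
#'   `pathway_signature` (character vector), `n_breaks`, `empty` flag.
#' @export
extract_pathway <- function(traj, p = switching_params(), threshold = 0.5,
                            dwell = 10L, lookback = 200L) {
  stopifnot(inherits(traj, "pulling_trajectory"))
  nfr <- length(traj$time)
  if (nfr < dwell) stop("trajectory shorter than the dwell window", call. = FALSE)
  pairs <- colnames(traj$pair_distances)

  events <- list()
  for (lab in pairs) {
    s <- switching_value(traj$pair_distances[[lab]], p)
    below <- s < threshold
    # first index starting a run of `dwell` sub-threshold frames
    run <- 0L; brk <- NA_integer_
    for (i in seq_len(nfr)) {
      run <- if (below[i]) run + 1L else 0L
      if (run == dwell) { brk <- i - dwell + 1L; break }
    }
    if (!is.na(brk)) {
      w0 <- max(1L, brk - lookback + 1L)
      events[[lab]] <- data.frame(
        pair = lab,
        break_frame = brk,
        break_time = traj$time[brk],
        break_cv = traj$cv[brk],
        rupture_force = max(traj$force[w0:brk]),
        terminal_distance = traj$pair_distances[[lab]][nfr],
        stringsAsFactors = FALSE)
    }
  }
  if (length(events) == 0L) {
    return(structure(list(ordered_breaks = NULL, pathway_signature = character(0),
                          n_breaks = 0L, empty = TRUE, replica_id = traj$replica_id),
                     class = "pathway_result"))
  }
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$break_frame, -ev$terminal_distance), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(ordered_breaks = ev, pathway_signature = ev$pair,
                 n_breaks = nrow(ev), empty = FALSE, replica_id = traj$replica_id),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  if (x$empty) {
    cat("Pathway: no Zn-S bond breaks detected\n")
  } else {
    cat(sprintf("Pathway (%d breaks): %s\n", x$n_breaks,
                paste(x$pathway_signature, collapse = " -> ")))
  }
  invisible(x)
}

#' Tabulate unbinding pathways across replicas
#'
#' Groups identical pathway signatures and counts replicas per group, most
#' populated first. The first row is the "most populated pathway" reported
#' for an ensemble of pulling runs.
#'
#' @param results List of `pathway_result` objects, length >= 1.
#' @return A data frame with columns `signature` (arrow-joined label
#'   string) and `count`, sorted by decreasing count.
#' @export
classify_pathways <- function(results) {
  if (length(results) < 1L) stop("need at least one replica", call. = FALSE)
  sigs <- vapply(results, function(r) {
    stopifnot(inherits(r, "pathway_result"))
    paste(r$pathway_signature, collapse = " -> ")
  }, character(1))
  tab <- sort(table(sigs), decreasing = TRUE)
  data.frame(signature = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rupture-force histogram statistics
#'
#' Histograms the rupture forces of an ensemble and least-squares fits a
#' Gaussian `A * exp(-(x - mean)^2 / (2 sd^2))` to the bin counts,
#' reporting mean and standard deviation. When the fit fails or describes
#' the histogram poorly (e.g. a bimodal force distribution) the sample mean
#' and standard deviation are reported instead and the result is flagged.
#'
#' @param forces Numeric vector of rupture forces, length >= 5.
#' @param bins Number of histogram bins.
#' @return An object of class `rupture_stats`: `mean_force`, `sd_force`,
#'   `histogram`, `gaussian_fit` (or NULL), `fit_ok`, `poor_fit`.
#' @export
rupture_force_stats <- function(forces, bins = 20L) {
  if (length(forces) < 5L) stop("need >= 5 rupture forces", call. = FALSE)
  h <- graphics::hist(forces, breaks = bins, plot = FALSE)
  x <- h$mids; y <- h$counts

  sample_mean <- mean(forces); sample_sd <- stats::sd(forces)
  fallback <- function(poor) {
    structure(list(mean_force = sample_mean, sd_force = sample_sd,
                   histogram = h, gaussian_fit = NULL,
                   fit_ok = FALSE, poor_fit = poor),
              class = "rupture_stats")
  }
  if (sample_sd == 0 || sum(y > 0) < 3L) return(fallback(poor = FALSE))

  resid_fn <- function(p) p[["A"]] * exp(-(x - p[["mu"]])^2 / (2 * p[["sigma"]]^2)) - y
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A = max(y), mu = sample_mean, sigma = sample_sd),
                       fn = resid_fn,
                       lower = c(A = 0, mu = min(x), sigma = 1e-12),
                       upper = c(A = Inf, mu = max(x), sigma = Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0L, 9L)) return(fallback(poor = TRUE))

  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - fit$deviance / sst else 0
  p <- fit$par
  structure(list(mean_force = p[["mu"]], sd_force = abs(p[["sigma"]]),
                 histogram = h,
                 gaussian_fit = list(amplitude = p[["A"]], mean = p[["mu"]],
                                     sd = abs(p[["sigma"]]), r_squared = r2),
                 fit_ok = TRUE, poor_fit = r2 < 0.9),
            class = "rupture_stats")
}

#' @export
print.rupture_stats <- function(x, ...) {
  cat(sprintf("Rupture force: %.1f +/- %.1f%s%s\n", x$mean_force, x$sd_force,
              if (!x$fit_ok) " (sample statistics, Gaussian fit unavailable)" else "",
              if (isTRUE(x$poor_fit)) " [poor Gaussian fit]" else ""))
  invisible(x)
}

#' Mechanical work along a pulling trajectory
#'
#' Cumulative trapezoid integral of the applied force over the pulling
#' coordinate, `W(x) = integral F dcv`, in kcal/mol when the force is in
#' kcal mol^-1 A^-1 and the coordinate in Angstrom. Small non-monotone
#' jitter in the coordinate is tolerated; grossly reversed travel
#' (backward motion exceeding 10 percent of the forward span) is an error.
#'
#' @param traj A [pulling_trajectory()].
#' @return A list with `cv`, `cumulative_work` and `total_work`.
#' @export
work_profile <- function(traj) {
  stopifnot(inherits(traj, "pulling_trajectory"))
  dcv <- diff(traj$cv)
  span <- max(traj$cv) - min(traj$cv)
  backward <- -sum(dcv[dcv < 0])
  if (span <= 0) stop("pulling coordinate does not advance", call. = FALSE)
  if (backward > 0.1 * span) {
    stop(sprintf("grossly non-monotone pulling coordinate: %.1f%% backward travel",
                 100 * backward / span), call. = FALSE)
  }
  w <- pracma::cumtrapz(traj$cv, traj$force)[, 1L]
  list(cv = traj$cv, cumulative_work = w, total_work = w[length(w)])
}
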