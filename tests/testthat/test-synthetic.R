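test_that("probe-competition generator is exact at zero noise and seeded otherwise", {
  aff <- mt2_affinities()
  tot <- mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6)
  gen0 <- gen_par_competition(aff, par_probe(), tot, noise = noise_spec(sigma = 0))
  expect_equal(gen0$trace$a492[nrow(gen0$trace)],
               gen0$endpoint_absorbance * (1 - exp(-0.15 * 30)), tolerance = 1e-12)
  expect_equal(gen0$endpoint_absorbance,
               gen0$endpoint_state$probe_complex * 71500, tolerance = 1e-12)
  # identical seeds give identical output; different seeds differ
  g1 <- gen_par_competition(aff, par_probe(), tot,
                            noise = noise_spec(sigma = 0.01, seed = 4))
  g2 <- gen_par_competition(aff, par_probe(), tot,
                            noise = noise_spec(sigma = 0.01, seed = 4))
  g3 <- gen_par_competition(aff, par_probe(), tot,
                            noise = noise_spec(sigma = 0.01, seed = 5))
  expect_identical(g1$trace, g2$trace)
  expect_false(identical(g1$trace, g3$trace))
  # generator metadata carries the generating truth
  expect_equal(g1$truth$neg_log_kds, -log10(aff$kds))
})

test_that("a 10.40-average-constant protein transfers close to one equivalent", {
  # cumulative Kd12 = 10^-20.8 split across the two weakest sites
  aff <- stepwise_affinities(c(10^-9.9, 10^-10.9, 10^-10.9,
                               rep(1e-12, 4)), allow_unordered = FALSE)
  tot <- mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6)
  gen <- gen_par_competition(aff, par_probe(), tot, noise = noise_spec(sigma = 0))
  eq <- transferred_equivalents(gen$endpoint_state, tot)
  expect_gt(eq, 0.95)
  expect_lt(eq, 1.25)
})

test_that("fluorogenic series closes the loop through calibration and Hill fit", {
  grid <- seq(0.05e-6, 3e-6, length.out = 12)
  gen <- gen_znaf_series(true_kd1 = 10^-8.4, hill_n = 1.1, probe_kd = 2.7e-9,
                         probe_grid = grid, protein_total = 0.5e-6,
                         noise = noise_spec(sigma = 0))
  # noise-free: rendered fluorescence inverts exactly to the generator free zinc
  z_back <- free_zn_from_fluorescence(gen$series$fluorescence, gen$calibration)
  expect_equal(z_back, gen$series$free_zn, tolerance = 1e-9)
  fit <- fit_hill(gen$series$free_zn, gen$series$transferred_eq)
  expect_equal(fit$neg_log_kd1, 8.4, tolerance = 1e-4)
  expect_equal(fit$hill_n, 1.1, tolerance = 1e-3)

  # noisy closed loop at the stated assay noise stays within 0.1 log units
  set.seed(31)
  errs <- vapply(1:25, function(i) {
    g <- gen_znaf_series(10^-8.4, 1.1, 2.7e-9, grid, 0.5e-6,
                         noise = noise_spec(sigma = 0.02, seed = i))
    f <- pmin(pmax(g$series$fluorescence, g$calibration$f_min + 1e-6),
              g$calibration$f_max - 1e-6)
    z <- free_zn_from_fluorescence(f, g$calibration)
    theta <- (f - g$calibration$f_min) / (g$calibration$f_max - g$calibration$f_min)
    tr <- g$series$probe_total * theta / 0.5e-6
    abs(fit_hill(z, tr)$neg_log_kd1 - 8.4)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.1)
  # seed determinism
  expect_identical(gen_znaf_series(10^-8.4, 1.1, 2.7e-9, grid, 0.5e-6,
                                   noise = noise_spec(sigma = 0.02, seed = 2)),
                   gen_znaf_series(10^-8.4, 1.1, 2.7e-9, grid, 0.5e-6,
                                   noise = noise_spec(sigma = 0.02, seed = 2)))
})

test_that("oxidation-trace generator feeds the kinetic fit", {
  g <- gen_dtnb_trace(kobs = 0.05, amplitude = 0.03, baseline = 0.001,
                      noise = noise_spec(sigma = 0))
  expect_equal(g$trace$a412,
               0.001 + 0.03 * (1 - exp(-0.05 * g$trace$time_min)), tolerance = 1e-12)
  fit <- fit_first_order(g$trace$time_min, g$trace$a412)
  expect_equal(fit$kobs, 0.05, tolerance = 1e-8)
  # biphasic mode trips the monophasicity diagnostic
  gb <- gen_dtnb_trace(kobs = 0.1, amplitude = 0.04, baseline = 0.001,
                       duration_min = 200, n_points = 80,
                       noise = noise_spec(sigma = 0), biphasic = TRUE,
                       kobs2 = 0.01, frac2 = 0.5)
  expect_true(fit_first_order(gb$trace$time_min, gb$trace$a412)$biphasic_suspect)
  # seed determinism
  expect_identical(gen_dtnb_trace(0.05, 0.03, 0.001,
                                  noise = noise_spec(sigma = 0.01, seed = 9)),
                   gen_dtnb_trace(0.05, 0.03, 0.001,
                                  noise = noise_spec(sigma = 0.01, seed = 9)))
})

test_that("pulling generator work metadata matches the work profile exactly", {
  gen <- gen_pulling_trajectory(c("Cys7", "Cys24", "Cys21", "Cys5"),
                                c(5, 10, 15, 20), c(40, 35, 30, 25))
  wp <- work_profile(gen$trajectory)
  expect_equal(wp$total_work, gen$truth$total_work, tolerance = 1e-6)
})

test_that("pathway order and force statistics survive a replica ensemble", {
  set.seed(23)
  order_true <- c("Cys7", "Cys24", "Cys21", "Cys5")
  n_rep <- 50L
  hits <- 0L
  peaks <- numeric(0)
  for (i in seq_len(n_rep)) {
    jitter <- sort(stats::runif(4, -1, 1))
    pf <- pmax(stats::rnorm(4, 36, 13), 5)
    gen <- gen_pulling_trajectory(order_true, c(5, 10, 15, 20) + jitter, pf,
                                  noise = noise_spec("additive-gaussian",
                                                     sigma = 0.5, seed = i),
                                  replica_id = i)
    pw <- extract_pathway(gen$trajectory)
    if (identical(pw$pathway_signature, order_true)) hits <- hits + 1L
    peaks <- c(peaks, pw$ordered_breaks$rupture_force)
  }
  expect_equal(hits, n_rep)
  st <- rupture_force_stats(peaks, bins = 20)
  expect_lt(abs(st$mean_force - 36), 2 * 13 / sqrt(4 * n_rep) + 2)
})

test_that("pulling generator validates its inputs", {
  expect_error(gen_pulling_trajectory(c("a", "b"), c(10, 5), c(30, 30)),
               "strictly increasing")
  expect_error(gen_pulling_trajectory(c("a", "b"), c(5, 10), 30), "equal length")
})
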