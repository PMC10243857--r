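test_that("constructors validate their invariants", {
  expect_error(stepwise_affinities(c(1e-12, 1e-8)), "non-increasing")
  expect_s3_class(stepwise_affinities(c(1e-12, 1e-8), allow_unordered = TRUE),
                  "stepwise_affinities")
  expect_error(stepwise_affinities(c(1e-8, -1)), "positive")
  expect_error(probe_model("x", 3L, 1e-9), "1 or 2")
  expect_error(probe_model("x", 1L, -1), "positive")
  expect_error(mixture_totals(-1e-6, 1e-6, 1e-6), "non-negative")
})

test_that("solver respects mass balances and degenerate inputs", {
  aff <- mt2_affinities()
  # probe-free mixture: speciation equals the closed binding-polynomial result
  tot0 <- mixture_totals(2e-6, 0, 10e-6)
  st0 <- solve_equilibrium(aff, par_probe(), tot0)
  expect_equal(st0$probe_complex, 0)
  expect_true(check_mass_balances(st0, aff, par_probe(), tot0))
  # zero zinc: everything at zero metal
  stz <- solve_equilibrium(aff, par_probe(), mixture_totals(2e-6, 200e-6, 0))
  expect_equal(stz$free_zn, 0)
  expect_equal(unname(stz$protein_species["Zn0"]), 2e-6)
  expect_equal(stz$probe_complex, 0)
})

test_that("one-site symmetric competition splits zinc evenly", {
  # protein site and 1:1 probe with identical Kd, equal totals: symmetry
  kd <- 1e-9
  aff <- stepwise_affinities(kd)
  probe <- probe_model("sym", 1L, kd)
  tot <- mixture_totals(1e-6, 1e-6, 1e-6)
  st <- solve_equilibrium(aff, probe, tot)
  bound_protein <- unname(st$protein_species["Zn1"])
  expect_equal(st$probe_complex, bound_protein, tolerance = 1e-9)
})

test_that("solver matches the brute-force grid oracle", {
  aff <- stepwise_affinities(c(1e-8, 1e-10, 1e-10, 1e-12, 1e-12, 1e-12, 1e-12))
  tot <- mixture_totals(2e-6, 200e-6, 14e-6)
  st <- solve_equilibrium(aff, par_probe(), tot)
  orc <- oracle_probe_complex(aff, par_probe(), tot, n_grid = 1e6)
  expect_equal(st$probe_complex, orc$probe_complex, tolerance = 0.05)

  # small systems agree tightly with the oracle
  set.seed(42)
  for (i in 1:10) {
    n <- sample(1:2, 1)
    aff <- stepwise_affinities(10^sort(runif(n, -12, -8), decreasing = TRUE))
    probe <- if (i %% 2 == 0) par_probe() else probe_model("F1", 1L, 1e-9)
    tot <- mixture_totals(runif(1, 0.5e-6, 3e-6), runif(1, 50e-6, 250e-6),
                          runif(1, 0.5e-6, 5e-6))
    st <- solve_equilibrium(aff, probe, tot)
    orc <- oracle_probe_complex(aff, probe, tot, n_grid = 2e5)
    expect_equal(st$probe_complex, orc$probe_complex, tolerance = 5e-3)
  }
})

test_that("probe complex is monotone in probe, zinc and site weakness", {
  base_aff <- stepwise_affinities(c(1e-9, 1e-11, 1e-12))
  probe <- par_probe()
  cplx <- function(aff, P, L, Zt) {
    solve_equilibrium(aff, probe, mixture_totals(P, L, Zt))$probe_complex
  }
  probe_series <- vapply(c(20, 50, 100, 200, 400) * 1e-6,
                         function(L) cplx(base_aff, 2e-6, L, 6e-6), numeric(1))
  expect_true(all(diff(probe_series) > 0))
  zinc_series <- vapply(seq(1e-6, 6e-6, length.out = 6),
                        function(Zt) cplx(base_aff, 2e-6, 200e-6, Zt), numeric(1))
  expect_true(all(diff(zinc_series) > 0))
  kd_series <- vapply(10^seq(-10, -8, length.out = 5), function(kd1) {
    cplx(stepwise_affinities(c(kd1, 1e-11, 1e-12)), 2e-6, 200e-6, 6e-6)
  }, numeric(1))
  expect_true(all(diff(kd_series) > 0))   # weaker binding, more transfer
})

test_that("transferred equivalents are probe complex per protein", {
  tot <- mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6)
  st <- solve_equilibrium(mt2_affinities(), par_probe(), tot)
  expect_equal(transferred_equivalents(st, tot), st$probe_complex / 1.7e-6)
  st$probe_complex <- 1.751e-6
  expect_equal(transferred_equivalents(st, tot), 1.03, tolerance = 1e-3)
  st$probe_complex <- 0
  expect_equal(transferred_equivalents(st, tot), 0)
  expect_error(transferred_equivalents(st, mixture_totals(0, 1e-6, 0)), "positive")
})

test_that("one-site inversion round-trips its own forward model exactly", {
  tot <- mixture_totals(1.7e-6, 200e-6, 4 * 1.7e-6)
  for (lkd in seq(-13, -9, by = 1)) {
    C <- forward_exchange(10^lkd, tot, par_probe(), "one-site")
    inv <- invert_one_site(C, tot, par_probe(), loading = 4)
    expect_equal(inv$kd1, 10^lkd, tolerance = 1e-9)
  }
})

test_that("one-site inversion recovers the truth through the full solver", {
  tot <- mixture_totals(1.7e-6, 200e-6, 4 * 1.7e-6)
  for (lkd in c(-12.19, -11.5, -10.5)) {
    aff <- stepwise_affinities(c(10^lkd, rep(1e-16, 3)))
    st <- solve_equilibrium(aff, par_probe(), tot)
    inv <- invert_one_site(st$probe_complex, tot, par_probe(), loading = 4)
    # the simplified partition ignores free zinc, a ~Kdprobe/[PAR]^2 offset
    expect_equal(inv$kd1, 10^lkd, tolerance = 1e-4)
  }
})

test_that("one-site Kd falls monotonically as observed transfer vanishes", {
  tot <- mixture_totals(1.7e-6, 200e-6, 4 * 1.7e-6)
  obs <- 1.7e-6 * c(0.5, 0.1, 0.02, 0.004)
  kds <- vapply(obs, function(C) invert_one_site(C, tot, par_probe())$kd1, numeric(1))
  expect_true(all(diff(kds) < 0))
})

test_that("model applicability is policed with a hysteresis band", {
  tot <- mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6)
  expect_error(invert_one_site(1.2 * 1.7e-6, tot, par_probe()), "invert_two_site")
  expect_error(invert_two_site(0.5 * 1.7e-6, tot, par_probe()), "one-site")
  expect_error(invert_two_site(2.5 * 1.7e-6, tot, par_probe()), "exceeds 2")
  # just below 1 eq both models accept (hysteresis band)
  expect_silent(invert_one_site(0.99 * 1.7e-6, tot, par_probe()))
  expect_silent(invert_two_site(0.99 * 1.7e-6, tot, par_probe()))
  # exactly 2 eq leaves no intact protein
  expect_error(invert_two_site(2 * 1.7e-6, tot, par_probe()), "singular|no supported")
})

test_that("two-site inversion reproduces the printed worked example", {
  tot <- mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6)
  inv <- invert_two_site(1.03 * 1.7e-6, tot, par_probe(), loading = 7)
  expect_equal(inv$kex12, 2.2e3, tolerance = 0.02)
  expect_equal(inv$kd12, 1.101e-21, tolerance = 1e-3)
  expect_equal(inv$neg_log_kd12av, 10.479, tolerance = 1e-3)
})

test_that("two-site inversion round-trips its forward model over six decades", {
  tot <- mixture_totals(1.7e-6, 200e-6, 7 * 1.7e-6)
  for (lkd12 in seq(-24, -18, by = 1)) {
    C <- forward_exchange(10^lkd12, tot, par_probe(), "two-site")
    tr <- C / tot$protein_total
    if (tr <= 1 - 0.02 || tr > 2) next   # outside the two-site window
    inv <- invert_two_site(C, tot, par_probe())
    expect_equal(inv$kd12, 10^lkd12, tolerance = 1e-9)
  }
})

test_that("mass balances hold on a large randomised instance set", {
  set.seed(7)
  for (i in 1:1000) {
    cs <- random_equilibrium_case()
    st <- solve_equilibrium(cs$affinities, cs$probe, cs$totals)
    expect_true(check_mass_balances(st, cs$affinities, cs$probe, cs$totals,
                                    tol = 1e-9))
  }
})

test_that("titration shows tight-site protection and a linear control", {
  grid <- seq(0, 14e-6, length.out = 15)
  # four uniformly tight sites: no transfer until they are filled
  tight <- stepwise_affinities(rep(1e-12, 4))
  sim <- simulate_titration(tight, par_probe(), 2e-6, grid)
  eq <- sim$summary$transferred_eq
  below <- sim$summary$zn_added <= 3 * 2e-6          # up to 3 of 4 equivalents
  expect_true(all(eq[below] < 0.06))
  expect_gt(eq[length(eq)], 2.5)                     # excess zinc goes to the probe
  # protein-free control: essentially all added zinc shows up as complex
  ctrl <- simulate_titration(NULL, par_probe(), 0, grid)
  with_zn <- ctrl$summary$zn_added > 0
  expect_equal(ctrl$summary$probe_complex[with_zn],
               ctrl$summary$zn_added[with_zn], tolerance = 1e-3)
  # zero added zinc gives the empty state
  expect_equal(sim$summary$probe_complex[1], 0)
})
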