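# Brute-force equilibrium oracle: dense log-grid search over free zinc
# minimising the zinc mass-balance residual. Independent of the package's
# root-finding path (direct vectorised arithmetic on the grid).
oracle_probe_complex <- function(affinities, probe, totals,
                                 n_grid = 2e5, lo = -18, hi = -3) {
  z <- 10^seq(lo, hi, length.out = n_grid)
  L <- totals$probe_total
  P <- totals$protein_total
  s <- probe$ligands_per_metal
  K <- probe$kd_cumulative
  C <- if (L <= 0) rep(0, length(z)) else if (s == 1L) {
    z * L / (K + z)
  } else {
    b <- 4 * z * L + K
    2 * z * L^2 / (b + sqrt(pmax(b^2 - 16 * z^2 * L^2, 0)))
  }
  kds <- affinities$kds
  n <- length(kds)
  lw <- matrix(0, length(z), n + 1L)
  for (j in seq_len(n)) lw[, j + 1L] <- lw[, j] + log(z) - log(kds[n - j + 1L])
  mx <- do.call(pmax, as.data.frame(lw))
  w <- exp(lw - mx)
  bound <- P * as.vector(w %*% (0:n)) / rowSums(w)
  resid <- z + C + bound - totals$zinc_total
  i <- which.min(abs(resid))
  list(free_zn = z[i], probe_complex = C[i], residual = resid[i])
}

# Random but chemically sensible solver instance under a seeded RNG.
random_equilibrium_case <- function() {
  n <- sample(1:7, 1)
  lkd <- sort(runif(n, -13, -8), decreasing = TRUE)  # weakest site first
  aff <- stepwise_affinities(10^lkd)
  probe <- if (runif(1) < 0.5) par_probe() else probe_model("F1", 1L, 10^runif(1, -10, -8))
  P <- runif(1, 0.2e-6, 5e-6)
  L <- runif(1, 10e-6, 300e-6)
  Zt <- runif(1, 0.1, 1) * n * P
  list(affinities = aff, probe = probe, totals = mixture_totals(P, L, Zt))
}

check_mass_balances <- function(state, affinities, probe, totals, tol = 1e-9) {
  n <- affinities$n_sites
  s <- probe$ligands_per_metal
  ok_protein <- totals$protein_total == 0 ||
    abs(sum(state$protein_species) - totals$protein_total) <=
      tol * totals$protein_total
  ok_probe <- totals$probe_total == 0 ||
    abs(state$free_probe + s * state$probe_complex - totals$probe_total) <=
      tol * totals$probe_total
  ok_zinc <- totals$zinc_total == 0 ||
    abs(state$free_zn + state$probe_complex +
          sum((0:n) * state$protein_species) - totals$zinc_total) <=
      tol * totals$zinc_total
  ok_protein && ok_probe && ok_zinc
}
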