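# Bias potential, window grid, WHAM, errors, theta diagnostic, macroscopic
# binding free energies.

KT300 <- 0.0019872041 * 300

test_that("the bias potential evaluates both branches exactly", {
  expect_equal(bias_energy(3.0, d_c = 3.0, k = 300), 0)
  expect_equal(bias_energy(3.1, d_c = 3.0, k = 300), 3.0)
  expect_equal(bias_energy(c(2.9, 2.9), d_c = 3.0, k = 300), 6.0)
  # mixed list: below-center pairs summed, above-center pairs ignored
  expect_equal(bias_energy(c(2.9, 2.9, 3.4), d_c = 3.0, k = 300), 6.0)
  # minimal pair at or beyond the center: only the minimal pair biased
  expect_equal(bias_energy(c(3.2, 3.6), d_c = 3.0, k = 300),
               300 * 0.2^2)
  expect_error(bias_energy(numeric(), 3, 300), "empty")
  expect_error(bias_energy(c(-1, 2), 3, 300), ">= 0")
})

test_that("the window grid is inclusive and arithmetic", {
  g <- window_grid(2.55, 5.5, 0.05)
  expect_length(g, 60L)
  expect_equal(g[1], 2.55)
  expect_equal(g[60], 5.5)
  expect_lt(max(abs(diff(g) - 0.05)), 1e-12)
  expect_equal(window_grid(3.0, 3.0, 0.05), 3.0)
})

test_that("WHAM recovers a flat profile from exact Boltzmann samples", {
  # rejection-free: harmonic-bias samples on a flat profile are Gaussian
  set.seed(6)
  k <- 20; c0 <- 4.0
  sig <- sqrt(KT300 / (2 * k))
  ds <- umbrella_dataset(
    tibble::tibble(center = c0, k = k,
                   samples = list(rnorm(4e4, c0, sig))),
    thermo = thermo(300))
  fp <- wham(ds, bin_width = 0.01)
  tab <- tidy(fp)
  core <- tab[abs(tab$d - c0) <= 2 * sig, ]
  expect_lt(diff(range(core$G)), 3 * 0.05)
  expect_true(fp$converged)
})

test_that("two-window WHAM offsets match the Gaussian closed form", {
  # flat profile, two harmonic biases: window free energies differ by
  # -kT log of the Gaussian normalizations, i.e. not at all for equal k
  set.seed(8)
  k <- 20
  sig <- sqrt(KT300 / (2 * k))
  ds <- umbrella_dataset(
    tibble::tibble(center = c(3.9, 4.0), k = k,
                   samples = list(rnorm(4e4, 3.9, sig),
                                  rnorm(4e4, 4.0, sig))),
    thermo = thermo(300))
  fp <- wham(ds, bin_width = 0.005)
  expect_equal(fp$f[2] - fp$f[1], 0, tolerance = 2 * 0.01)
  # and the recovered profile is flat across both windows
  tab <- tidy(fp)
  core <- tab[tab$d >= 3.85 & tab$d <= 4.05, ]
  expect_lt(diff(range(core$G)), 0.08)
  # cross-check the window offsets against an MBAR-style estimator
  f_mbar <- oracle_mbar_f(ds, subsample = 20)
  expect_lt(abs((fp$f[2] - fp$f[1]) - (f_mbar[2] - f_mbar[1])), 0.05)
})

test_that("WHAM reconstructs a Brownian double-well within 0.3 kcal/mol", {
  dw <- pmf_double_well()
  wins <- tibble::tibble(center = seq(2.6, 5.4, length.out = 20), k = 15)
  ds <- gen_bd_umbrella(dw, wins,
                        bd = bd_params(n_steps = 2e5, save_stride = 10,
                                       seed = 11))
  fp <- wham(ds)
  expect_true(fp$converged)
  tab <- tidy(fp)
  sup <- tab[tab$d >= 2.7 & tab$d <= 5.2, ]
  ref <- pmf_eval(dw, sup$d)
  off <- mean(sup$G - ref)
  expect_lt(sqrt(mean((sup$G - ref - off)^2)), 0.3)
  # window-order permutation leaves the profile untouched
  ds_perm <- ds
  ds_perm$windows <- ds_perm$windows[c(7:20, 1:6), ]
  ds_perm <- umbrella_dataset(ds_perm$windows, ds_perm$thermo)
  fp_perm <- wham(ds_perm)
  expect_lt(max(abs(fp_perm$profile$G - fp$profile$G), na.rm = TRUE),
            1e-6)
  # MBAR cross-check of window free-energy offsets on identical
  # (subsampled) data, so only the histogram discretization differs
  w_sub <- ds$windows[, c("center", "k", "samples")]
  w_sub$samples <- lapply(w_sub$samples,
                          function(x) x[seq(1, length(x), by = 40)])
  ds_sub <- umbrella_dataset(w_sub, thermo = ds$thermo)
  f_wham <- wham(ds_sub)$f
  f_mbar <- oracle_mbar_f(ds_sub, subsample = 1)
  expect_lt(max(abs((f_wham - f_wham[1]) - (f_mbar - f_mbar[1]))), 0.05)
  # non-overlapping windows warn
  ds2 <- umbrella_dataset(
    tibble::tibble(center = c(3, 5), k = 300,
                   samples = list(rnorm(1000, 3, 0.02),
                                  rnorm(1000, 5, 0.02))),
    thermo = thermo(300))
  expect_warning(wham(ds2), "no sampled bins")
})

test_that("bootstrap profile errors scale as 1/sqrt(n)", {
  flat <- reference_pmf(c(3.4, 4.6), c(0, 0))
  mkds <- function(n, seed) {
    set.seed(seed)
    k <- 15; sig <- sqrt(KT300 / (2 * k))
    umbrella_dataset(
      tibble::tibble(center = c(3.9, 4.0, 4.1), k = k,
                     samples = list(rnorm(n, 3.9, sig),
                                    rnorm(n, 4.0, sig),
                                    rnorm(n, 4.1, sig))),
      thermo = thermo(300))
  }
  e1 <- wham_error(mkds(4000, 1), n_boot = 48, seed = 2)
  e2 <- wham_error(mkds(8000, 1), n_boot = 48, seed = 2)
  # compare over the well-sampled core (tail bins carry 1-count noise)
  core <- function(e) {
    t <- tidy(e)
    mean(t$error[abs(t$d - 4.0) <= 0.12])
  }
  expect_equal(core(e1) / core(e2), sqrt(2), tolerance = 0.2)
  expect_true(all(tidy(e1)$error >= 0))
  expect_error(wham_error(mkds(1000, 1), n_boot = 10), ">= 20")
  # degenerate zero-variance window: single occupied bin, zero error
  dsz <- umbrella_dataset(
    tibble::tibble(center = 4, k = 15,
                   samples = list(rep(4.0, 500))),
    thermo = thermo(300))
  ez <- wham_error(dsz, n_boot = 24, seed = 1)
  expect_equal(tidy(ez)$error, 0)
})

test_that("bootstrap errors bracket the true profile deviation", {
  # coverage: over seeded replicates, ~68% of bins within 1 sigma of the
  # flat truth (anchored at the profile minimum, compared through offsets)
  cov <- vapply(1:12, function(sd) {
    set.seed(sd)
    k <- 15; sig <- sqrt(KT300 / (2 * k))
    ds <- umbrella_dataset(
      tibble::tibble(center = c(3.9, 4.0, 4.1), k = k,
                     samples = list(rnorm(1500, 3.9, sig),
                                    rnorm(1500, 4.0, sig),
                                    rnorm(1500, 4.1, sig))),
      thermo = thermo(300))
    fp <- wham_error(ds, n_boot = 32, seed = sd)
    tab <- tidy(fp)
    tab <- tab[tab$error > 1e-8 & abs(tab$d - 4.0) <= 0.15, ]
    dev <- tab$G - mean(tab$G)   # flat truth up to the anchor
    mean(abs(dev) <= tab$error)
  }, numeric(1))
  expect_gt(mean(cov), 0.40)
  expect_lt(mean(cov), 0.95)
})

test_that("theta is ~0 for twin windows, 2 for disjoint, responsive to starvation", {
  set.seed(14)
  s <- rnorm(3e4, 4.0, 0.2)
  twin <- umbrella_dataset(
    tibble::tibble(center = c(3.999, 4.001), k = 1e-9,
                   samples = list(s, s)),
    thermo = thermo(300))
  th <- theta_consistency(twin)
  expect_lt(th$theta, 1e-6)
  expect_false(th$disjoint)
  disj <- umbrella_dataset(
    tibble::tibble(center = c(3, 5), k = 300,
                   samples = list(rnorm(2000, 3, 0.02),
                                  rnorm(2000, 5, 0.02))),
    thermo = thermo(300))
  thd <- theta_consistency(disj)
  expect_equal(thd$theta, 2)
  expect_true(thd$disjoint)
  # converged Brownian data: small theta; starving a window raises it
  dw <- pmf_double_well()
  wins <- tibble::tibble(center = seq(2.6, 5.4, length.out = 20), k = 15)
  ds <- gen_bd_umbrella(dw, wins,
                        bd = bd_params(n_steps = 2e5, save_stride = 10,
                                       seed = 23))
  th0 <- theta_consistency(ds)
  ds_st <- ds
  ds_st$windows$samples[[10]] <-
    ds_st$windows$samples[[10]][seq_len(140)]
  th1 <- theta_consistency(ds_st)
  expect_gt(th1$theta[9], th0$theta[9])
  expect_gt(th1$theta[10], th0$theta[10])
})

test_that("macroscopic dG matches piecewise and smooth closed forms", {
  kT <- KT300
  # piecewise-constant profile: bound width 0.75 at G = -3, unbound width
  # 2.0 at G = 0 -> closed form -kT ln(w_b exp(g/kT) / w_u)
  d <- seq(2.55, 5.5, by = 0.01)
  G <- ifelse(d < 3.3, -3, 0)
  prof <- tibble::tibble(d = d, G = G)
  want <- -kT * log((0.75 / 2.0) * exp(3 / kT))
  expect_equal(want, -2.4153, tolerance = 1e-4)
  est <- pmf_to_dG(prof, thermo(300), threshold = 3.3, upper = 5.3)
  expect_equal(est$dG, want, tolerance = 0.02)
  # constant G with equal widths -> exactly 0
  prof0 <- tibble::tibble(d = seq(3, 5, by = 0.01), G = 1.7)
  expect_equal(pmf_to_dG(prof0, thermo(300), threshold = 4,
                         upper = 5)$dG, 0, tolerance = 1e-12)
  # linear ramp vs symbolic exponential integral, 1e-3 at 0.01 bins
  a <- 4 / 3   # kcal/mol per A over [2.5, 5.5]
  dr <- seq(2.5, 5.5, by = 0.01)
  ramp <- tibble::tibble(d = dr, G = a * (dr - 2.5))
  b <- a / kT
  exact <- function(lo, hi) (exp(-b * (lo - 2.5)) - exp(-b * (hi - 2.5))) / b
  want_r <- -kT * log(exact(2.5, 3.5) / exact(3.5, 5.5))
  est_r <- pmf_to_dG(ramp, thermo(300), threshold = 3.5, upper = 5.5)
  expect_equal(est_r$dG, want_r, tolerance = 1e-3 / abs(want_r))
  # shifting G by a constant leaves dG unchanged
  shifted <- dplyr::mutate(ramp, G = .data$G + 11.3)
  expect_equal(pmf_to_dG(shifted, thermo(300), 3.5, 5.5)$dG, est_r$dG,
               tolerance = 1e-12)
  # refining the bin width changes dG by < 0.01
  fine <- tibble::tibble(d = seq(2.5, 5.5, by = 0.005),
                         G = a * (seq(2.5, 5.5, by = 0.005) - 2.5))
  expect_lt(abs(pmf_to_dG(fine, thermo(300), 3.5, 5.5)$dG - est_r$dG),
            0.01)
  expect_error(pmf_to_dG(ramp, thermo(300), threshold = 9), "outside")
})

test_that("dG errors propagate linearly and agree with Monte Carlo", {
  set.seed(5)
  d <- seq(2.6, 5.5, by = 0.01)
  G <- pmf_eval(pmf_double_well(), d)
  prof <- tibble::tibble(d = d, G = G, error = runif(length(d), 0.02, 0.1))
  zl <- dG_error(dplyr::mutate(prof, error = 0), thermo(300),
                 threshold = 3.85)
  expect_equal(zl, 0)
  lin <- dG_error(prof, thermo(300), threshold = 3.85)
  mc <- dG_error(prof, thermo(300), threshold = 3.85,
                 method = "monte-carlo", n_mc = 4000, seed = 9)
  expect_equal(lin, mc, tolerance = 0.15)
  # scaling all per-bin errors scales the linear result exactly
  expect_equal(dG_error(dplyr::mutate(prof, error = 3 * .data$error),
                        thermo(300), threshold = 3.85),
               3 * lin, tolerance = 1e-12)
})

test_that("threshold sweeps return one estimate per threshold", {
  d <- seq(2.55, 5.5, by = 0.01)
  prof <- tibble::tibble(d = d, G = pmf_eval(pmf_double_well(), d))
  sw <- threshold_sweep(prof, thermo(300))
  expect_equal(nrow(sw), 7L)
  expect_equal(sw$threshold, seq(3.1, 4.3, by = 0.2), tolerance = 1e-9)
  # each value matches its own single-threshold computation
  for (i in c(1, 4, 7))
    expect_equal(sw$dG[i],
                 pmf_to_dG(prof, thermo(300), sw$threshold[i])$dG)
  # |dG| grows as the threshold moves past the well on a single-well profile
  dsw <- seq(2.55, 5.5, by = 0.01)
  single <- tibble::tibble(d = dsw, G = ifelse(dsw < 3.6, -4 * (3.6 - dsw),
                                               0))
  s2 <- threshold_sweep(single, thermo(300))
  expect_true(all(diff(abs(s2$dG)) >= -1e-9))
})
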