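# Synthetic generators: idealized duplex geometry, toy complex statistics,
# Brownian umbrella sampling against Boltzmann closed forms.

test_that("ideal duplex has the forced helical geometry", {
  dna <- gen_ideal_bdna(10)
  top <- dna$topology
  expect_equal(length(unique(paste(top$chain_id, top$residue_index))), 20L)
  xyz <- frame_coords(dna)
  # helical length along the axis: (10 - 1) * 3.38
  base_i <- which(top$atom_name %in% c("N3", "C4") & top$chain_id == "A")
  expect_equal(diff(range(xyz[base_i, 3])), 9 * 3.38, tolerance = 1e-9)
  # twist 36 deg: base pair i and i+10 share azimuth mod 360
  p <- which(top$atom_name == "P" & top$chain_id == "A")
  dna12 <- gen_ideal_bdna(12)
  xyz12 <- frame_coords(dna12)
  p12 <- which(dna12$topology$atom_name == "P" &
                 dna12$topology$chain_id == "A")
  az <- atan2(xyz12[p12, 2], xyz12[p12, 1]) * 180 / pi
  wrap <- (az[11] - az[1]) %% 360
  expect_lt(min(wrap, 360 - wrap), 1e-9)
  # phosphate radial distance constant across residues
  pall <- which(dna12$topology$atom_name == "P")
  rads <- sqrt(rowSums(xyz12[pall, 1:2]^2))
  expect_lt(stats::sd(rads), 1e-6)
  expect_error(gen_ideal_bdna(3), ">= 4")
})

test_that("toy ensembles honor designed persistence and covariance", {
  # persistence 1, default covariance: designated contacts in every frame
  spec1 <- std_toy_spec(seed = 3, persistence = c(1, 1, 1))
  ens1 <- gen_toy_complex_ensemble(spec1, 50)
  ct1 <- contact_map(ens1, prot_region(), dna_region())
  des1 <- ct1[grepl("CG", ct1$atom_name_i) &
                ct1$atom_name_j %in% c("N3", "C4", "P"), ]
  expect_true(all(des1$occupancy[des1$occupancy > 0.5] == 1))
  # persistence 0.7 at 2000 frames: occupancy within the binomial bound
  spec2 <- std_toy_spec(seed = 7, persistence = c(0.7, 0.7, 0.7))
  ens2 <- gen_toy_complex_ensemble(spec2, 2000)
  md <- min_distance(ens2, prot_region(), dna_region(), frames = 1L)
  ct2 <- contact_map(ens2, prot_region(), dna_region())
  des2 <- ct2[paste(ct2$residue_i, ct2$atom_name_j) %in%
                c("1 N3", "2 P", "3 N3") & grepl("CG", ct2$atom_name_i), ]
  des2 <- des2[des2$occupancy > 0.5, ]
  expect_equal(nrow(des2), 3L)
  expect_true(all(abs(des2$occupancy - 0.7) < 0.03))
  # designed node correlation recovered by the estimator
  nu <- 3 + 12
  V <- diag(0.0025, nu); V[1, 5] <- V[5, 1] <- 0.9 * 0.0025
  spec3 <- std_toy_spec(seed = 11, node_cov = V)
  ens3 <- gen_toy_complex_ensemble(spec3, 2000)
  nodes <- network_nodes(ens3)
  corr <- cross_correlation(ens3, nodes)
  i <- which(nodes$chain_id == "P" & nodes$residue_index == 1 &
               nodes$kind == "ca")
  j <- which(nodes$chain_id == "A" & nodes$residue_index == 2 &
               nodes$kind == "dna_base")
  expect_equal(corr[i, j], 0.9, tolerance = 0.05)
  # seeded bit-reproducibility
  again <- gen_toy_complex_ensemble(spec3, 5)
  first <- gen_toy_complex_ensemble(spec3, 5)
  expect_identical(first$coords, again$coords)
  # invalid covariance rejected
  Vbad <- diag(0.01, nu); Vbad[1, 2] <- 0.5
  expect_error(std_toy_spec(node_cov = Vbad), "symmetric")
  Vbad2 <- diag(0.01, nu); Vbad2[1, 2] <- Vbad2[2, 1] <- 0.5
  expect_error(std_toy_spec(node_cov = Vbad2), "semi-definite")
})

test_that("unbinding schedules break contacts exactly as scheduled", {
  spec <- std_toy_spec(persistence = c(1, 1, 1))
  sched <- tibble::tibble(d_min = c(2.8, 3.2, 3.6),
                          broken = list(integer(), c(1L), c(1L, 2L, 3L)))
  wins <- gen_unbinding_schedule(spec, sched, n_frames = 3)
  ref <- contact_map(gen_toy_complex_ensemble(spec, 20),
                     prot_region(), dna_region())
  prof <- unbinding_profile(wins, ref)
  expect_equal(prof$d_min, c(2.8, 3.2, 3.6))
  expect_equal(prof$fraction_recurrent[1], 1)
  expect_equal(prof$fraction_recurrent[3], 0)
  expect_lt(prof$fraction_recurrent[2], 1)
  # monotone violation rejected
  bad <- tibble::tibble(d_min = c(3.0, 3.4),
                        broken = list(c(1L), integer()))
  expect_error(gen_unbinding_schedule(spec, bad), "monotone")
  expect_error(gen_unbinding_schedule(
    spec, tibble::tibble(d_min = c(3.4, 3.0),
                         broken = list(integer(), integer()))),
    "increasing")
})

test_that("biased Brownian sampling reproduces Boltzmann closed forms", {
  kT <- thermo(300)$kT
  # stationary variance of a stiff harmonic window on a flat profile
  flat <- reference_pmf(c(2.5, 5.5), c(0, 0))
  bd <- bd_params(dt = 2e-4, n_steps = 1e6, save_stride = 25, seed = 5)
  ds <- gen_bd_umbrella(flat, tibble::tibble(center = 4, k = 300), bd = bd)
  expect_equal(var(ds$windows$samples[[1]]), kT / (2 * 300),
               tolerance = 0.1)
  # double well, nearly unbiased window: well occupancy ratio follows
  # exp(-dG_wells / kT) computed from the reference by direct quadrature
  xs <- seq(2.5, 5.5, by = 0.005)
  G <- pmin(2.5 * (xs - 3)^2, 0.8 + 2.5 * (xs - 5)^2)
  dw <- reference_pmf(xs, G)
  bd2 <- bd_params(dt = 0.01, n_steps = 2e6, save_stride = 20, seed = 9)
  ds2 <- gen_bd_umbrella(dw, tibble::tibble(center = 4, k = 1e-9),
                         bd = bd2, equilibration = 0.1)
  s <- ds2$windows$samples[[1]]
  r <- exp(-G / kT)
  expected <- sum(r[xs < 4]) / sum(r[xs >= 4])
  observed <- sum(s < 4) / sum(s >= 4)
  expect_equal(log(observed), log(expected), tolerance = 0.25)
  # near-zero temperature collapses onto the window center
  bd3 <- bd_params(temperature = 1, dt = 1e-6, n_steps = 1e5,
                   save_stride = 10, seed = 2)
  ds3 <- gen_bd_umbrella(flat, tibble::tibble(center = 4, k = 300),
                         bd = bd3)
  expect_lt(max(abs(ds3$windows$samples[[1]] - 4)), 0.01)
  # stability guard trips on an under-resolved timestep
  expect_error(gen_bd_umbrella(flat, tibble::tibble(center = 4, k = 300),
                               bd = bd_params(dt = 0.01, seed = 1)),
               "reduce dt")
})

test_that("biased histograms converge to the analytic biased density", {
  kT <- thermo(300)$kT
  xs <- seq(2.5, 5.5, by = 0.005)
  G <- 2 * sin(2 * xs) + 0.5 * (xs - 4)^2
  pmf <- reference_pmf(xs, G)
  k0 <- 10; c0 <- 3.6
  bd <- bd_params(dt = 0.005, n_steps = 2e6, save_stride = 20, seed = 13)
  ds <- gen_bd_umbrella(pmf, tibble::tibble(center = c0, k = k0), bd = bd)
  s <- ds$windows$samples[[1]]
  expect_gte(length(s), 7e4)
  dens <- exp(-(pmf_eval(pmf, xs) + k0 * (xs - c0)^2) / kT)
  cdf <- cumsum(dens) / sum(dens)
  ks <- max(abs(stats::ecdf(s)(xs) - cdf))
  expect_lt(ks, 0.05)
})

test_that("umbrella datasets round-trip through plain-text files", {
  flat <- reference_pmf(c(2.5, 5.5), c(0, 0))
  bd <- bd_params(dt = 2e-4, n_steps = 2e4, save_stride = 10, seed = 3)
  ds <- gen_bd_umbrella(flat, tibble::tibble(center = c(3.5, 4), k = 300),
                        bd = bd)
  dir <- withr::local_tempdir()
  write_umbrella_text(ds, dir)
  back <- read_umbrella_text(dir)
  expect_equal(back$windows$center, ds$windows$center)
  expect_equal(back$windows$k, ds$windows$k)
  expect_equal(back$windows$samples, ds$windows$samples,
               tolerance = 1e-12)
  expect_equal(back$thermo$temperature, 300)
})
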