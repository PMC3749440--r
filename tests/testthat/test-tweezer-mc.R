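test_that("total energy decomposes into traps plus tether terms", {
  cfg <- assay_config(list(ssdna_model()))
  # bead displaced 3 nm along the pulling axis, tether fully slack
  # (zero bead-bead distance)
  st <- system_state(bead1 = c(3, 0, 0), bead2 = c(3, 0, 0),
                     trap_separation = 3)
  expect_equal(total_energy(st, cfg), 0.5 * 0.4 * 9, tolerance = 1e-9)
  # full system at a stated geometry equals the sum of recomputed parts
  st2 <- system_state(bead1 = c(2, 1, -4), bead2 = c(12, 0, 3),
                      trap_separation = 5)
  r <- sqrt(sum((st2$bead2 - st2$bead1)^2))
  manual <- 0.5 * (0.4 * 4 + 0.4 * 1 + 0.04 * 16) +
    0.5 * (0.4 * (12 - 5)^2 + 0.04 * 9) +
    stretch_energy(r, ssdna_model())
  expect_equal(total_energy(st2, cfg), manual, tolerance = 1e-8)
  # overstretched tether: infinite energy, not an error
  st3 <- system_state(bead2 = c(20, 0, 0), trap_separation = 20)
  expect_identical(total_energy(st3, cfg), Inf)
})

test_that("hairpin state swaps tether composition and adds dG0", {
  hp <- hairpin_model(16, dG0 = 25)
  cfg <- assay_config(list(bundle_model()), hairpin = hp)
  d <- 460
  st_f <- system_state(bead2 = c(d, 0, 0), trap_separation = d,
                       hairpin_folded = TRUE)
  st_u <- system_state(bead2 = c(d, 0, 0), trap_separation = d,
                       hairpin_folded = FALSE)
  ss <- polymer_model("wlc", L = 16 * 0.59, p = 1)
  expect_equal(total_energy(st_f, cfg),
               rigidlink:::series_stretch_energy(d - 2, list(bundle_model()),
                                                 thermal()),
               tolerance = 1e-8)
  expect_equal(total_energy(st_u, cfg),
               rigidlink:::series_stretch_energy(d, list(bundle_model(), ss),
                                                 thermal()) + 25,
               tolerance = 1e-8)
})

test_that("Metropolis steps respect detailed balance bookkeeping", {
  cfg <- assay_config(list(ssdna_model()), step_size = 0.5, seed = 1)
  set.seed(1)
  st <- system_state(bead1 = c(1, 0, 0), bead2 = c(9, 0.5, 0),
                     trap_separation = 9)
  # accepted-move energy differences telescope to E(final) - E(initial)
  e0 <- total_energy(st, cfg)
  dsum <- 0
  n_rej <- 0
  for (i in 1:300) {
    out <- mc_step(st, cfg)
    if (!out$accepted) {
      n_rej <- n_rej + 1
      expect_identical(out$state, st)  # rejected: state bitwise unchanged
    }
    dsum <- dsum + out$dE
    st <- out$state
  }
  expect_equal(dsum, total_energy(st, cfg) - e0,
               tolerance = 1e-6 * max(1, abs(dsum)))
  expect_gt(n_rej, 0)
})

test_that("downhill proposals are always accepted", {
  # at kT -> 0 the Metropolis rule becomes greedy descent: from a strained
  # start every accepted move lowers the energy and the walk must relax
  cfg <- assay_config(list(), thermal = thermal(1e-9), step_size = 0.5)
  cfg$tether <- list()
  set.seed(3)
  st <- system_state(bead1 = c(30, 0, 0), bead2 = c(0, 0, 0),
                     trap_separation = 0)
  e <- total_energy(st, cfg)
  for (i in 1:400) {
    out <- mc_step(st, cfg)
    if (out$accepted) expect_lte(out$dE, 0)
    st <- out$state
  }
  expect_lt(total_energy(st, cfg), e / 4)  # relaxed towards the minimum
})

test_that("bead fluctuations satisfy equipartition per trap axis", {
  # slack tether at large step size for fast mixing; variance of the
  # Boltzmann ensemble is exact for any Metropolis step size
  cfg <- assay_config(list(dsdna_model()), mc_rate = 2e4, output_rate = 2e4,
                      step_size = 1.5, seed = 7)
  tr <- simulate_constant_distance(cfg, duration = 60,
                                   trap_separation = 200)
  expect_lt(abs(mean(tr$force_pN)), 0.15)  # slack: mean force ~ 0
  expect_equal(sd(tr$defl1_nm), sqrt(4.18 / 0.4), tolerance = 0.05)
  expect_equal(sd(tr$defl2_nm), sqrt(4.18 / 0.4), tolerance = 0.05)
})

test_that("simulated traces are seed-deterministic with exact sample count", {
  cfg <- preset_config("tenhelix_linker", seed = 99)
  tr1 <- simulate_pull(cfg, max_force = 5)
  tr2 <- simulate_pull(cfg, max_force = 5)
  expect_identical(tr1, tr2)
  cfg2 <- preset_config("dsDNA_linker", seed = 3)
  trc <- simulate_constant_distance(cfg2, duration = 1, target_force = 5)
  expect_identical(nrow(trc), 20000L)  # 1 s at 20 kHz output
  expect_equal(mean(trc$force_pN), 5, tolerance = 0.1)
})

test_that("downsampling takes block means with the expected variance", {
  expect_identical(downsample(rep(2, 100), 5), rep(2, 20))
  expect_identical(downsample(1:10, 1), 1:10)
  set.seed(11)
  x <- rnorm(5e4, sd = 1)
  s5 <- sd(downsample(x, 5))
  expect_equal(s5, 1 / sqrt(5), tolerance = 3 * s5 / sqrt(2 * (1e4 - 1)))
  expect_warning(downsample(1:11, 5), "trailing")
})

test_that("telegraph switching matches the imposed rates", {
  cfg <- cd_config("tenhelix_hairpin6", seed = 21, mc_rate = 1e5)
  d <- separation_for_force(6, cfg, "folded")
  tr <- simulate_constant_distance(cfg, duration = 10, rates = c(50, 50),
                                   trap_separation = d)
  n_trans <- sum(diff(as.integer(tr$state == "unfolded")) != 0)
  # two-state process with k12 = k21 = 50/s: 500 expected transitions
  expect_lt(abs(n_trans - 500), 3 * sqrt(500))
  # no-switching limit: single population
  tr0 <- simulate_constant_distance(cfg, duration = 0.5, rates = c(0, 0),
                                    trap_separation = d)
  expect_identical(unique(tr0$state), "folded")
})

test_that("calibrated dG0 makes the two states equally occupied", {
  cfg <- cd_config("tenhelix_hairpin6", seed = 22, mc_rate = 1e5)
  cfg <- calibrate_dg0(cfg, target_force = 6.25)
  d <- separation_for_force(6.25, cfg, "folded")
  dg <- state_free_energy_difference(cfg, d)
  expect_lt(abs(dg), 0.05)  # free energies equal after calibration
  rates <- boltzmann_rates(cfg, d, k_sum = 200)
  expect_equal(unname(rates["k_fold"] / rates["k_unfold"]), 1,
               tolerance = 0.05)
  tr <- simulate_constant_distance(cfg, duration = 10, rates = rates,
                                   trap_separation = d)
  occ <- mean(tr$state == "unfolded")
  n_dwell <- sum(diff(as.integer(tr$state == "unfolded")) != 0)
  expect_lt(abs(occ - 0.5), 3 * 0.5 / sqrt(n_dwell))
})

test_that("stiff linkers suppress extension noise across 1-10 pN", {
  # ensemble-averaged moving-window SD, 20 pulls per arm
  ens_sd <- function(preset) {
    breaks <- 1:10
    sds <- sapply(1:20, function(i) {
      cfg <- preset_config(preset, seed = 7000 + i)
      cfg$step_size <- 3
      tr <- simulate_pull(cfg, max_force = 12)
      rigidlink:::bin_noise_profile(noise_profile(tr), breaks)$sd_nm
    })
    rowMeans(sds)
  }
  floppy <- ens_sd("dsDNA_linker")
  stiff <- ens_sd("tenhelix_linker")
  expect_true(all(stiff < floppy))
})
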