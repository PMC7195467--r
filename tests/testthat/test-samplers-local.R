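test_that("zero-friction stepping reduces to velocity Verlet with bounded drift", {
  ref <- conformation(6L, matrix(0, 1, 3))
  pot <- harmonic_potential(ref, k = 0.05)
  cfg <- md_config(friction_per_fs = 0, dt_fs = 0.5)
  m <- alchemforge:::atomic_masses(6L)
  conv <- alchemforge:::AMU_A2_FS2_PER_HA
  conf <- conformation(6L, matrix(c(0.3, 0, 0), 1, 3))
  vel <- matrix(0, 1, 3)
  e0 <- pot$energy(conf) + 0.5 * m * sum(vel^2) * conv
  forces <- NULL
  energies <- numeric(1000)
  for (s in 1:1000) {
    st <- langevin_step(conf, vel, m, 300, cfg, pot$forces, forces)
    conf <- st$conformation; vel <- st$velocities; forces <- st$forces
    energies[s] <- pot$energy(conf) + 0.5 * m * sum(vel^2) * conv
  }
  expect_lt(max(abs(energies - e0)) / abs(e0 + 1e-12), 0.02)
})

test_that("a fixed RNG state reproduces the trajectory exactly", {
  ref <- conformation(6L, matrix(0, 1, 3))
  pot <- harmonic_potential(ref, k = 0.05)
  cfg <- md_config()
  run <- function() {
    set.seed(77)
    conf <- ref; vel <- maxwell_boltzmann_velocities(12.011, 300)
    forces <- NULL
    for (s in 1:50) {
      st <- langevin_step(conf, vel, 12.011, 300, cfg, pot$forces, forces)
      conf <- st$conformation; vel <- st$velocities; forces <- st$forces
    }
    conf$coordinates
  }
  expect_identical(run(), run())
})

test_that("the thermostat holds the kinetic temperature near the set point", {
  ref <- conformation(6L, matrix(0, 1, 3))
  pot <- harmonic_potential(ref, k = 0.05)
  cfg <- md_config(dt_fs = 0.5, friction_per_fs = 0.02)
  set.seed(5)
  conf <- ref; vel <- maxwell_boltzmann_velocities(12.011, 300)
  forces <- NULL; tsum <- 0; n <- 0
  for (s in 1:120000) {
    st <- langevin_step(conf, vel, 12.011, 300, cfg, pot$forces, forces)
    conf <- st$conformation; vel <- st$velocities; forces <- st$forces
    if (s > 5000) { tsum <- tsum + kinetic_temperature(vel, 12.011); n <- n + 1 }
  }
  expect_lt(abs(tsum / n - 300) / 300, 0.05)
})

test_that("non-finite forces raise a numerical error", {
  bad <- list(energy = function(conf) NaN,
              forces = function(conf) matrix(NaN, n_atoms(conf), 3))
  conf <- conformation(1L, matrix(0, 1, 3))
  expect_error(langevin_step(conf, matrix(0, 1, 3), 1.008, 300, md_config(),
                             bad$forces),
               "non-finite force")
})

test_that("md_sample selects only above-threshold structures and replays", {
  eth <- make_toy_molecules("ethanol")[[1]]
  # identical members: rho == 0 everywhere, empty batch after max_steps
  ens0 <- make_surrogate_ensemble(k = 3, amplitude = 0, seed = 1)
  b0 <- md_sample(eth, ens0, md_config(rho_threshold = 0, max_steps = 50),
                  seed = 2)
  expect_length(b0, 0L)
  # threshold 0 + disagreeing ensemble: selected at the first check step
  ens <- make_surrogate_ensemble(k = 4, amplitude = 0.02,
                                 localization = "stretch", seed = 7)
  b1 <- md_sample(eth, ens, md_config(rho_threshold = 0, max_steps = 100),
                  seed = 2)
  expect_length(b1, 1L)
  expect_equal(b1[[1]]$provenance$step, 5L)
  # gated run: replay the checks; no earlier check exceeds the threshold
  b2 <- md_sample(eth, ens, md_config(rho_threshold = 0.8, max_steps = 2000),
                  seed = 4, record = TRUE)
  checks <- attr(b2, "checks")
  if (length(b2)) {
    rhos <- vapply(checks, `[[`, numeric(1), "rho")
    expect_gt(b2[[1]]$rho, 0.8)
    expect_true(all(utils::head(rhos, -1) <= 0.8))
    expect_equal(checks[[length(checks)]]$rho, b2[[1]]$rho)
    # re-evaluating rho on the stored frames reproduces the log
    replay <- vapply(checks, function(ch)
      ensemble_rho(ens, ch$conformation), numeric(1))
    expect_equal(replay, rhos, tolerance = 1e-12)
  }
  # atoms and finiteness preserved
  expect_identical(b1[[1]]$conformation$atomic_numbers, eth$atomic_numbers)
  expect_true(all(is.finite(b1[[1]]$conformation$coordinates)))
  # determinism
  b3 <- md_sample(eth, ens, md_config(rho_threshold = 0.8, max_steps = 2000),
                  seed = 4)
  expect_equal(b3[[1]]$conformation$coordinates,
               b2[[1]]$conformation$coordinates)
})

two_mode_toy <- function(k1 = 0.4, k2 = 1.1) {
  ref <- conformation(c(1L, 1L), matrix(c(0, 0, 0, 2, 0, 0), 2, 3,
                                        byrow = TRUE))
  m <- alchemforge:::atomic_masses(1L)
  v1 <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE) / sqrt(m)
  v2 <- matrix(c(0, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE) / sqrt(m)
  normal_modes(ref, c(k1, k2), list(v1, v2))
}

test_that("normal-mode displacement obeys the Boltzmann energy bound", {
  nm <- two_mode_toy()
  # T = 0 reproduces the reference exactly
  c0 <- nms_generate(nm, 5, temperature_K = 0, seed = 3)
  for (cc in c0)
    expect_identical(cc$coordinates, nm$reference$coordinates)
  # every per-mode energy is below kT
  kT <- alchemforge:::KB_HA_PER_K * 400
  confs <- nms_generate(nm, 500, temperature_K = 400, seed = 3)
  q <- attr(confs, "displacements")
  expect_true(all(0.5 * nm$force_constants[1] * q[, 1]^2 <= kT))
  expect_true(all(0.5 * nm$force_constants[2] * q[, 2]^2 <= kT))
})

test_that("mean harmonic energy approaches modes * kT / 2", {
  nm <- two_mode_toy()
  confs <- nms_generate(nm, 10000, temperature_K = 300, seed = 8)
  q <- attr(confs, "displacements")
  etot <- apply(q, 1, function(qq) harmonic_energy(nm, qq))
  kT <- alchemforge:::KB_HA_PER_K * 300
  expect_lt(abs(mean(etot) - kT) / kT, 0.05)   # 2 modes: expectation = kT
})

test_that("soft modes are skipped with a warning record", {
  nm <- two_mode_toy(k1 = -0.1, k2 = 0.5)
  expect_warning(confs <- nms_generate(nm, 3, 300, seed = 1),
                 "non-positive")
  expect_equal(attr(confs, "skipped_modes"), 1L)
  q <- attr(confs, "displacements")
  expect_true(all(q[, 1] == 0))
})

test_that("nms_sample equals generate-then-filter", {
  pot <- mean_potential(make_surrogate_ensemble(k = 2, seed = 1))
  w <- minimize_geometry(make_toy_molecules("water")[[1]], pot, tol = 1e-5,
                         max_iter = 1000)
  nm <- normal_modes_from_potential(pot, w)
  ens0 <- make_surrogate_ensemble(k = 3, amplitude = 0, seed = 1)
  expect_length(nms_sample(nm, ens0, 20, 300, threshold = 0, seed = 5), 0L)
  ens <- make_surrogate_ensemble(k = 4, amplitude = 0.05,
                                 localization = "none", seed = 2)
  all_sel <- nms_sample(nm, ens, 20, 300, threshold = 0, seed = 5)
  expect_length(all_sel, 20L)
  thr <- stats::median(vapply(all_sel, `[[`, numeric(1), "rho"))
  some <- nms_sample(nm, ens, 20, 300, threshold = thr, seed = 5)
  confs <- nms_generate(nm, 20, 300, seed = 5)
  brute <- which(vapply(confs, function(cc) ensemble_rho(ens, cc),
                        numeric(1)) > thr)
  expect_equal(vapply(some, function(e) e$provenance$index, numeric(1)),
               brute)
})
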