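butane_spec <- function(but) {
  # central C2-C3 bond
  torsion_spec(1, 2, 3, 4, torsion_rotating_set(but, 2, 3))
}

test_that("torsion specs and rotating sets are validated", {
  but <- make_toy_molecules("butane")[[1]]
  rot <- torsion_rotating_set(but, 2, 3)
  expect_true(4L %in% rot)
  expect_false(any(c(1L, 2L, 3L) %in% rot))
  expect_error(torsion_spec(1, 2, 3, 3, rot), "distinct")
  expect_error(torsion_spec(1, 2, 3, 4, setdiff(rot, 4L)), "contain l")
  expect_error(torsion_spec(1, 2, 3, 4, c(rot, 2L)), "not contain")
})

test_that("set_dihedral hits the target exactly and only moves the rotating side", {
  but <- make_toy_molecules("butane")[[1]]
  spec <- butane_spec(but)
  for (target in c(-150, -60, 0, 35.5, 179)) {
    out <- set_dihedral(but, spec, target)
    expect_lt(abs(alchemforge:::wrap_angle(
      dihedral_angle(out$coordinates, 1, 2, 3, 4) - target)), 1e-8)
    fixed <- setdiff(seq_len(n_atoms(but)), spec$rotating)
    expect_equal(out$coordinates[fixed, ], but$coordinates[fixed, ])
  }
})

test_that("constrained minimization recovers the closed-form minimum", {
  but <- make_toy_molecules("butane")[[1]]
  spec <- butane_spec(but)
  # potential harmonic in pair distances that are invariant to the torsion:
  # the exact constrained minimum at any target is set_dihedral(ref, target)
  # with energy 0
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 3), c(2, 4))
  pot <- pair_distance_potential(but, pairs, k = 0.8)
  set.seed(13)
  start <- conformation(but$atomic_numbers,
                        but$coordinates + matrix(stats::rnorm(42, sd = 0.05),
                                                 14, 3))
  for (target in c(-120, 20, 95)) {
    out <- constrained_minimize(start, pot, spec, target, tol = 1e-6,
                                max_iter = 2000)
    expect_lt(abs(alchemforge:::wrap_angle(
      dihedral_angle(out$coordinates, 1, 2, 3, 4) - target)), 0.1)
    expect_lt(pot$energy(out), 1e-8)
  }
  # already at a constrained minimum: geometry unchanged within tolerance
  at_min <- set_dihedral(but, spec, 42)
  out <- constrained_minimize(at_min, pot, spec, 42, tol = 1e-6,
                              max_iter = 500)
  expect_lt(max(abs(out$coordinates - at_min$coordinates)), 1e-4)
})

test_that("a complete scan has 36 points in a 10-degree arithmetic sequence", {
  but <- make_toy_molecules("butane")[[1]]
  spec <- butane_spec(but)
  ens0 <- make_surrogate_ensemble(k = 3, amplitude = 0, seed = 1)
  scan <- relaxed_scan(but, ens0, spec, torsion_config(rho_threshold = 0))
  expect_null(scan$halt_index)
  expect_length(scan$points, 36L)
  dh <- vapply(scan$points, `[[`, numeric(1), "dihedral_deg")
  gaps <- (diff(dh) + 360) %% 360
  expect_true(all(abs(gaps - 10) < 0.1))
  expect_true(all(vapply(scan$points, `[[`, numeric(1), "rho") == 0))
})

test_that("the scan halts minimally inside a dihedral disagreement window", {
  but <- make_toy_molecules("butane")[[1]]
  spec <- butane_spec(but)
  phi0 <- dihedral_angle(but$coordinates, 1, 2, 3, 4)
  center <- alchemforge:::wrap_angle(phi0 + 120)
  ens <- make_surrogate_ensemble(k = 4, amplitude = 0.3,
                                 localization = "dihedral", seed = 2,
                                 dihedral = c(1, 2, 3, 4),
                                 dihedral_center_deg = center,
                                 dihedral_width_deg = 15)
  cfg <- torsion_config(rho_threshold = 5)
  scan <- relaxed_scan(but, ens, spec, cfg)
  expect_false(is.null(scan$halt_index))
  halted <- scan$points[[scan$halt_index]]
  expect_gt(halted$rho, 5)
  # halting is minimal: no earlier checked point exceeded the threshold
  earlier <- utils::head(vapply(scan$points, `[[`, numeric(1), "rho"), -1)
  expect_true(all(earlier <= 5))
  # the halt falls in the planted window
  expect_lt(abs(alchemforge:::wrap_angle(halted$dihedral_deg - center)), 60)
  # threshold 0 with any disagreement: halt at step 1
  ens_any <- make_surrogate_ensemble(k = 4, amplitude = 0.05,
                                     localization = "none", seed = 3)
  scan0 <- relaxed_scan(but, ens_any, spec,
                        torsion_config(rho_threshold = 0))
  expect_equal(scan0$halt_index, 1L)
})

test_that("mode perturbation respects count, scale zero, and the energy rule", {
  pot <- mean_potential(make_surrogate_ensemble(k = 2, seed = 1))
  w <- minimize_geometry(make_toy_molecules("water")[[1]], pot, tol = 1e-5,
                         max_iter = 1000)
  nm <- normal_modes_from_potential(pot, w)
  out <- perturb_along_modes(w, nm, n = 4, scale_K = 50, seed = 6)
  expect_length(out, 4L)
  for (p in out) expect_gt(max(abs(p$coordinates - w$coordinates)), 0)
  zero <- perturb_along_modes(w, nm, n = 3, scale_K = 0, seed = 6)
  for (p in zero) expect_identical(p$coordinates, w$coordinates)
  # per-mode harmonic energy bounded by kT(scale)
  q <- attr(out, "displacements")
  kT <- alchemforge:::KB_HA_PER_K * 50
  for (m in seq_along(nm$force_constants))
    expect_true(all(0.5 * nm$force_constants[m] * q[, m]^2 <= kT))
})

test_that("a torsion-sampling iteration yields 0 or n_perturbed structures", {
  emb <- fixture_embedder()
  cfg <- torsion_config(rho_threshold = 5, opt_tolerance = 5e-3)
  # zero disagreement: full scan, no halt, empty batch
  ens0 <- make_surrogate_ensemble(k = 3, amplitude = 0, seed = 1)
  expect_length(torsion_sampling_iteration("CCCC", emb, ens0, cfg, seed = 2,
                                           torsion_index = 2), 0L)
  # planted dihedral window: halt, then exactly four perturbations
  but <- make_toy_molecules("butane")[[1]]
  phi0 <- dihedral_angle(but$coordinates, 1, 2, 3, 4)
  ens <- make_surrogate_ensemble(k = 4, amplitude = 0.3,
                                 localization = "dihedral", seed = 2,
                                 dihedral = c(1, 2, 3, 4),
                                 dihedral_center_deg =
                                   alchemforge:::wrap_angle(phi0 + 100),
                                 dihedral_width_deg = 15)
  b <- torsion_sampling_iteration("CCCC", emb, ens, cfg, seed = 2,
                                  torsion_index = 2)
  expect_length(b, cfg$n_perturbed)
  prov <- b[[1]]$provenance
  expect_equal(prov$sampler, "torsion")
  expect_equal(prov$smiles, "CCCC")
  expect_true(prov$halt_step >= 1 && prov$halt_step <= 36)
  # the halted structure itself is not in the batch
  scan <- relaxed_scan(fixture_embedder()("CCCC")$conformation, ens,
                       butane_spec(but), cfg)
  xh <- scan$points[[scan$halt_index]]$conformation$coordinates
  for (e in b) expect_gt(max(abs(e$conformation$coordinates - xh)), 1e-8)
  # reproducibility
  b2 <- torsion_sampling_iteration("CCCC", emb, ens, cfg, seed = 2,
                                   torsion_index = 2)
  expect_equal(b[[1]]$conformation$coordinates,
               b2[[1]]$conformation$coordinates)
  # unknown SMILES: input error carrying the string
  expect_error(torsion_sampling_iteration("c1ccccc1", emb, ens, cfg),
               "c1ccccc1")
})
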