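test_that("molecule choice respects the size bias", {
  small <- make_toy_molecules("water")[[1]]      # 1 heavy atom
  big <- make_toy_molecules("butane")[[1]]       # 4 heavy atoms
  pool <- list(small = small, big = big)
  cfg1 <- dimer_config(size_bias_exponent = 1)
  set.seed(10)
  picks <- integer(0)
  for (r in 1:4000) {
    mols <- choose_molecules(pool, cfg1, volume = 400,
                             target_density = 0.01)
    picks <- c(picks, vapply(mols, function(m) attr(m, "pool_index"),
                             integer(1)))
  }
  frac_small <- mean(picks == 1L)
  # weights 1 : 1/4 -> expected fraction 0.8
  expect_lt(abs(frac_small - 0.8), 0.03)
  # exponent 0: uniform draws; chi-square test must not reject
  cfg0 <- dimer_config(size_bias_exponent = 0)
  set.seed(11)
  picks0 <- integer(0)
  for (r in 1:4000) {
    mols <- choose_molecules(pool, cfg0, volume = 400,
                             target_density = 0.01)
    picks0 <- c(picks0, vapply(mols, function(m) attr(m, "pool_index"),
                               integer(1)))
  }
  p <- stats::chisq.test(table(factor(picks0, levels = 1:2)))$p.value
  expect_gt(p, 0.01)
  # single-molecule pool: that molecule repeated
  set.seed(1)
  only <- choose_molecules(list(small), dimer_config(), volume = 1000,
                           target_density = 0.01)
  expect_true(all(vapply(only, function(m) attr(m, "pool_index"),
                         integer(1)) == 1L))
  expect_error(choose_molecules(list(), dimer_config()), "empty")
})

test_that("boxes satisfy the placement constraints", {
  pool <- make_toy_molecules(c("water", "methane", "ethanol"))
  cfg <- dimer_config(density_range = c(0.004, 0.008))
  set.seed(21)
  for (rep in 1:10) {
    cell <- stats::runif(3, 20, 30)
    mols <- choose_molecules(unname(pool), cfg, volume = prod(cell))
    box <- build_box(mols, cfg, cell = cell)
    expect_true(all(box$cell >= 20 & box$cell <= 30))
    expect_equal(n_atoms(box), sum(vapply(mols, n_atoms, integer(1))))
    # brute-force audit of all cross-molecule minimum-image distances
    for (a in unique(box$molecule_ids)) {
      for (b in unique(box$molecule_ids)) {
        if (b <= a) next
        d <- alchemforge:::cross_distances(
          box$coordinates[box$molecule_ids == a, , drop = FALSE],
          box$coordinates[box$molecule_ids == b, , drop = FALSE], box$cell)
        expect_gte(min(d), 1.5)
      }
    }
  }
})

test_that("an impossibly dense box fails with a placement error", {
  w <- make_toy_molecules("water")[[1]]
  mols <- rep(list(w), 500)
  cfg <- dimer_config(max_place_attempts = 5)
  set.seed(2)
  expect_error(build_box(mols, cfg, cell = c(20, 20, 20)),
               "placement failed")
})

test_that("dimer decomposition matches the brute-force minimum-image rule", {
  pool <- unname(make_toy_molecules(c("water", "methane")))
  cfg <- dimer_config(density_range = c(0.004, 0.010))
  set.seed(31)
  for (rep in 1:50) {
    cell <- stats::runif(3, 20, 30)
    mols <- choose_molecules(pool, cfg, volume = prod(cell))
    box <- build_box(mols, cfg, cell = cell)
    cutoff <- stats::runif(1, 3, 8)
    dimers <- decompose_to_dimers(box, cutoff)
    got <- vapply(dimers, function(d) paste(attr(d, "monomers"),
                                            collapse = "-"), character(1))
    # brute force over all pairs and all atoms with minimum image
    ids <- sort(unique(box$molecule_ids))
    want <- character(0)
    for (ai in seq_along(ids)) {
      for (bi in seq_along(ids)) {
        if (bi <= ai) next
        d <- alchemforge:::cross_distances(
          box$coordinates[box$molecule_ids == ids[ai], , drop = FALSE],
          box$coordinates[box$molecule_ids == ids[bi], , drop = FALSE],
          box$cell)
        if (min(d) <= cutoff)
          want <- c(want, paste(c(ids[ai], ids[bi]), collapse = "-"))
      }
    }
    expect_setequal(got, want)
    expect_lte(length(dimers), choose(length(mols), 2))
    # post hoc: each dimer has two monomers and a contact pair in range
    for (d in dimers) {
      expect_setequal(unique(d$molecule_ids), c(1L, 2L))
      dm <- alchemforge:::cross_distances(
        d$coordinates[d$molecule_ids == 1L, , drop = FALSE],
        d$coordinates[d$molecule_ids == 2L, , drop = FALSE], NULL)
      expect_lte(min(dm), cutoff)
      expect_null(d$cell)
    }
  }
})

test_that("dimers missing molecule ids are rejected", {
  w <- make_toy_molecules("water")[[1]]
  expect_error(decompose_to_dimers(w, 6), "molecule_ids")
})

test_that("the full sampling round reduces and reproduces as expected", {
  pool <- unname(make_toy_molecules(c("water", "methane", "ethanol")))
  # identical members: empty batch
  ens0 <- make_surrogate_ensemble(k = 3, amplitude = 0, seed = 1)
  cfg <- dimer_config(md_steps = 5, density_range = c(0.003, 0.005))
  expect_length(dimer_sampling_round(pool, ens0, cfg, seed = 3), 0L)
  # md_steps 0, threshold 0, disagreeing ensemble: batch == all contact
  # dimers of the initial box
  ens <- make_surrogate_ensemble(k = 4, amplitude = 0.05,
                                 localization = "none", seed = 2)
  cfg0 <- dimer_config(md_steps = 0, rho_threshold = 0,
                       density_range = c(0.003, 0.005))
  b <- dimer_sampling_round(pool, ens, cfg0, seed = 5)
  set.seed(5)
  cell <- stats::runif(3, cfg0$cell_range_A[1], cfg0$cell_range_A[2])
  mols <- choose_molecules(pool, cfg0, volume = prod(cell))
  box <- build_box(mols, cfg0, cell = cell)
  stats::runif(1)   # the temperature draw consumed by the sampling round
  dimers <- decompose_to_dimers(box, cfg0$contact_cutoff_A)
  expect_length(b, length(dimers))
  # determinism
  b1 <- dimer_sampling_round(pool, ens, cfg, seed = 9)
  b2 <- dimer_sampling_round(pool, ens, cfg, seed = 9)
  expect_equal(length(b1), length(b2))
  if (length(b1))
    expect_equal(b1[[1]]$conformation$coordinates,
                 b2[[1]]$conformation$coordinates)
})
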