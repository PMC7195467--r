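make_small_group <- function(gk = "CH4_00001", nc = 2L, seed = 1L) {
  set.seed(seed)
  mol <- make_toy_molecules("methane")[[1]]
  na <- n_atoms(mol)
  grid <- function(x) round(x * 1024) / 1024
  coords <- array(0, c(nc, na, 3))
  for (c_ in seq_len(nc))
    coords[c_, , ] <- grid(mol$coordinates +
                             matrix(stats::rnorm(na * 3, sd = 0.05), na, 3))
  conformer_group(gk, mol$atomic_numbers,
                  list(coordinates = coords,
                       "wb97x_dz.energy" = round(stats::rnorm(nc, -40), 6)))
}

test_that("a written dataset validates and round-trips bitwise", {
  path <- withr::local_tempfile(fileext = ".h5")
  g <- make_small_group()
  write_dataset(g, path)
  rep <- validate_schema(path)
  expect_true(rep$valid)
  expect_equal(nrow(rep$violations), 0L)
  back <- read_dataset(path)[["CH4_00001"]]
  expect_identical(back$atomic_numbers, g$atomic_numbers)
  expect_identical(back$properties[["coordinates"]],
                   g$properties[["coordinates"]])
  expect_identical(back$properties[["wb97x_dz.energy"]],
                   g$properties[["wb97x_dz.energy"]])
})

test_that("a group with every supported property key round-trips bitwise", {
  path <- withr::local_tempfile(fileext = ".h5")
  p <- make_fixture_h5(path, n_groups = 2, seed = 4, all_keys = TRUE)
  expect_true(validate_schema(path)$valid)
  before <- read_dataset(path)
  g1 <- before[[grep("_00001$", names(before))]]
  expect_setequal(c(names(g1$properties), "atomic_numbers"),
                  property_schema()$key)
  # write the read content again: second generation must be identical
  path2 <- withr::local_tempfile(fileext = ".h5")
  write_dataset(before, path2)
  after <- read_dataset(path2)
  for (gk in names(before)) {
    for (key in names(before[[gk]]$properties)) {
      expect_identical(after[[gk]]$properties[[key]],
                       before[[gk]]$properties[[key]],
                       info = paste(gk, key))
    }
  }
})

test_that("schema violations are rejected or reported with group and key", {
  mol <- make_toy_molecules("methane")[[1]]
  # malformed shape refused at construction
  expect_error(
    conformer_group("CH4_00001", mol$atomic_numbers,
                    list(coordinates = array(0, c(2, 5, 3)),
                         "wb97x_dz.forces" = array(0, c(2, 5, 2)))),
    "wb97x_dz.forces.*shape")
  expect_error(
    conformer_group("CH4_00001", mol$atomic_numbers,
                    list(coordinates = array(0, c(2, 5, 3)),
                         made_up_key = 1:2)),
    "unknown property key")
  # duplicate group keys refused at write time
  path <- withr::local_tempfile(fileext = ".h5")
  g <- make_small_group()
  expect_error(write_dataset(list(g, g), path), "duplicate group_key")
  # hand-built file with wrong dtype and wrong quadrupole width
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "bad")
  rhdf5::h5createDataset(path, "bad/atomic_numbers", dims = 5,
                         H5type = "H5T_STD_U8LE")
  rhdf5::h5write(as.integer(c(6, 1, 1, 1, 1)), path, "bad/atomic_numbers")
  rhdf5::h5createDataset(path, "bad/coordinates", dims = c(3, 5, 2),
                         H5type = "H5T_IEEE_F32LE")
  rhdf5::h5createDataset(path, "bad/wb97x_dz.energy", dims = 2,
                         H5type = "H5T_IEEE_F32LE")  # must be f8
  rhdf5::h5createDataset(path, "bad/wb97x_tz.quadrupole", dims = c(9, 2),
                         H5type = "H5T_IEEE_F32LE")  # trailing 9, expect 6
  rhdf5::h5closeAll()
  rep <- validate_schema(path)
  expect_false(rep$valid)
  v <- rep$violations
  expect_true(any(v$property_key == "wb97x_dz.energy" &
                    grepl("F32LE", v$message)))
  expect_true(any(v$property_key == "wb97x_tz.quadrupole" &
                    grepl("expected \\(2,6\\)", v$message)))
})

test_that("the key-filtered loader honors NaN availability", {
  path <- withr::local_tempfile(fileext = ".h5")
  mol <- make_toy_molecules("water")[[1]]
  e_dft <- c(-76.1, -76.2, -76.3)
  e_cc <- c(-76.15, NaN, -76.35)
  g <- conformer_group("H2O_00001", mol$atomic_numbers, list(
    coordinates = array(rep(mol$coordinates, each = 3), c(3, 3, 3)),
    "wb97x_dz.energy" = e_dft, "ccsd(t)_cbs.energy" = e_cc))
  write_dataset(g, path)
  both <- iter_data_buckets(path, c("wb97x_dz.energy", "ccsd(t)_cbs.energy"))
  expect_equal(length(both[["H2O_00001"]][["wb97x_dz.energy"]]), 2L)
  expect_equal(both[["H2O_00001"]][["wb97x_dz.energy"]], e_dft[c(1, 3)])
  one <- iter_data_buckets(path, "wb97x_dz.energy")
  expect_equal(length(one[["H2O_00001"]][["wb97x_dz.energy"]]), 3L)
  none <- iter_data_buckets(path)
  expect_equal(dim(none[["H2O_00001"]]$coordinates)[1], 3L)
  expect_error(iter_data_buckets(path, "no_such.key"), "valid keys")
})

test_that("loader counts are monotone under key-set growth", {
  path <- withr::local_tempfile(fileext = ".h5")
  make_fixture_h5(path, n_groups = 6, missing_fraction = 0.4, seed = 9)
  count <- function(keys) {
    b <- iter_data_buckets(path, keys)
    sum(vapply(b, function(x) dim(x$coordinates)[1], numeric(1)))
  }
  n_all <- count(character())
  n_a <- count("wb97x_dz.energy")
  n_ab <- count(c("wb97x_dz.energy", "ccsd(t)_cbs.energy"))
  expect_lte(n_ab, n_a)
  expect_lte(n_a, n_all)
  # per group too
  b_a <- iter_data_buckets(path, "wb97x_dz.energy")
  b_ab <- iter_data_buckets(path, c("wb97x_dz.energy", "ccsd(t)_cbs.energy"))
  for (gk in names(b_ab)) {
    expect_lte(dim(b_ab[[gk]]$coordinates)[1], dim(b_a[[gk]]$coordinates)[1])
  }
})
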