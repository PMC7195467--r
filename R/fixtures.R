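# Synthetic fixtures: toy molecules with sane geometry, schema-valid HDF5
# files with planted per-key availability, component-energy tables with
# independently computed reference composites, and toy potentials for
# integrator and active-learning tests.  Everything is deterministic given
# its seed.  No physical realism is claimed beyond smoothness, sane bond
# lengths and correct units.

# tetrahedral unit directions
.tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

.toy_water <- function() {
  ang <- 104.52 * pi / 180
  conformation(c(8L, 1L, 1L),
               rbind(c(0, 0, 0),
                     c(0.9572, 0, 0),
                     0.9572 * c(cos(ang), sin(ang), 0)))
}

.toy_methane <- function() {
  conformation(c(6L, 1L, 1L, 1L, 1L),
               rbind(c(0, 0, 0), 1.09 * .tet))
}

.toy_ammonia <- function() {
  conformation(c(7L, 1L, 1L, 1L),
               rbind(c(0, 0, 0), 1.01 * .tet[2:4, ]))
}

.toy_ethane <- function() {
  c1 <- c(0, 0, 0)
  c2 <- 1.54 * .tet[1, ]
  h1 <- 1.09 * .tet[2:4, ]
  h2 <- sweep(-1.09 * .tet[2:4, ], 2, c2, "+")  # staggered wrt h1
  conformation(c(6L, 6L, rep(1L, 6)), rbind(c1, c2, h1, h2))
}

# CH3-CH2-OH, 9 atoms; atoms: C1, C2, O, 3x H(C1), 2x H(C2), H(O)
.toy_ethanol <- function() {
  c1 <- c(0, 0, 0)
  c2 <- 1.54 * .tet[1, ]
  o  <- c2 + 1.43 * -.tet[2, ]
  h_c1 <- 1.09 * .tet[2:4, ]
  h_c2 <- sweep(1.09 * -.tet[3:4, ], 2, c2, "+")
  h_o  <- o + 0.96 * .tet[3, ]
  conformation(c(6L, 6L, 8L, rep(1L, 6)),
               rbind(c1, c2, o, h_c1, h_c2, h_o))
}

# n-butane, anti conformer; carbons 1-4 then hydrogens
.toy_butane <- function() {
  c1 <- c(0, 0, 0)
  c2 <- 1.54 * .tet[1, ]
  c3 <- c2 + 1.54 * -.tet[2, ]
  c4 <- c3 + 1.54 * .tet[1, ]
  h1 <- 1.09 * .tet[2:4, ]
  h2 <- sweep(1.09 * -.tet[c(3, 4), ], 2, c2, "+")
  h3 <- sweep(1.09 * .tet[c(3, 4), ], 2, c3, "+")
  h4 <- sweep(1.09 * -.tet[2:4, ], 2, c4, "+")
  conformation(c(rep(6L, 4), rep(1L, 10)),
               rbind(c1, c2, c3, c4, h1, h2, h3, h4))
}

# random H/C/N/O chain with tetrahedral-ish geometry and filled valences
.toy_chain <- function(n_heavy, seed) {
  set.seed(seed)
  valence <- c(`6` = 4L, `7` = 3L, `8` = 2L)
  zs <- sample(c(6L, 7L, 8L), n_heavy, replace = TRUE,
               prob = c(0.6, 0.2, 0.2))
  pos <- matrix(0, n_heavy, 3)
  dir <- c(1, 0, 0)
  for (i in seq_len(n_heavy)[-1]) {
    # bend the chain by a random perpendicular kick, keep ~1.5 A bonds
    kick <- stats::rnorm(3, sd = 0.4)
    kick <- kick - sum(kick * dir) * dir
    dir <- dir + kick
    dir <- dir / sqrt(sum(dir^2))
    pos[i, ] <- pos[i - 1, ] + 1.5 * dir
  }
  z_all <- zs
  x_all <- pos
  for (i in seq_len(n_heavy)) {
    n_h <- valence[as.character(zs[i])] -
      (i > 1L) - (i < n_heavy)
    if (n_h <= 0L) next
    # place hydrogens on a ring perpendicular to the local chain direction
    ref <- if (i < n_heavy) pos[i + 1L, ] - pos[i, ] else pos[i, ] - pos[i - 1L, ]
    ref <- ref / sqrt(sum(ref^2))
    perp <- cross3(ref, c(0, 0, 1))
    if (sum(perp^2) < 1e-8) perp <- cross3(ref, c(0, 1, 0))
    perp <- perp / sqrt(sum(perp^2))
    perp2 <- cross3(ref, perp)
    phase <- stats::runif(1, 0, 2 * pi)
    for (h in seq_len(n_h)) {
      a <- phase + 2 * pi * h / max(n_h, 2)
      d <- -0.35 * ref + cos(a) * perp + sin(a) * perp2
      d <- d / sqrt(sum(d^2))
      z_all <- c(z_all, 1L)
      x_all <- rbind(x_all, pos[i, ] + 1.09 * d)
    }
  }
  conformation(z_all, x_all)
}

#' Toy molecule fixtures
#'
#' Small H/C/N/O structures with sane geometries: named molecules
#' (`"water"`, `"methane"`, `"ammonia"`, `"ethane"`, `"ethanol"`,
#' `"butane"`) and `"chain<n>"` for a random chain with `n` heavy atoms
#' (e.g. `"chain4"`).
#'
#' @param which character vector of molecule names.
#' @param seed seed used by the random-chain generator.
#' @return named list of [conformation()]s.
#' @export
make_toy_molecules <- function(which = c("water", "methane", "ethanol"),
                               seed = 1L) {
  out <- list()
  for (w in which) {
    out[[w]] <- if (w == "water") .toy_water()
    else if (w == "methane") .toy_methane()
    else if (w == "ammonia") .toy_ammonia()
    else if (w == "ethane") .toy_ethane()
    else if (w == "ethanol") .toy_ethanol()
    else if (w == "butane") .toy_butane()
    else if (grepl("^chain[0-9]+$", w))
      .toy_chain(as.integer(sub("chain", "", w)), seed)
    else stop("unknown toy molecule: ", w)
  }
  out
}

#' Fixture structure provider for the torsion sampler
#'
#' Maps a handful of SMILES strings (`"CC"` ethane, `"CCO"` ethanol,
#' `"CCCC"` butane) to toy geometries, with rotatable bonds perceived from
#' the covalent bond graph. Honors the embedder contract of
#' [torsion_sampling_iteration()].
#'
#' @return `function(smiles)` returning a list with `conformation` and
#'   `torsions`.
#' @export
fixture_embedder <- function() {
  function(smiles) {
    conf <- switch(smiles,
                   "CC" = .toy_ethane(),
                   "CCO" = .toy_ethanol(),
                   "CCCC" = .toy_butane(),
                   stop("fixture embedder knows no SMILES '", smiles, "'"))
    list(conformation = conf, torsions = find_torsions(conf))
  }
}

#' Enumerate rotatable torsions of a conformation
#'
#' A bond j-k is rotatable when both atoms have at least one further
#' neighbor and the bond is not in a ring; for each such bond one
#' [torsion_spec()] is built with arbitrary outer atoms.
#'
#' @param conf a [conformation()].
#' @return list of [torsion_spec()]s (possibly empty).
#' @export
find_torsions <- function(conf) {
  adj <- bond_adjacency(conf)
  out <- list()
  na <- n_atoms(conf)
  for (j in seq_len(na)) {
    for (k in seq_len(na)) {
      if (k <= j || !adj[j, k]) next
      if (conf$atomic_numbers[j] == 1L || conf$atomic_numbers[k] == 1L) next
      ni <- setdiff(which(adj[j, ]), k)
      nl <- setdiff(which(adj[k, ]), j)
      if (!length(ni) || !length(nl)) next
      rotating <- tryCatch(torsion_rotating_set(conf, j, k),
                           error = function(e) NULL)
      if (is.null(rotating)) next   # ring bond
      out[[length(out) + 1L]] <-
        torsion_spec(ni[1], j, k, nl[1], rotating)
    }
  }
  out
}

#' OpenBabel-based structure provider
#'
#' Embeds a SMILES string in 3D with the `obabel` command-line tool
#' (`--gen3d`) and perceives rotatable bonds from the covalent bond graph.
#' Requires `obabel` on the PATH.
#'
#' @return `function(smiles)` matching the embedder contract.
#' @export
openbabel_embedder <- function() {
  function(smiles) {
    tmp <- tempfile(fileext = ".xyz")
    status <- system2("obabel", c(paste0("-:", shQuote(smiles)), "-oxyz",
                                  "--gen3d", "-O", tmp),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L || !file.exists(tmp))
      stop("obabel failed to embed the SMILES")
    conf <- read_xyz(tmp)[[1]]
    list(conformation = conf, torsions = find_torsions(conf))
  }
}

# round to the nearest float32-representable value on a 1/1024 grid, so
# single-precision storage round-trips bitwise
.f4grid <- function(x) round(x * 1024) / 1024

#' Write a schema-valid fixture HDF5 dataset with planted availability
#'
#' Generates `n_groups` isomer groups of random-chain molecules, each with a
#' random conformer count in `nc_range`. Every group carries
#' `wb97x_dz.energy`, `coordinates` and forces for all conformers; the
#' coupled-cluster composite energy `ccsd(t)_cbs.energy` is `NaN` for a
#' planted fraction `missing_fraction` of conformers, so key-filtered loader
#' counts are predictable. All single-precision values lie on a 1/1024 grid
#' so storage round-trips bitwise.
#'
#' @param path output file path.
#' @param n_groups number of isomer groups.
#' @param nc_range length-2 range of conformers per group.
#' @param missing_fraction fraction of conformers without the composite
#'   energy.
#' @param seed integer seed.
#' @param all_keys if `TRUE`, one group carries every supported property key.
#' @return `path`, with the planted bookkeeping (per-group conformer and
#'   non-missing counts) in the `"planted"` attribute.
#' @export
make_fixture_h5 <- function(path, n_groups = 5L, nc_range = c(3L, 12L),
                            missing_fraction = 0.3, seed = 1L,
                            all_keys = FALSE) {
  set.seed(seed)
  groups <- list()
  planted <- data.frame(group_key = character(), nc = integer(),
                        n_with_cc = integer(), stringsAsFactors = FALSE)
  for (g in seq_len(n_groups)) {
    mol <- .toy_chain(sample(2:4, 1), seed = seed * 1000L + g)
    na <- n_atoms(mol)
    nc <- sample(nc_range[1]:nc_range[2], 1)
    coords <- array(0, dim = c(nc, na, 3))
    for (c_idx in seq_len(nc)) {
      coords[c_idx, , ] <- .f4grid(mol$coordinates +
                                     matrix(stats::rnorm(na * 3, sd = 0.05),
                                            na, 3))
    }
    e_dft <- round(stats::rnorm(nc, mean = -40, sd = 0.5), 6)
    miss <- stats::runif(nc) < missing_fraction
    e_cc <- round(e_dft + stats::rnorm(nc, sd = 0.01), 6)
    e_cc[miss] <- NaN
    forces <- array(.f4grid(stats::rnorm(nc * na * 3, sd = 0.05)),
                    dim = c(nc, na, 3))
    props <- list("coordinates" = coords,
                  "wb97x_dz.energy" = e_dft,
                  "ccsd(t)_cbs.energy" = e_cc,
                  "wb97x_dz.forces" = forces)
    if (all_keys && g == 1L) {
      schema <- property_schema()
      for (key in setdiff(schema$key,
                          c(names(props), "atomic_numbers"))) {
        row <- schema[schema$key == key, ]
        dims <- schema_dims(row$shape, nc, na)
        vals <- if (row$dtype == "f8")
          round(stats::rnorm(prod(dims)), 6) else
            .f4grid(stats::rnorm(prod(dims)))
        props[[key]] <- array(vals, dim = dims)
      }
    }
    gk <- make_group_key(mol$atomic_numbers, g)
    groups[[length(groups) + 1L]] <- conformer_group(gk, mol$atomic_numbers,
                                                     props)
    planted <- rbind(planted,
                     data.frame(group_key = gk, nc = nc,
                                n_with_cc = sum(!miss),
                                stringsAsFactors = FALSE))
  }
  write_dataset(groups, path)
  attr(path, "planted") <- planted
  invisible(path)
}

# independent reference composite used for fixture ground truth: written as
# the literal six-term weighted sum, separate from the cbs module code path
.reference_composite <- function(hf3, hf4, mp2_3, mp2_4, npno2, npno3, tpno2,
                                 alpha = 5.46, beta = 3.05) {
  t1 <- (exp(-alpha * sqrt(4)) * hf3 - exp(-alpha * sqrt(3)) * hf4) /
    (exp(-alpha * sqrt(4)) - exp(-alpha * sqrt(3)))
  t2 <- (4^beta * mp2_4 - 3^beta * mp2_3) / (4^beta - 3^beta)
  t1 + t2 - mp2_3 + npno3 + tpno2 - npno2
}

#' Write a random component-energy table with reference composites
#'
#' Generates `n_records` random sets of HF/MP2/coupled-cluster component
#' energies in the format read by [read_components()], plus a reference file
#' (`<path>.truth.csv`) with composites computed by an independent code path
#' for cross-checking.
#'
#' @param path output CSV path.
#' @param n_records number of records.
#' @param seed integer seed.
#' @return `path`; the reference data.frame is in the `"truth"` attribute.
#' @export
make_component_table <- function(path, n_records = 50L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  truth <- data.frame(id = character(), composite = numeric(),
                      stringsAsFactors = FALSE)
  for (r in seq_len(n_records)) {
    id <- sprintf("rec%04d", r)
    hf3 <- stats::rnorm(1, -76, 5); hf4 <- hf3 - stats::runif(1, 0, 0.05)
    mp2_3 <- -stats::runif(1, 0.1, 0.6)
    mp2_4 <- mp2_3 - stats::runif(1, 0, 0.05)
    npno2 <- -stats::runif(1, 0.1, 0.6)
    npno3 <- npno2 - stats::runif(1, 0, 0.05)
    tpno2 <- npno2 - stats::runif(1, 0, 0.01)
    rows[[r]] <- data.frame(
      id = id,
      method = c("hf", "hf", "mp2_corr", "mp2_corr", "npno_ccsdt_corr",
                 "npno_ccsdt_corr", "tpno_ccsdt_corr"),
      cardinal = c(3, 4, 3, 4, 2, 3, 2),
      energy_Ha = c(hf3, hf4, mp2_3, mp2_4, npno2, npno3, tpno2),
      stringsAsFactors = FALSE)
    truth <- rbind(truth, data.frame(
      id = id,
      composite = .reference_composite(hf3, hf4, mp2_3, mp2_4, npno2, npno3,
                                       tpno2),
      stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(truth, paste0(path, ".truth.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  attr(path, "truth") <- truth
  invisible(path)
}

# ---- toy potentials for integrator / active-learning tests -----------------

#' Isotropic harmonic toy potential
#'
#' `E = 0.5 * k * sum((x - x0)^2)`, one spring per atom to its reference
#' position. Useful for thermostat and integrator checks.
#'
#' @param reference reference [conformation()].
#' @param k force constant (Ha/Angstrom^2).
#' @return a potential (list with `energy`, `forces`).
#' @export
harmonic_potential <- function(reference, k = 0.05) {
  x0 <- reference$coordinates
  list(energy = function(conf) 0.5 * k * sum((conf$coordinates - x0)^2),
       forces = function(conf) -k * (conf$coordinates - x0))
}

#' Toy two-dimensional potential energy surface
#'
#' A smooth three-well surface on roughly `[-2, 2]^2`, used by the
#' active-learning recovery experiments. The "conformation" is a single atom
#' whose (x, y) coordinates are the surface coordinates.
#'
#' @param x,y surface coordinates (vectorized).
#' @return energy values (Ha-scaled arbitrary units).
#' @export
toy_pes_2d <- function(x, y) {
  -0.8 * exp(-((x - 1)^2 + y^2) / 0.6) -
    1.0 * exp(-((x + 1)^2 + (y - 0.8)^2) / 0.4) -
    0.6 * exp(-(x^2 + (y + 1.2)^2) / 0.5) +
    0.05 * (x^2 + y^2)
}

#' Single-point conformation on the toy 2-D surface
#' @param x,y surface coordinates.
#' @return a 1-atom [conformation()] at (x, y, 0).
#' @export
pes_point <- function(x, y) conformation(6L, matrix(c(x, y, 0), 1, 3))
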