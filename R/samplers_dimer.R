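# Dimer sampling: random periodic boxes of small molecules, short Langevin
# MD, decomposition into minimum-image contact dimers, disagreement
# selection.

#' Configuration for dimer sampling
#'
#' Defaults follow the published protocol: rectangular cell edges drawn
#' uniformly from 20-30 Angstrom, a 1.5 Angstrom minimum intermolecular
#' placement distance, MD at 50-600 K for 100 steps, and a 6 Angstrom contact
#' cutoff for dimer extraction. The atom-density range and size-bias exponent
#' are exposed configuration (the density range yields roughly 5-40 small
#' molecules per box).
#'
#' @param cell_range_A cell edge range (Angstrom).
#' @param min_intermolecular_dist_A placement exclusion distance (Angstrom).
#' @param temp_range_K MD temperature range (K).
#' @param md_steps number of Langevin steps before decomposition.
#' @param contact_cutoff_A dimer contact cutoff (Angstrom).
#' @param rho_threshold selection threshold (kcal/mol/sqrt(atom)).
#' @param density_range target atom density range (atoms/Angstrom^3).
#' @param size_bias_exponent molecules drawn with probability proportional to
#'   `n_heavy^(-size_bias_exponent)` (0 = uniform).
#' @param max_place_attempts placement retries per molecule before failing.
#' @param dt_fs,friction_per_fs Langevin integrator parameters.
#' @return list with class `dimer_config`.
#' @export
dimer_config <- function(cell_range_A = c(20, 30),
                         min_intermolecular_dist_A = 1.5,
                         temp_range_K = c(50, 600), md_steps = 100L,
                         contact_cutoff_A = 6.0, rho_threshold = 1.0,
                         density_range = c(0.005, 0.02),
                         size_bias_exponent = 1,
                         max_place_attempts = 200L,
                         dt_fs = 0.5, friction_per_fs = 0.02) {
  stopifnot(length(cell_range_A) == 2L, all(cell_range_A > 0),
            cell_range_A[1] <= cell_range_A[2],
            min_intermolecular_dist_A > 0, contact_cutoff_A > 0,
            md_steps >= 0L, all(density_range > 0),
            density_range[1] <= density_range[2])
  structure(list(cell_range_A = cell_range_A,
                 min_intermolecular_dist_A = min_intermolecular_dist_A,
                 temp_range_K = temp_range_K, md_steps = as.integer(md_steps),
                 contact_cutoff_A = contact_cutoff_A,
                 rho_threshold = rho_threshold,
                 density_range = density_range,
                 size_bias_exponent = size_bias_exponent,
                 max_place_attempts = as.integer(max_place_attempts),
                 dt_fs = dt_fs, friction_per_fs = friction_per_fs),
            class = "dimer_config")
}

#' Draw molecules for a box, biased toward small molecules
#'
#' Samples molecules from the pool with replacement, with probability
#' proportional to `n_heavy^(-cfg$size_bias_exponent)` (all-hydrogen species
#' count as one heavy atom for weighting), until the drawn target atom
#' density is reached for the given box volume. Consumes the current RNG
#' stream.
#'
#' @param pool non-empty list of [conformation()]s.
#' @param cfg a [dimer_config()].
#' @param volume box volume (Angstrom^3); default the midpoint 25 A cell.
#' @param target_density atoms/Angstrom^3; drawn uniformly from
#'   `cfg$density_range` when `NULL`.
#' @return list of [conformation()]s (with `"pool_index"` attributes).
#' @export
choose_molecules <- function(pool, cfg = dimer_config(), volume = 25^3,
                             target_density = NULL) {
  if (length(pool) == 0L) stop("molecule pool is empty")
  if (is.null(target_density))
    target_density <- stats::runif(1, cfg$density_range[1],
                                   cfg$density_range[2])
  n_heavy <- vapply(pool, function(m) max(1L, sum(m$atomic_numbers > 1L)),
                    integer(1))
  w <- n_heavy^(-cfg$size_bias_exponent)
  target_atoms <- target_density * volume
  chosen <- list()
  total <- 0
  while (total < target_atoms) {
    pick <- sample.int(length(pool), 1L, prob = w)
    mol <- pool[[pick]]
    attr(mol, "pool_index") <- pick
    chosen[[length(chosen) + 1L]] <- mol
    total <- total + n_atoms(mol)
  }
  chosen
}

# uniform random rotation matrix (random unit quaternion)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Pack molecules into a random periodic box
#'
#' Each molecule is rigidly rotated (uniform random rotation) and translated
#' to a uniform random position in a rectangular cell whose edges are drawn
#' uniformly from `cfg$cell_range_A` (unless `cell` is given). A placement is
#' accepted only if every minimum-image distance to atoms of already-placed
#' molecules is at least `cfg$min_intermolecular_dist_A`; after
#' `cfg$max_place_attempts` failures the box is declared too dense. Monomer
#' coordinates are stored unwrapped (molecules are never split across the
#' boundary).
#'
#' @param molecules non-empty list of [conformation()]s.
#' @param cfg a [dimer_config()].
#' @param cell optional fixed cell edges (length 3).
#' @return a [conformation()] with `cell` and `molecule_ids`.
#' @export
build_box <- function(molecules, cfg = dimer_config(), cell = NULL) {
  if (length(molecules) == 0L) stop("no molecules to place")
  if (is.null(cell))
    cell <- stats::runif(3, cfg$cell_range_A[1], cfg$cell_range_A[2])
  placed_xyz <- NULL
  zs <- integer(); ids <- integer()
  for (m in seq_along(molecules)) {
    mol <- molecules[[m]]
    x0 <- mol$coordinates
    centroid <- colMeans(x0)
    ok <- FALSE
    for (attempt in seq_len(cfg$max_place_attempts)) {
      R <- random_rotation()
      shift <- stats::runif(3, 0, cell)
      xr <- sweep(x0, 2, centroid) %*% t(R)
      xr <- sweep(xr, 2, shift, "+")
      if (is.null(placed_xyz) ||
          min(cross_distances(xr, placed_xyz, cell)) >=
            cfg$min_intermolecular_dist_A) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(
        "placement failed for molecule %d after %d attempts: box too dense",
        m, cfg$max_place_attempts))
    placed_xyz <- rbind(placed_xyz, xr)
    zs <- c(zs, mol$atomic_numbers)
    ids <- c(ids, rep(m, n_atoms(mol)))
  }
  conformation(zs, placed_xyz, cell = cell, molecule_ids = ids)
}

#' Decompose a periodic box into contact dimers
#'
#' One dimer per unordered molecule pair whose minimum-image cross-molecule
#' distance is within `cutoff_A`. The second monomer is translated by the
#' lattice vector that realizes the minimum-image separation of the closest
#' cross pair, so the contact is at its minimum-image geometry; dimers carry
#' no cell.
#'
#' @param box a [conformation()] with `molecule_ids` (and usually a cell).
#' @param cutoff_A contact distance cutoff (Angstrom), default 6.
#' @return list of dimer [conformation()]s; each has `molecule_ids` 1/2 and a
#'   `"monomers"` attribute with the parent molecule ids.
#' @export
decompose_to_dimers <- function(box, cutoff_A = 6.0) {
  if (is.null(box$molecule_ids))
    stop("box has no molecule_ids; cannot decompose")
  ids <- sort(unique(box$molecule_ids))
  out <- list()
  for (ai in seq_along(ids)) {
    for (bi in seq_along(ids)) {
      if (bi <= ai) next
      sel_a <- box$molecule_ids == ids[ai]
      sel_b <- box$molecule_ids == ids[bi]
      xa <- box$coordinates[sel_a, , drop = FALSE]
      xb <- box$coordinates[sel_b, , drop = FALSE]
      dmat <- cross_distances(xa, xb, box$cell)
      if (min(dmat) > cutoff_A) next
      amin <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      if (!is.null(box$cell)) {
        draw <- xb[amin[2], ] - xa[amin[1], ]
        lat <- -box$cell * round(draw / box$cell)
        xb <- sweep(xb, 2, lat, "+")
      }
      dim_conf <- conformation(
        c(box$atomic_numbers[sel_a], box$atomic_numbers[sel_b]),
        rbind(xa, xb), cell = NULL,
        molecule_ids = c(rep(1L, nrow(xa)), rep(2L, nrow(xb))))
      attr(dim_conf, "monomers") <- c(ids[ai], ids[bi])
      out[[length(out) + 1L]] <- dim_conf
    }
  }
  out
}

#' One full dimer-sampling round
#'
#' Draws a cell and an atom density, selects molecules (small-molecule
#' biased), packs the box, runs `cfg$md_steps` Langevin steps at a
#' temperature drawn from `cfg$temp_range_K`, decomposes the box into contact
#' dimers, and keeps dimers whose ensemble disagreement exceeds
#' `cfg$rho_threshold`.
#'
#' @param pool list of monomer [conformation()]s.
#' @param ensemble a [potential_ensemble()].
#' @param cfg a [dimer_config()].
#' @param seed integer seed.
#' @return a [selection_batch()]; provenance records the box seed, the
#'   monomer ids and the MD temperature.
#' @export
dimer_sampling_round <- function(pool, ensemble, cfg = dimer_config(),
                                 seed = 1L) {
  set.seed(seed)
  cell <- stats::runif(3, cfg$cell_range_A[1], cfg$cell_range_A[2])
  mols <- choose_molecules(pool, cfg, volume = prod(cell))
  box <- build_box(mols, cfg, cell = cell)
  temperature <- stats::runif(1, cfg$temp_range_K[1], cfg$temp_range_K[2])
  if (cfg$md_steps > 0L) {
    masses <- atomic_masses(box$atomic_numbers)
    vel <- maxwell_boltzmann_velocities(masses, temperature)
    pot <- mean_potential(ensemble)
    mdcfg <- md_config(temp_range_K = cfg$temp_range_K, dt_fs = cfg$dt_fs,
                       friction_per_fs = cfg$friction_per_fs)
    forces <- NULL
    for (step in seq_len(cfg$md_steps)) {
      st <- langevin_step(box, vel, masses, temperature, mdcfg, pot$forces,
                          forces)
      box <- st$conformation; vel <- st$velocities; forces <- st$forces
    }
  }
  dimers <- decompose_to_dimers(box, cfg$contact_cutoff_A)
  cands <- lapply(dimers, function(d) {
    list(conformation = d,
         prediction = ensemble_prediction(ensemble_energies(ensemble, d),
                                          n_atoms(d)),
         provenance = list(sampler = "dimer", box_seed = seed,
                           monomers = attr(d, "monomers"),
                           temperature_K = temperature))
  })
  select_high_rho(cands, cfg$rho_threshold)
}
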