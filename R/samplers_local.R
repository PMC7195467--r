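# Single-molecule samplers: disagreement-gated Langevin molecular dynamics
# and harmonic normal-mode displacement sampling.

#' Configuration for molecular-dynamics sampling
#'
#' Defaults follow the published protocol: simulation temperature drawn
#' uniformly between 50 and 800 K, 0.5 fs time step, 0.02 1/fs friction, and
#' a disagreement check every 5 steps. The trajectory cap `max_steps` and the
#' rho threshold are configuration (thresholds are campaign-specific and the
#' shipped default is an arbitrary choice).
#'
#' @param temp_range_K length-2 temperature range (K).
#' @param dt_fs integration time step (fs).
#' @param friction_per_fs Langevin friction coefficient (1/fs).
#' @param check_interval_steps steps between disagreement checks.
#' @param rho_threshold selection threshold (kcal/mol/sqrt(atom)).
#' @param max_steps trajectory cap.
#' @return list with class `md_config`.
#' @export
md_config <- function(temp_range_K = c(50, 800), dt_fs = 0.5,
                      friction_per_fs = 0.02, check_interval_steps = 5L,
                      rho_threshold = 1.0, max_steps = 10000L) {
  stopifnot(length(temp_range_K) == 2L, all(temp_range_K > 0),
            temp_range_K[1] <= temp_range_K[2],
            dt_fs > 0, friction_per_fs >= 0, check_interval_steps >= 1L,
            rho_threshold >= 0, max_steps >= 1L)
  structure(list(temp_range_K = temp_range_K, dt_fs = dt_fs,
                 friction_per_fs = friction_per_fs,
                 check_interval_steps = as.integer(check_interval_steps),
                 rho_threshold = rho_threshold,
                 max_steps = as.integer(max_steps)),
            class = "md_config")
}

#' Maxwell-Boltzmann velocities
#'
#' Draws per-component velocities from the Maxwell-Boltzmann distribution at
#' temperature `temperature_K` (units Angstrom/fs). Consumes the current RNG
#' stream.
#'
#' @param masses atomic masses (amu).
#' @param temperature_K temperature (K).
#' @return Na x 3 velocity matrix.
#' @export
maxwell_boltzmann_velocities <- function(masses, temperature_K) {
  na <- length(masses)
  sd <- sqrt(KB_HA_PER_K * temperature_K / (masses * AMU_A2_FS2_PER_HA))
  matrix(stats::rnorm(3L * na), na, 3) * sd
}

#' Instantaneous kinetic temperature
#'
#' `2 * KE / (3 * Na * kB)` with all 3Na degrees of freedom counted (no
#' center-of-mass removal).
#'
#' @param velocities Na x 3 matrix (Angstrom/fs).
#' @param masses atomic masses (amu).
#' @return temperature (K).
#' @export
kinetic_temperature <- function(velocities, masses) {
  ke <- 0.5 * sum(masses * rowSums(velocities^2)) * AMU_A2_FS2_PER_HA
  2 * ke / (3 * length(masses) * KB_HA_PER_K)
}

#' One Langevin (BAOAB) integration step
#'
#' Kick - drift - Ornstein-Uhlenbeck - drift - kick splitting. With zero
#' friction the stochastic piece is skipped entirely (no RNG draw) and the
#' update is exactly one velocity-Verlet step. Deterministic given the R RNG
#' state.
#'
#' @param conf current [conformation()].
#' @param velocities Na x 3 velocity matrix (Angstrom/fs).
#' @param masses atomic masses (amu).
#' @param temperature_K thermostat set point (K).
#' @param cfg an [md_config()] (supplies `dt_fs` and `friction_per_fs`).
#' @param force_fn function(conformation) -> Na x 3 forces (Ha/Angstrom).
#' @param forces optional forces at `conf` (recomputed when `NULL`).
#' @return list with `conformation`, `velocities`, `forces` (at the new
#'   geometry).
#' @export
langevin_step <- function(conf, velocities, masses, temperature_K, cfg,
                          force_fn, forces = NULL) {
  if (is.null(forces)) forces <- force_fn(conf)
  if (!all(is.finite(forces)))
    stop("non-finite force: the potential blew up")
  dt <- cfg$dt_fs
  gamma <- cfg$friction_per_fs
  macc <- masses * AMU_A2_FS2_PER_HA
  v <- velocities + (dt / 2) * forces / macc
  x <- conf$coordinates + (dt / 2) * v
  if (gamma > 0) {
    c1 <- exp(-gamma * dt)
    c2 <- sqrt((1 - c1^2) * KB_HA_PER_K * temperature_K / macc)
    v <- c1 * v + c2 * matrix(stats::rnorm(length(v)), nrow(v), 3)
  }
  x <- x + (dt / 2) * v
  conf2 <- conformation(conf$atomic_numbers, x, conf$cell, conf$molecule_ids)
  f2 <- force_fn(conf2)
  if (!all(is.finite(f2)))
    stop("non-finite force: the potential blew up")
  v <- v + (dt / 2) * f2 / macc
  list(conformation = conf2, velocities = v, forces = f2)
}

#' Disagreement-gated molecular-dynamics sampling
#'
#' Runs ensemble-mean-driven Langevin dynamics at a temperature drawn
#' uniformly from `cfg$temp_range_K`, evaluating the ensemble disagreement
#' every `cfg$check_interval_steps` steps. At the first check with
#' `rho > cfg$rho_threshold` the trajectory halts and that single structure is
#' returned (the potential is assumed untrustworthy beyond it); if
#' `cfg$max_steps` is reached the batch is empty.
#'
#' @param mol starting [conformation()].
#' @param ensemble a [potential_ensemble()].
#' @param cfg an [md_config()].
#' @param seed integer seed (drives temperature, velocities and noise).
#' @param parent_id provenance identifier of the starting molecule.
#' @param record if `TRUE`, attach the per-check rho values (and step ids) as
#'   the `"checks"` attribute for replay audits.
#' @return a [selection_batch()] with 0 or 1 entries.
#' @export
md_sample <- function(mol, ensemble, cfg = md_config(), seed = 1L,
                      parent_id = "mol", record = FALSE) {
  set.seed(seed)
  temperature <- stats::runif(1, cfg$temp_range_K[1], cfg$temp_range_K[2])
  masses <- atomic_masses(mol$atomic_numbers)
  vel <- maxwell_boltzmann_velocities(masses, temperature)
  pot <- mean_potential(ensemble)
  conf <- mol
  forces <- NULL
  checks <- list()
  batch <- selection_batch()
  for (step in seq_len(cfg$max_steps)) {
    st <- langevin_step(conf, vel, masses, temperature, cfg, pot$forces,
                        forces)
    conf <- st$conformation; vel <- st$velocities; forces <- st$forces
    if (step %% cfg$check_interval_steps == 0L) {
      r <- ensemble_rho(ensemble, conf)
      if (record)
        checks[[length(checks) + 1L]] <- list(step = step, rho = r,
                                              conformation = conf)
      if (r > cfg$rho_threshold) {
        batch <- selection_batch(list(list(
          conformation = conf, rho = r,
          provenance = list(sampler = "md", parent_id = parent_id,
                            seed = seed, step = step,
                            temperature_K = temperature))))
        break
      }
    }
  }
  if (record) attr(batch, "checks") <- checks
  batch
}

#' Generate conformers by harmonic normal-mode displacement
#'
#' Each conformer displaces the reference geometry along every mode by a
#' random signed amount scaled so the harmonic energy deposited in mode `i`
#' is `c_i * kT` with `c_i` uniform on `[0, 1)`; the expected total harmonic
#' energy is therefore `n_modes * kT / 2`. Modes with non-positive force
#' constant are skipped (recorded in the `"skipped_modes"` attribute).
#'
#' @param modes a [normal_modes()].
#' @param n_conf number of conformers to generate.
#' @param temperature_K sampling temperature (K); 0 reproduces the reference.
#' @param seed integer seed.
#' @return list of [conformation()]s, with the per-conformer mode
#'   displacements in the `"displacements"` attribute (n_conf x n_modes).
#' @export
nms_generate <- function(modes, n_conf, temperature_K = 300, seed = 1L) {
  stopifnot(n_conf >= 1L, temperature_K >= 0)
  set.seed(seed)
  kvec <- modes$force_constants
  usable <- kvec > 0
  if (any(!usable))
    warning(sum(!usable), " mode(s) with non-positive force constant skipped")
  kT_ha <- KB_HA_PER_K * temperature_K
  nm <- length(kvec)
  out <- vector("list", n_conf)
  qmat <- matrix(0, n_conf, nm)
  for (c_idx in seq_len(n_conf)) {
    x <- modes$reference$coordinates
    for (m in seq_len(nm)) {
      if (!usable[m]) next
      ci <- stats::runif(1)
      sgn <- sample(c(-1, 1), 1)
      q <- sgn * sqrt(2 * ci * kT_ha / kvec[m])
      qmat[c_idx, m] <- q
      x <- x + q * modes$mode_vectors[[m]]
    }
    out[[c_idx]] <- conformation(modes$reference$atomic_numbers, x)
  }
  attr(out, "displacements") <- qmat
  attr(out, "skipped_modes") <- which(!usable)
  out
}

#' Harmonic energy of mode displacements
#'
#' @param modes a [normal_modes()].
#' @param q numeric vector of per-mode displacements.
#' @return total harmonic energy (Ha).
#' @export
harmonic_energy <- function(modes, q) sum(0.5 * modes$force_constants * q^2)

#' Normal-mode sampling with disagreement selection
#'
#' Generates `n_conf` conformers with [nms_generate()], evaluates the
#' ensemble disagreement on each, and keeps those above `threshold`.
#'
#' @inheritParams nms_generate
#' @param ensemble a [potential_ensemble()].
#' @param threshold rho selection threshold (kcal/mol/sqrt(atom)).
#' @param parent_id provenance identifier.
#' @return a [selection_batch()].
#' @export
nms_sample <- function(modes, ensemble, n_conf, temperature_K = 300,
                       threshold = 1.0, seed = 1L, parent_id = "mol") {
  confs <- nms_generate(modes, n_conf, temperature_K, seed)
  cands <- lapply(seq_along(confs), function(i) {
    conf <- confs[[i]]
    list(conformation = conf,
         prediction = ensemble_prediction(ensemble_energies(ensemble, conf),
                                          n_atoms(conf)),
         provenance = list(sampler = "nms", parent_id = parent_id,
                           seed = seed, index = i,
                           temperature_K = temperature_K))
  })
  select_high_rho(cands, threshold)
}
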