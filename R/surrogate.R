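# Surrogate potential ensembles: cheap analytic pairwise Morse potentials
# with controllable, optionally geometry-localized, member disagreement.
# They honor the potential-ensemble contract (energies Ha, forces Ha/A,
# minimum-image aware when a conformation carries a cell) and stand in for
# trained ML potential ensembles in tests and demonstrations.

# pair list + minimum-image displacements/distances for a conformation
.pair_geometry <- function(conf) {
  na <- n_atoms(conf)
  if (na < 2L)
    return(list(i = integer(), j = integer(), d = matrix(0, 0, 3),
                r = numeric(), r0 = numeric()))
  idx <- which(upper.tri(diag(na)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  x <- conf$coordinates
  d <- x[j, , drop = FALSE] - x[i, , drop = FALSE]
  if (!is.null(conf$cell)) {
    cl <- rep(conf$cell, each = nrow(d))
    d <- d - cl * round(d / cl)
  }
  r <- sqrt(rowSums(d^2))
  rc <- covalent_radii(conf$atomic_numbers)
  list(i = i, j = j, d = d, r = r, r0 = rc[i] + rc[j])
}

# scatter per-pair radial derivatives into per-atom forces:
# F_a = -dE/dx_a for E = sum over pairs f(r)
.pair_forces <- function(pg, dfdr, na) {
  f <- matrix(0, na, 3)
  if (!length(pg$i)) return(f)
  w <- dfdr / pg$r
  contrib <- pg$d * w            # dE/dx_i per pair (since dr/dx_i = -d/r)
  for (k in 1:3) {
    f[, k] <- f[, k] + rowsum_vec(contrib[, k], pg$i, na) -
      rowsum_vec(contrib[, k], pg$j, na)
  }
  f
}

rowsum_vec <- function(v, idx, n) {
  out <- numeric(n)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Build a surrogate potential ensemble
#'
#' Each ensemble shares an all-pairs Morse base potential (well depth
#' `well_depth` Ha, steepness `steepness` 1/Angstrom, equilibrium distance =
#' sum of covalent radii). Member `m` adds `amplitude * z_m * u(x)` where the
#' `z_m` are fixed, centered standard-normal draws (so the ensemble mean is
#' exactly the base potential) and `u(x)` is a smooth internal-coordinate
#' disagreement field selected by `localization`:
#'
#' * `"none"`: the dimensionless Morse shape summed over all pairs;
#' * `"stretch"`: a stretched-bond measure, zero at or below the pair
#'   equilibrium distance, growing with bond stretch and Gaussian-damped
#'   beyond the bonding range (so distant nonbonded pairs do not
#'   contribute);
#' * `"dihedral"`: a Gaussian window in one dihedral angle (`dihedral`,
#'   `dihedral_center_deg`, `dihedral_width_deg`).
#'
#' With `amplitude = 0` all members are identical and the disagreement
#' [ensemble_rho()] is identically zero; on a fixed conformation rho scales
#' linearly with `amplitude`. Forces are analytic.
#'
#' @param k number of ensemble members (>= 2).
#' @param amplitude disagreement amplitude (Ha per unit of `u`).
#' @param localization one of `"none"`, `"stretch"`, `"dihedral"`.
#' @param seed integer seed fixing the member offsets `z_m`.
#' @param dihedral integer vector (i, j, k, l) for `"dihedral"` localization.
#' @param dihedral_center_deg,dihedral_width_deg center and width (degrees)
#'   of the dihedral disagreement window.
#' @param well_depth Morse well depth (Ha).
#' @param steepness Morse exponent (1/Angstrom).
#' @return a [potential_ensemble()].
#' @export
make_surrogate_ensemble <- function(k = 5, amplitude = 0,
                                    localization = c("none", "stretch",
                                                     "dihedral"),
                                    seed = 1,
                                    dihedral = NULL,
                                    dihedral_center_deg = 0,
                                    dihedral_width_deg = 30,
                                    well_depth = 0.15, steepness = 2.0) {
  localization <- match.arg(localization)
  if (k < 2L) stop("ensemble needs k >= 2 members")
  if (localization == "dihedral" && (is.null(dihedral) ||
                                     length(dihedral) != 4L))
    stop("dihedral localization needs 4 atom indices")
  z <- withr_seed(seed, stats::rnorm(k))
  z <- z - mean(z)

  D <- well_depth; a <- steepness

  base_energy <- function(conf) {
    pg <- .pair_geometry(conf)
    em <- exp(-a * (pg$r - pg$r0))
    sum(D * ((1 - em)^2 - 1))
  }
  base_forces <- function(conf) {
    pg <- .pair_geometry(conf)
    em <- exp(-a * (pg$r - pg$r0))
    dfdr <- 2 * D * a * (1 - em) * em
    .pair_forces(pg, dfdr, n_atoms(conf))
  }

  u_value <- function(conf) {
    switch(localization,
      none = {
        pg <- .pair_geometry(conf)
        em <- exp(-a * (pg$r - pg$r0))
        sum((1 - em)^2)
      },
      stretch = {
        pg <- .pair_geometry(conf)
        del <- pmax(pg$r - pg$r0, 0)
        em <- exp(-a * del)
        sum((1 - em)^2 * exp(-(del / 0.5)^2))
      },
      dihedral = {
        phi <- dihedral_angle(conf$coordinates, dihedral[1], dihedral[2],
                              dihedral[3], dihedral[4])
        dphi <- wrap_angle(phi - dihedral_center_deg)
        exp(-0.5 * (dphi / dihedral_width_deg)^2)
      })
  }
  u_grad <- function(conf) {       # dU/dx, Na x 3
    switch(localization,
      none = {
        pg <- .pair_geometry(conf)
        em <- exp(-a * (pg$r - pg$r0))
        -.pair_forces(pg, 2 * a * (1 - em) * em, n_atoms(conf))
      },
      stretch = {
        pg <- .pair_geometry(conf)
        del <- pmax(pg$r - pg$r0, 0)
        em <- exp(-a * del)
        damp <- exp(-(del / 0.5)^2)
        dudr <- (2 * a * (1 - em) * em - (2 * del / 0.5^2) * (1 - em)^2) * damp
        dudr[pg$r <= pg$r0] <- 0
        -.pair_forces(pg, dudr, n_atoms(conf))
      },
      dihedral = {
        phi <- dihedral_angle(conf$coordinates, dihedral[1], dihedral[2],
                              dihedral[3], dihedral[4])
        dphi <- wrap_angle(phi - dihedral_center_deg)
        u <- exp(-0.5 * (dphi / dihedral_width_deg)^2)
        gdeg <- dihedral_gradient(conf$coordinates, dihedral[1], dihedral[2],
                                  dihedral[3], dihedral[4]) * 180 / pi
        (-dphi / dihedral_width_deg^2) * u * gdeg
      })
  }

  member <- function(zm) {
    list(
      energy = function(conf) base_energy(conf) + amplitude * zm * u_value(conf),
      forces = function(conf) {
        f <- base_forces(conf)
        if (amplitude != 0 && zm != 0) f <- f - amplitude * zm * u_grad(conf)
        f
      })
  }
  members <- lapply(z, member)
  mean_pot <- list(energy = base_energy, forces = base_forces)
  potential_ensemble(members, mean = mean_pot)
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
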