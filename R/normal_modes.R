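# Harmonic normal modes: container, finite-difference Hessian helper, and
# JSON (de)serialization.  Mode vectors are stored as Cartesian displacement
# shapes d_i (Na x 3) that are mass-orthonormal (d_i' M d_j = delta_ij, M the
# diagonal atomic-mass matrix); a displacement q along mode i moves the
# geometry by q * d_i and costs harmonic energy 0.5 * k_i * q^2, where k_i is
# the mass-weighted Hessian eigenvalue.

#' Construct a set of harmonic normal modes
#'
#' @param reference the reference [conformation()] (equilibrium geometry).
#' @param force_constants numeric vector of per-mode harmonic force constants
#'   (mass-weighted Hessian eigenvalues, Ha/(amu A^2)).
#' @param mode_vectors list of Na x 3 displacement matrices, mass-orthonormal
#'   with respect to `masses`.
#' @param masses atomic masses (amu); defaults to standard masses of the
#'   reference's elements.
#' @param check if `TRUE` (default), verify mass-orthonormality to 1e-6.
#' @return object of class `normal_modes`.
#' @export
normal_modes <- function(reference, force_constants, mode_vectors,
                         masses = NULL, check = TRUE) {
  if (is.null(masses)) masses <- atomic_masses(reference$atomic_numbers)
  nm <- length(force_constants)
  if (length(mode_vectors) != nm)
    stop("force_constants and mode_vectors lengths differ")
  if (check && nm > 0) {
    for (i in seq_len(nm)) {
      for (j in i:nm) {
        ip <- sum(masses * rowSums(mode_vectors[[i]] * mode_vectors[[j]]))
        if (abs(ip - as.numeric(i == j)) > 1e-6)
          stop(sprintf("mode vectors not mass-orthonormal (modes %d,%d: %g)",
                       i, j, ip))
      }
    }
  }
  structure(list(reference = reference,
                 force_constants = as.numeric(force_constants),
                 mode_vectors = mode_vectors, masses = as.numeric(masses)),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("<normal_modes>", length(x$force_constants), "modes,",
      n_atoms(x$reference), "atoms\n")
  invisible(x)
}

#' Finite-difference Hessian of a potential
#'
#' Central differences of the analytic forces (step `step` Angstrom),
#' symmetrized. Units Ha/A^2.
#'
#' @param potential a potential (list with `energy` and `forces`).
#' @param conf the [conformation()] at which to differentiate.
#' @param step displacement step (Angstrom), default 0.005.
#' @return 3Na x 3Na symmetric matrix.
#' @export
fd_hessian <- function(potential, conf, step = 0.005) {
  na <- n_atoms(conf)
  n <- 3L * na
  H <- matrix(0, n, n)
  x0 <- conf$coordinates
  for (p in seq_len(n)) {
    at <- (p - 1L) %/% 3L + 1L
    cc <- (p - 1L) %% 3L + 1L
    xp <- x0; xp[at, cc] <- xp[at, cc] + step
    xm <- x0; xm[at, cc] <- xm[at, cc] - step
    fp <- potential$forces(conformation(conf$atomic_numbers, xp, conf$cell))
    fm <- potential$forces(conformation(conf$atomic_numbers, xm, conf$cell))
    # H = d2E/dx2 = -dF/dx; flatten row-major per atom (x,y,z)
    H[, p] <- -as.numeric(t(fp - fm)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Normal modes of a potential at a geometry
#'
#' Mass-weights the finite-difference Hessian, diagonalizes it, and keeps
#' modes whose eigenvalue exceeds `drop_tol` (discarding rigid translations,
#' rotations and any soft/imaginary mode, each recorded in the
#' `"dropped_modes"` attribute).
#'
#' @inheritParams fd_hessian
#' @param masses atomic masses (amu); defaults to standard masses.
#' @param drop_tol eigenvalue cutoff (Ha/(amu A^2)) below which modes are
#'   dropped, default 1e-3: vibrational eigenvalues of molecular potentials
#'   in these units are of order 0.1-10, while rigid-motion contamination of
#'   the finite-difference Hessian is of order 1e-4.
#' @return a [normal_modes()] object.
#' @export
normal_modes_from_potential <- function(potential, conf, masses = NULL,
                                        step = 0.005, drop_tol = 1e-3) {
  if (is.null(masses)) masses <- atomic_masses(conf$atomic_numbers)
  H <- fd_hessian(potential, conf, step)
  minv <- rep(1 / sqrt(masses), each = 3L)
  Hm <- H * outer(minv, minv)
  eg <- eigen(Hm, symmetric = TRUE)
  keep <- eg$values > drop_tol
  vecs <- lapply(which(keep), function(m) {
    d <- eg$vectors[, m] * minv
    matrix(d, n_atoms(conf), 3, byrow = TRUE)
  })
  nm <- normal_modes(conf, eg$values[keep], vecs, masses = masses)
  attr(nm, "dropped_modes") <- eg$values[!keep]
  nm
}

#' Serialize normal modes to JSON
#' @param modes a [normal_modes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modes_json <- function(modes, path) {
  obj <- list(
    atomic_numbers = modes$reference$atomic_numbers,
    coordinates = modes$reference$coordinates,
    masses = modes$masses,
    force_constants = modes$force_constants,
    mode_vectors = lapply(modes$mode_vectors, identity)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read normal modes from JSON
#' @param path path written by [write_modes_json()].
#' @return a [normal_modes()].
#' @export
read_modes_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- conformation(obj$atomic_numbers, obj$coordinates)
  vecs <- if (is.list(obj$mode_vectors)) {
    lapply(obj$mode_vectors, function(v) matrix(as.numeric(unlist(v)),
                                                ncol = 3))
  } else {
    lapply(seq_len(dim(obj$mode_vectors)[1]),
           function(m) obj$mode_vectors[m, , ])
  }
  normal_modes(ref, obj$force_constants, vecs, masses = obj$masses)
}
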