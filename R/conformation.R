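#' Construct a molecular conformation
#'
#' A conformation bundles atomic numbers with Cartesian coordinates, plus an
#' optional rectangular periodic cell and optional per-atom molecule ids (used
#' for multi-molecule boxes built by the dimer sampler).
#'
#' @param atomic_numbers integer vector of atomic numbers Z (length Na).
#' @param coordinates numeric Na x 3 matrix of Cartesian coordinates in
#'   Angstrom.
#' @param cell optional numeric length-3 vector of rectangular cell edge
#'   lengths (Angstrom), or `NULL` for a free molecule.
#' @param molecule_ids optional integer vector (length Na) assigning each atom
#'   to a monomer, or `NULL`.
#' @return An object of class `conformation`.
#' @examples
#' w <- conformation(c(8, 1, 1),
#'                   rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' n_atoms(w)
#' @export
conformation <- function(atomic_numbers, coordinates, cell = NULL,
                         molecule_ids = NULL) {
  atomic_numbers <- as.integer(atomic_numbers)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (ncol(coordinates) != 3L)
    stop("coordinates must have 3 columns")
  if (length(atomic_numbers) != nrow(coordinates))
    stop("length(atomic_numbers) must equal the number of coordinate rows")
  if (!all(is.finite(coordinates)))
    stop("coordinates must all be finite")
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 3L || !all(is.finite(cell)) || any(cell <= 0))
      stop("cell must be 3 positive finite edge lengths")
  }
  if (!is.null(molecule_ids)) {
    molecule_ids <- as.integer(molecule_ids)
    if (length(molecule_ids) != length(atomic_numbers))
      stop("molecule_ids must have one entry per atom")
  }
  structure(list(atomic_numbers = atomic_numbers, coordinates = coordinates,
                 cell = cell, molecule_ids = molecule_ids),
            class = "conformation")
}

#' Number of atoms in a conformation
#' @param conf a [conformation()].
#' @return integer atom count.
#' @export
n_atoms <- function(conf) length(conf$atomic_numbers)

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", n_atoms(x), " atoms (",
      paste(element_symbol(sort(unique(x$atomic_numbers))), collapse = ","),
      ")", if (!is.null(x$cell)) sprintf(" cell %.2f x %.2f x %.2f A",
                                         x$cell[1], x$cell[2], x$cell[3]),
      "\n", sep = "")
  invisible(x)
}

# displacement of b relative to a under the minimum-image convention for a
# rectangular cell; a, b are length-3 vectors or matrices with 3 columns
min_image_disp <- function(a, b, cell) {
  d <- b - a
  if (!is.null(cell)) {
    if (is.matrix(d)) {
      d <- d - rep(cell, each = nrow(d)) * round(d / rep(cell, each = nrow(d)))
    } else {
      d <- d - cell * round(d / cell)
    }
  }
  d
}

# all pairwise minimum-image distances between rows of xa and rows of xb
cross_distances <- function(xa, xb, cell = NULL) {
  na <- nrow(xa); nb <- nrow(xb)
  out <- matrix(0, na, nb)
  for (k in 1:3) {
    d <- outer(xa[, k], xb[, k], "-")
    if (!is.null(cell)) d <- d - cell[k] * round(d / cell[k])
    out <- out + d * d
  }
  sqrt(out)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four atoms
#'
#' Signed dihedral i-j-k-l in degrees, in (-180, 180].
#'
#' @param coordinates Na x 3 coordinate matrix (Angstrom).
#' @param i,j,k,l atom indices (1-based) defining the dihedral.
#' @return numeric angle in degrees.
#' @export
dihedral_angle <- function(coordinates, i, j, k, l) {
  b1 <- coordinates[j, ] - coordinates[i, ]
  b2 <- coordinates[k, ] - coordinates[j, ]
  b3 <- coordinates[l, ] - coordinates[k, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# gradient (radians per Angstrom) of the dihedral wrt all coordinates;
# returns Na x 3 matrix, nonzero only in rows i, j, k, l
dihedral_gradient <- function(coordinates, i, j, k, l) {
  b1 <- coordinates[j, ] - coordinates[i, ]
  b2 <- coordinates[k, ] - coordinates[j, ]
  b3 <- coordinates[l, ] - coordinates[k, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  gi <- nb2 / sum(n1^2) * n1
  gl <- -nb2 / sum(n2^2) * n2
  d12 <- sum(b1 * b2) / sum(b2^2)
  d32 <- sum(b3 * b2) / sum(b2^2)
  g <- matrix(0, nrow(coordinates), 3)
  g[i, ] <- gi
  g[j, ] <- (-1 - d12) * gi + d32 * gl
  g[k, ] <- d12 * gi + (-1 - d32) * gl
  g[l, ] <- gl
  g
}

# wrap an angle difference (degrees) into (-180, 180]
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}
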