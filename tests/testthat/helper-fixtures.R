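# shared test helpers: finite-difference force audits, tiny potentials, and
# random conformation generators

fd_forces <- function(potential, conf, h = 1e-5) {
  x0 <- conf$coordinates
  f <- matrix(0, nrow(x0), 3)
  for (a in seq_len(nrow(x0))) {
    for (c_ in 1:3) {
      xp <- x0; xp[a, c_] <- xp[a, c_] + h
      xm <- x0; xm[a, c_] <- xm[a, c_] - h
      f[a, c_] <- -(potential$energy(conformation(conf$atomic_numbers, xp,
                                                  conf$cell)) -
                    potential$energy(conformation(conf$atomic_numbers, xm,
                                                  conf$cell))) / (2 * h)
    }
  }
  f
}

random_conformation <- function(na = 5, seed = NULL, spread = 2) {
  if (!is.null(seed)) set.seed(seed)
  z <- sample(c(1L, 6L, 7L, 8L), na, replace = TRUE)
  conformation(z, matrix(stats::runif(na * 3, -spread, spread), na, 3))
}

rigid_transform <- function(conf, seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x),
                1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
  shift <- stats::runif(3, -5, 5)
  conformation(conf$atomic_numbers,
               sweep(conf$coordinates %*% t(R), 2, shift, "+"))
}

# harmonic potential in a set of pair distances (no dihedral dependence for
# the listed pairs): closed-form constrained-scan oracle for torsion tests
pair_distance_potential <- function(ref, pairs, k = 0.5) {
  x0 <- ref$coordinates
  r0 <- apply(pairs, 1, function(p) sqrt(sum((x0[p[1], ] - x0[p[2], ])^2)))
  list(
    energy = function(conf) {
      x <- conf$coordinates
      r <- apply(pairs, 1, function(p) sqrt(sum((x[p[1], ] - x[p[2], ])^2)))
      0.5 * k * sum((r - r0)^2)
    },
    forces = function(conf) {
      x <- conf$coordinates
      f <- matrix(0, nrow(x), 3)
      for (pi in seq_len(nrow(pairs))) {
        i <- pairs[pi, 1]; j <- pairs[pi, 2]
        d <- x[i, ] - x[j, ]
        r <- sqrt(sum(d^2))
        g <- k * (r - r0[pi]) * d / r
        f[i, ] <- f[i, ] - g
        f[j, ] <- f[j, ] + g
      }
      f
    })
}

# constant-energy-offset ensemble: members disagree by fixed offsets,
# independent of geometry
offset_ensemble <- function(offsets, base = NULL) {
  base_e <- if (is.null(base)) function(conf) 0 else base$energy
  base_f <- if (is.null(base)) function(conf) matrix(0, n_atoms(conf), 3) else
    base$forces
  members <- lapply(offsets, function(o) {
    list(energy = function(conf) base_e(conf) + o,
         forces = function(conf) base_f(conf))
  })
  potential_ensemble(members)
}
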