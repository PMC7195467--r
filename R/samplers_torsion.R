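# Torsion sampling: relaxed dihedral scans driven by the potential ensemble,
# disagreement-gated halting, and normal-mode perturbation of halted
# structures.

#' Configuration for torsion sampling
#'
#' Defaults follow the published protocol: 10 degree increments over the full
#' 36-step torsion profile, four perturbed conformations per halted scan, and
#' 20 iterations of the protocol.
#'
#' @param increment_deg scan increment (degrees); `increment_deg * n_steps`
#'   must equal 360.
#' @param n_steps number of scan steps.
#' @param n_perturbed perturbed conformations generated per halted scan.
#' @param n_iterations iterations of the full protocol.
#' @param rho_threshold halting threshold (kcal/mol/sqrt(atom)).
#' @param opt_tolerance convergence tolerance on the max projected force
#'   component (Ha/Angstrom).
#' @param opt_max_iter maximum minimizer iterations.
#' @param perturb_scale_K temperature equivalent controlling the perturbation
#'   magnitude (K); the published protocol says only "slightly perturbed",
#'   the 50 K default is this package's choice.
#' @return list with class `torsion_config`.
#' @export
torsion_config <- function(increment_deg = 10, n_steps = 36L,
                           n_perturbed = 4L, n_iterations = 20L,
                           rho_threshold = 1.0, opt_tolerance = 1e-3,
                           opt_max_iter = 200L, perturb_scale_K = 50) {
  if (abs(increment_deg * n_steps - 360) > 1e-9)
    stop("increment_deg * n_steps must equal 360")
  stopifnot(n_perturbed >= 1L, rho_threshold >= 0, opt_tolerance > 0)
  structure(list(increment_deg = increment_deg, n_steps = as.integer(n_steps),
                 n_perturbed = as.integer(n_perturbed),
                 n_iterations = as.integer(n_iterations),
                 rho_threshold = rho_threshold,
                 opt_tolerance = opt_tolerance,
                 opt_max_iter = as.integer(opt_max_iter),
                 perturb_scale_K = perturb_scale_K),
            class = "torsion_config")
}

#' Define a torsion (rotatable dihedral)
#'
#' @param i,j,k,l four distinct atom indices; the dihedral is measured
#'   i-j-k-l and rotation is about the j-k bond.
#' @param rotating integer indices of the atoms rotated with the l side; must
#'   contain `l`, must not contain `i`, `j` or `k`.
#' @return list with class `torsion_spec`.
#' @export
torsion_spec <- function(i, j, k, l, rotating) {
  idx <- c(i, j, k, l)
  if (anyDuplicated(idx)) stop("dihedral indices must be distinct")
  if (!(l %in% rotating)) stop("rotating set must contain l")
  if (any(c(i, j, k) %in% rotating))
    stop("rotating set must not contain i, j or k")
  structure(list(i = as.integer(i), j = as.integer(j), k = as.integer(k),
                 l = as.integer(l), rotating = as.integer(rotating)),
            class = "torsion_spec")
}

#' Rotating-side atom set of a bond
#'
#' Computes the set of atoms that move when rotating about the j-k bond: the
#' connected component of `k` in the covalent bond graph with the j-k edge
#' removed (excluding `k` itself, which lies on the axis). Errors if the bond
#' is in a ring.
#'
#' @param conf a [conformation()].
#' @param j,k bonded atom indices.
#' @return integer vector of rotating atom indices.
#' @export
torsion_rotating_set <- function(conf, j, k) {
  adj <- bond_adjacency(conf)
  adj[j, k] <- adj[k, j] <- FALSE
  seen <- rep(FALSE, n_atoms(conf))
  seen[k] <- TRUE
  queue <- k
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (seen[j]) stop("bond ", j, "-", k, " is in a ring: not rotatable")
  setdiff(which(seen), k)
}

#' Set a dihedral to a target angle
#'
#' Rigidly rotates the torsion's rotating set about the j-k axis so the
#' dihedral equals `target_deg` exactly (up to floating point).
#'
#' @param conf a [conformation()].
#' @param spec a [torsion_spec()].
#' @param target_deg target dihedral (degrees).
#' @return the rotated [conformation()].
#' @export
set_dihedral <- function(conf, spec, target_deg) {
  x <- conf$coordinates
  phi <- dihedral_angle(x, spec$i, spec$j, spec$k, spec$l)
  delta <- wrap_angle(target_deg - phi) * pi / 180
  axis <- x[spec$k, ] - x[spec$j, ]
  axis <- axis / sqrt(sum(axis^2))
  rot_about <- function(x, theta) {
    # Rodrigues rotation of the rotating set about the axis through x_j
    pts <- sweep(x[spec$rotating, , drop = FALSE], 2, x[spec$j, ])
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
    out <- x
    out[spec$rotating, ] <- sweep(pts %*% t(R), 2, x[spec$j, ], "+")
    out
  }
  x2 <- rot_about(x, delta)
  if (abs(wrap_angle(dihedral_angle(x2, spec$i, spec$j, spec$k, spec$l) -
                     target_deg)) > 1e-6)
    x2 <- rot_about(x, -delta)
  conformation(conf$atomic_numbers, x2, conf$cell, conf$molecule_ids)
}

#' Unconstrained geometry minimization
#'
#' Steepest descent with backtracking line search on the potential energy.
#'
#' @param conf starting [conformation()].
#' @param potential a potential (list with `energy`, `forces`).
#' @param tol convergence threshold on the max force component (Ha/Angstrom).
#' @param max_iter iteration cap; when reached the `"converged"` attribute of
#'   the result is `FALSE`.
#' @return the minimized [conformation()].
#' @export
minimize_geometry <- function(conf, potential, tol = 1e-3, max_iter = 200L) {
  x <- conf
  e <- potential$energy(x)
  if (!is.finite(e)) stop("non-finite energy at the starting geometry")
  eta <- 0.1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- potential$forces(x)
    if (max(abs(f)) <= tol) { converged <- TRUE; break }
    accepted <- FALSE
    for (bt in 1:25) {
      x2 <- conformation(x$atomic_numbers, x$coordinates + eta * f, x$cell,
                         x$molecule_ids)
      e2 <- potential$energy(x2)
      if (is.finite(e2) && e2 <= e) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break
    x <- x2; e <- e2
    eta <- min(eta * 1.2, 1.0)
  }
  attr(x, "converged") <- converged
  x
}

#' Constrained minimization at a fixed dihedral
#'
#' Minimizes the potential with the torsion held at `target_deg`: forces are
#' projected onto the constraint manifold (the component along the dihedral
#' gradient is removed), a backtracking steepest-descent step is taken, and
#' the dihedral is re-enforced exactly by rigid rotation after every step.
#'
#' @param conf starting [conformation()].
#' @param potential a potential (list with `energy`, `forces`).
#' @param spec a [torsion_spec()].
#' @param target_deg dihedral constraint (degrees).
#' @param tol convergence threshold on the max projected force component
#'   (Ha/Angstrom).
#' @param max_iter iteration cap (`"converged"` attribute reports the
#'   outcome).
#' @return the constrained-minimized [conformation()]; its dihedral is within
#'   0.1 degrees of `target_deg`.
#' @export
constrained_minimize <- function(conf, potential, spec, target_deg,
                                 tol = 1e-3, max_iter = 200L) {
  x <- set_dihedral(conf, spec, target_deg)
  e <- potential$energy(x)
  if (!is.finite(e)) stop("non-finite energy at the starting geometry")
  eta <- 0.1
  converged <- FALSE
  project <- function(xc, f) {
    g <- dihedral_gradient(xc$coordinates, spec$i, spec$j, spec$k, spec$l)
    gv <- as.numeric(g)
    gv <- gv / sqrt(sum(gv^2))
    fv <- as.numeric(f) - sum(as.numeric(f) * gv) * gv
    matrix(fv, n_atoms(xc), 3)
  }
  for (it in seq_len(max_iter)) {
    f <- project(x, potential$forces(x))
    if (max(abs(f)) <= tol) { converged <- TRUE; break }
    accepted <- FALSE
    for (bt in 1:25) {
      x2 <- conformation(x$atomic_numbers, x$coordinates + eta * f, x$cell,
                         x$molecule_ids)
      x2 <- set_dihedral(x2, spec, target_deg)
      e2 <- potential$energy(x2)
      if (is.finite(e2) && e2 <= e) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break
    x <- x2; e <- e2
    eta <- min(eta * 1.2, 1.0)
  }
  attr(x, "converged") <- converged
  x
}

#' Relaxed dihedral scan with disagreement-gated halting
#'
#' Optimizes the starting geometry with the ensemble-mean potential, then
#' performs up to `cfg$n_steps` constrained minimizations at
#' `cfg$increment_deg` increments from the optimized geometry's dihedral. The
#' ensemble disagreement is measured at every scan step; the scan halts at
#' the first step with `rho > cfg$rho_threshold`.
#'
#' @param conf starting [conformation()].
#' @param ensemble a [potential_ensemble()].
#' @param spec a [torsion_spec()].
#' @param cfg a [torsion_config()].
#' @return list with `points` (per step: `conformation`, `dihedral_deg`,
#'   `rho`, `step`) and `halt_index` (`NULL` when the scan completed).
#' @export
relaxed_scan <- function(conf, ensemble, spec, cfg = torsion_config()) {
  pot <- mean_potential(ensemble)
  x <- minimize_geometry(conf, pot, cfg$opt_tolerance, cfg$opt_max_iter)
  phi0 <- dihedral_angle(x$coordinates, spec$i, spec$j, spec$k, spec$l)
  points <- vector("list", 0L)
  halt <- NULL
  for (s in seq_len(cfg$n_steps)) {
    target <- wrap_angle(phi0 + (s - 1L) * cfg$increment_deg)
    x <- constrained_minimize(x, pot, spec, target, cfg$opt_tolerance,
                              cfg$opt_max_iter)
    r <- ensemble_rho(ensemble, x)
    points[[s]] <- list(conformation = x,
                        dihedral_deg = dihedral_angle(x$coordinates, spec$i,
                                                      spec$j, spec$k, spec$l),
                        rho = r, step = s)
    if (r > cfg$rho_threshold) { halt <- s; break }
  }
  list(points = points, halt_index = halt)
}

#' Perturb a structure along its normal modes
#'
#' Generates `n` small random mode-space displacements of `x` using the same
#' bounded harmonic-energy rule as [nms_generate()] at temperature
#' `scale_K`. `x` itself is not included in the output.
#'
#' @param x the [conformation()] to perturb.
#' @param modes a [normal_modes()] computed at `x`.
#' @param n number of perturbed conformations.
#' @param scale_K temperature equivalent of the perturbation (K); 0 yields
#'   `n` copies of `x`.
#' @param seed integer seed.
#' @return list of `n` [conformation()]s.
#' @export
perturb_along_modes <- function(x, modes, n = 4L, scale_K = 50, seed = 1L) {
  modes$reference <- x
  out <- nms_generate(modes, n, scale_K, seed)
  attr(out, "skipped_modes") <- NULL
  out
}

#' One torsion-sampling iteration for a SMILES string
#'
#' Embeds the molecule in 3D through the supplied structure provider, picks a
#' rotatable torsion, optimizes, runs a disagreement-gated relaxed scan, and
#' -- if the scan halted -- returns `cfg$n_perturbed` normal-mode
#' perturbations of the halted structure (the halted structure itself is not
#' returned: the aim is to sample the space around the torsion valley, not
#' the path through it). Modes are computed from the finite-difference
#' Hessian of the ensemble-mean potential at the halted structure.
#'
#' @param smiles SMILES string handed to the embedder.
#' @param embedder structure provider: `function(smiles)` returning a list
#'   with `conformation` and `torsions` (list of [torsion_spec()]); see
#'   [fixture_embedder()].
#' @param ensemble a [potential_ensemble()].
#' @param cfg a [torsion_config()].
#' @param seed integer seed.
#' @param torsion_index which torsion to scan (random when `NULL`).
#' @return a [selection_batch()] with 0 or `cfg$n_perturbed` entries;
#'   provenance records the SMILES, torsion indices, halt step and seed.
#' @export
torsion_sampling_iteration <- function(smiles, embedder, ensemble,
                                       cfg = torsion_config(), seed = 1L,
                                       torsion_index = NULL) {
  emb <- tryCatch(embedder(smiles),
                  error = function(e) stop("embedding failed for SMILES '",
                                           smiles, "': ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (length(emb$torsions) == 0L)
    stop("no rotatable torsion for SMILES '", smiles, "'")
  set.seed(seed)
  ti <- torsion_index %||% sample.int(length(emb$torsions), 1L)
  spec <- emb$torsions[[ti]]
  scan <- relaxed_scan(emb$conformation, ensemble, spec, cfg)
  if (is.null(scan$halt_index)) return(selection_batch())
  xh <- scan$points[[scan$halt_index]]$conformation
  modes <- normal_modes_from_potential(mean_potential(ensemble), xh)
  pert <- perturb_along_modes(xh, modes, cfg$n_perturbed, cfg$perturb_scale_K,
                              seed = seed + 1L)
  entries <- lapply(seq_along(pert), function(p) {
    list(conformation = pert[[p]],
         rho = ensemble_rho(ensemble, pert[[p]]),
         provenance = list(sampler = "torsion", smiles = smiles,
                           torsion = c(spec$i, spec$j, spec$k, spec$l),
                           halt_step = scan$halt_index, seed = seed,
                           perturbation = p))
  })
  selection_batch(entries)
}
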