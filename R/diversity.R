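# Dataset statistics and diversity featurization: per-element energy
# baseline, energy/size histograms, bonded-neighbor environment labels,
# atomic environment vectors (radial + angular symmetry functions), and a
# pluggable 2-D embedding hook.

#' Covalent bond adjacency matrix
#'
#' Two atoms are bonded iff their distance is at most `factor` times the sum
#' of their covalent radii.
#'
#' @param conf a [conformation()].
#' @param factor bond-perception factor on covalent radii (default 1.3).
#' @return Na x Na logical matrix.
#' @export
bond_adjacency <- function(conf, factor = 1.3) {
  x <- conf$coordinates
  d <- cross_distances(x, x, conf$cell)
  rc <- covalent_radii(conf$atomic_numbers)
  cut <- factor * outer(rc, rc, "+")
  adj <- d <= cut
  diag(adj) <- FALSE
  adj
}

#' Bonded-neighbor environment label of an atom
#'
#' The element symbols of the atom's covalently bonded neighbors, sorted in
#' the order H < C < N < O and concatenated; e.g. the two carbons of ethanol
#' have environments `"HHHC"` and `"HHCO"`. An isolated atom gets the empty
#' label.
#'
#' @param conf a [conformation()].
#' @param atom_index 1-based atom index.
#' @param factor bond-perception factor (see [bond_adjacency()]).
#' @return character label.
#' @export
neighbor_environment_label <- function(conf, atom_index, factor = 1.3) {
  if (atom_index < 1L || atom_index > n_atoms(conf))
    stop("atom_index out of range")
  adj <- bond_adjacency(conf, factor)
  nb <- which(adj[atom_index, ])
  if (!length(nb)) return("")
  sym <- element_symbol(conf$atomic_numbers[nb])
  paste(sym[order(.element_rank[sym])], collapse = "")
}

#' Per-element linear energy baseline fit
#'
#' Ordinary least squares of total energies on per-element atom counts (one
#' coefficient per element, no global intercept unless `intercept = TRUE`).
#' The residuals are the energies with the per-element baseline removed, as
#' used for the energy-distribution histogram.
#'
#' @param energies numeric vector of total energies (Ha).
#' @param formulas list of named element-count vectors (e.g.
#'   `c(C = 2, H = 6, O = 1)`), or a numeric matrix/data.frame with one
#'   column per element.
#' @param intercept include a global intercept column (default `FALSE`).
#' @return object of class `element_fit`: `coefficients` (Ha/atom per
#'   element), `intercept`, `residuals`, `fitted`.
#' @export
linear_element_fit <- function(energies, formulas, intercept = FALSE) {
  energies <- as.numeric(energies)
  if (is.list(formulas) && !is.data.frame(formulas)) {
    elements <- unique(unlist(lapply(formulas, names)))
    X <- t(vapply(formulas, function(f) {
      v <- stats::setNames(numeric(length(elements)), elements)
      v[names(f)] <- f
      v
    }, numeric(length(elements))))
  } else {
    X <- as.matrix(formulas)
    elements <- colnames(X)
  }
  if (any(X < 0)) stop("element counts must be non-negative")
  if (nrow(X) != length(energies))
    stop("energies and formulas lengths differ")
  if (intercept) {
    X <- cbind(X, `(intercept)` = 1)
  }
  if (nrow(X) < ncol(X))
    stop("need at least as many conformers as fitted coefficients")
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: element counts do not vary enough ",
         "(e.g. all conformers share one formula)")
  fit <- stats::lm.fit(X, energies)
  coefs <- fit$coefficients
  structure(list(
    coefficients = coefs[setdiff(names(coefs), "(intercept)")],
    intercept = if (intercept) unname(coefs["(intercept)"]) else 0,
    residuals = unname(fit$residuals),
    fitted = unname(fit$fitted.values)),
    class = "element_fit")
}

#' @export
print.element_fit <- function(x, ...) {
  cat("<element_fit> coefficients (Ha/atom):\n")
  print(round(x$coefficients, 6))
  cat("residual sd:", stats::sd(x$residuals), "Ha\n")
  invisible(x)
}

#' Fixed-width histogram of energy residuals
#'
#' Right-open bins of exact width `bin_width_Ha` (default 1 millihartree)
#' aligned to multiples of the bin width; counts always sum to the number of
#' residuals.
#'
#' @param residuals numeric vector (Ha).
#' @param bin_width_Ha bin width (Ha).
#' @return list with `edges` (length nbins+1) and `counts`.
#' @export
energy_histogram <- function(residuals, bin_width_Ha = 0.001) {
  fixed_width_histogram(residuals, bin_width_Ha)
}

#' Histogram of conformer sizes
#'
#' Atom-count histogram over all conformers of all groups, bin width one.
#'
#' @param groups list of [conformer_group()]s.
#' @return list with `edges` and `counts` (bin width 1, edges at half
#'   integers).
#' @export
size_histogram <- function(groups) {
  sizes <- unlist(lapply(groups, function(g)
    rep(length(g$atomic_numbers), g$n_conformers)))
  if (is.null(sizes)) sizes <- numeric(0)
  fixed_width_histogram(sizes + 0.5, 1)  # shift so integer n falls in bin [n-0.5, n+0.5)
}

fixed_width_histogram <- function(x, bw) {
  x <- as.numeric(x)
  if (!length(x)) return(list(edges = numeric(0), counts = integer(0)))
  if (!all(is.finite(x))) stop("histogram input must be finite")
  lo <- floor(min(x) / bw)
  idx <- floor(x / bw) - lo + 1L
  nb <- max(idx)
  list(edges = (lo + 0L:nb) * bw, counts = tabulate(idx, nb))
}

#' Atomic environment descriptor configuration
#'
#' Hyperparameters of the radial/angular symmetry-function descriptor. The
#' descriptor length is
#' `n_radial * |species| + (n_ang_radial * n_ang_sections) * C(|species|+1, 2)`;
#' with the 4-species default (H, C, N, O), 16 radial shifts and 8 x 4
#' angular features per species pair this is 64 + 320 = 384.
#'
#' @param species character vector of element symbols.
#' @param n_radial number of radial Gaussian shifts (default 16).
#' @param radial_cutoff_A radial cutoff (Angstrom, default 5.2).
#' @param angular_cutoff_A angular cutoff (Angstrom, default 3.5).
#' @param n_ang_radial radial shifts of the angular block (default 8).
#' @param n_ang_sections angular sections (default 4).
#' @param eta_radial,eta_angular Gaussian widths (1/Angstrom^2).
#' @param zeta angular sharpness exponent.
#' @return list with class `descriptor_config`.
#' @export
descriptor_config <- function(species = c("H", "C", "N", "O"),
                              n_radial = 16L, radial_cutoff_A = 5.2,
                              angular_cutoff_A = 3.5, n_ang_radial = 8L,
                              n_ang_sections = 4L, eta_radial = 16,
                              eta_angular = 8, zeta = 8) {
  stopifnot(length(species) >= 1L, n_radial >= 1L, radial_cutoff_A > 0,
            angular_cutoff_A > 0)
  structure(list(species = species, n_radial = as.integer(n_radial),
                 radial_cutoff_A = radial_cutoff_A,
                 angular_cutoff_A = angular_cutoff_A,
                 n_ang_radial = as.integer(n_ang_radial),
                 n_ang_sections = as.integer(n_ang_sections),
                 eta_radial = eta_radial, eta_angular = eta_angular,
                 zeta = zeta),
            class = "descriptor_config")
}

#' Length of the atomic environment descriptor
#' @param cfg a [descriptor_config()].
#' @return integer descriptor length.
#' @export
descriptor_length <- function(cfg = descriptor_config()) {
  ns <- length(cfg$species)
  cfg$n_radial * ns +
    cfg$n_ang_radial * cfg$n_ang_sections * choose(ns + 1L, 2L)
}

.fcut <- function(r, rc) ifelse(r <= rc, 0.5 * cos(pi * r / rc) + 0.5, 0)

#' Atomic environment vector of one atom
#'
#' Rotation/translation/permutation-invariant per-atom descriptor built from
#' radial and angular symmetry functions over neighbors within the cutoffs:
#' a block of Gaussian-of-distance features per neighbor species, and a block
#' of (mean pair distance, enclosed angle) features per unordered species
#' pair. An atom with no neighbors in the cutoff gets the zero vector.
#'
#' @param conf a [conformation()].
#' @param atom_index 1-based atom index.
#' @param cfg a [descriptor_config()].
#' @return numeric vector of length [descriptor_length()].
#' @export
atomic_descriptor <- function(conf, atom_index, cfg = descriptor_config()) {
  ns <- length(cfg$species)
  out <- numeric(descriptor_length(cfg))
  x <- conf$coordinates
  sym <- element_symbol(conf$atomic_numbers)
  ci <- x[atom_index, ]
  d <- sweep(x, 2, ci)
  r <- sqrt(rowSums(d^2))
  nb <- which(r > 1e-12 & r <= cfg$radial_cutoff_A & seq_along(r) != atom_index)
  if (!length(nb)) return(out)
  # radial block: per species, n_radial Gaussian shifts with smooth cutoff
  shifts_r <- 0.9 + (0:(cfg$n_radial - 1L)) *
    (cfg$radial_cutoff_A - 0.9) / cfg$n_radial
  for (s in seq_len(ns)) {
    js <- nb[sym[nb] == cfg$species[s]]
    if (!length(js)) next
    rj <- r[js]
    fc <- .fcut(rj, cfg$radial_cutoff_A)
    block <- vapply(shifts_r, function(rs)
      sum(exp(-cfg$eta_radial * (rj - rs)^2) * fc), numeric(1))
    out[((s - 1L) * cfg$n_radial + 1L):(s * cfg$n_radial)] <- block
  }
  # angular block: per unordered species pair, n_ang_radial x n_ang_sections
  nba <- nb[r[nb] <= cfg$angular_cutoff_A]
  offset <- cfg$n_radial * ns
  n_per_pair <- cfg$n_ang_radial * cfg$n_ang_sections
  if (length(nba) >= 2L) {
    shifts_a <- 0.9 + (0:(cfg$n_ang_radial - 1L)) *
      (cfg$angular_cutoff_A - 0.9) / cfg$n_ang_radial
    theta_s <- (0:(cfg$n_ang_sections - 1L) + 0.5) * pi / cfg$n_ang_sections
    pair_index <- function(s1, s2) {   # unordered, s1 <= s2
      a <- min(s1, s2); b <- max(s1, s2)
      (a - 1L) * ns - (a - 1L) * (a - 2L) / 2 + (b - a + 1L)
    }
    combs <- utils::combn(length(nba), 2L)
    for (p in seq_len(ncol(combs))) {
      ja <- nba[combs[1, p]]; jb <- nba[combs[2, p]]
      ra <- r[ja]; rb <- r[jb]
      cosang <- sum(d[ja, ] * d[jb, ]) / (ra * rb)
      cosang <- max(-1, min(1, cosang))
      ang <- acos(cosang)
      fc2 <- .fcut(ra, cfg$angular_cutoff_A) * .fcut(rb, cfg$angular_cutoff_A)
      rmean <- (ra + rb) / 2
      s1 <- match(sym[ja], cfg$species); s2 <- match(sym[jb], cfg$species)
      pi_idx <- pair_index(s1, s2)
      base <- offset + (pi_idx - 1L) * n_per_pair
      feat <- 2^(1 - cfg$zeta) *
        outer((1 + cos(ang - theta_s))^cfg$zeta,
              exp(-cfg$eta_angular * (rmean - shifts_a)^2)) * fc2
      # layout: angular section varies slowest, radial shift fastest
      out[(base + 1L):(base + n_per_pair)] <-
        out[(base + 1L):(base + n_per_pair)] + as.numeric(t(feat))
    }
  }
  out
}

#' Descriptor matrix for all atoms of a set of conformations
#'
#' @param confs list of [conformation()]s.
#' @param cfg a [descriptor_config()].
#' @return matrix with one row per atom (conformations stacked in order).
#' @export
descriptor_matrix <- function(confs, cfg = descriptor_config()) {
  rows <- list()
  for (conf in confs) {
    for (a in seq_len(n_atoms(conf))) {
      rows[[length(rows) + 1L]] <- atomic_descriptor(conf, a, cfg)
    }
  }
  do.call(rbind, rows)
}

#' 2-D embedding of descriptor vectors
#'
#' Delegates to a pluggable embedder; the default projects onto the top two
#' principal axes (centered PCA scores). Degenerate input with zero variance
#' yields zeros with a warning.
#'
#' @param descriptors numeric matrix, one row per point.
#' @param embedder optional `function(matrix) -> N x 2 matrix`; any external
#'   2-D embedder (e.g. a t-SNE implementation) can be plugged in.
#' @return N x 2 matrix.
#' @export
embed_2d <- function(descriptors, embedder = NULL) {
  descriptors <- as.matrix(descriptors)
  if (!all(is.finite(descriptors))) stop("descriptor rows must be finite")
  if (!is.null(embedder)) {
    out <- embedder(descriptors)
    if (nrow(out) != nrow(descriptors))
      stop("embedder must preserve the number of rows")
    return(out)
  }
  centered <- sweep(descriptors, 2, colMeans(descriptors))
  if (all(abs(centered) < 1e-12)) {
    warning("zero-variance input: returning zeros")
    return(matrix(0, nrow(descriptors), 2))
  }
  sv <- svd(centered, nu = 0, nv = 2)
  if (ncol(sv$v) < 2L) {
    out <- cbind(centered %*% sv$v, 0)
  } else {
    out <- centered %*% sv$v
  }
  out
}

#' Summary statistics of a dataset file
#'
#' Per-element baseline fit of a chosen energy key plus the energy-residual
#' and size histograms.
#'
#' @param path HDF5 dataset path.
#' @param energy_key which energy to fit (default `"wb97x_dz.energy"`).
#' @param bin_width_Ha energy histogram bin width.
#' @return list with `fit`, `energy_hist`, `size_hist`, `n_conformers`.
#' @export
dataset_stats <- function(path, energy_key = "wb97x_dz.energy",
                          bin_width_Ha = 0.001) {
  groups <- read_dataset(path)
  energies <- numeric(0)
  formulas <- list()
  for (g in groups) {
    e <- g$properties[[energy_key]]
    if (is.null(e)) next
    keep <- is.finite(e)
    if (!any(keep)) next
    sym <- element_symbol(g$atomic_numbers)
    counts <- table(sym)
    f <- stats::setNames(as.numeric(counts), names(counts))
    energies <- c(energies, e[keep])
    formulas <- c(formulas, rep(list(f), sum(keep)))
  }
  fit <- linear_element_fit(energies, formulas)
  list(fit = fit,
       energy_hist = energy_histogram(fit$residuals, bin_width_Ha),
       size_hist = size_histogram(groups),
       n_conformers = length(energies))
}
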