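#' Ensemble prediction for one conformation
#'
#' @param member_energies numeric vector of per-member total energies (Ha);
#'   at least two members.
#' @param n_atoms positive integer atom count of the predicted system.
#' @return object of class `ensemble_prediction`.
#' @export
ensemble_prediction <- function(member_energies, n_atoms) {
  member_energies <- as.numeric(member_energies)
  if (length(member_energies) < 2L)
    stop("an ensemble prediction needs at least 2 members")
  if (!all(is.finite(member_energies)))
    stop("member energies must all be finite")
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 1L) stop("n_atoms must be positive")
  structure(list(member_energies = member_energies, n_atoms = n_atoms),
            class = "ensemble_prediction")
}

#' Ensemble disagreement measure rho
#'
#' The active-learning acquisition signal: the population standard deviation
#' of the ensemble's energy predictions, converted to kcal/mol and normalized
#' by the square root of the number of atoms. Units are therefore
#' kcal/mol/sqrt(atom). `rho` is zero exactly when all members agree.
#'
#' @param pred an [ensemble_prediction()], or a numeric vector of member
#'   energies in Ha (then `n_atoms` must be given).
#' @param n_atoms atom count, only used when `pred` is a bare numeric vector.
#' @return non-negative numeric disagreement.
#' @examples
#' rho(ensemble_prediction(c(-40.50, -40.52), n_atoms = 4))
#' @export
rho <- function(pred, n_atoms = NULL) {
  if (!inherits(pred, "ensemble_prediction"))
    pred <- ensemble_prediction(pred, n_atoms)
  e <- pred$member_energies * HARTREE_TO_KCALMOL
  sigma_pop <- sqrt(mean((e - mean(e))^2))
  sigma_pop / sqrt(pred$n_atoms)
}

#' Select high-disagreement structures into a batch
#'
#' Filters candidates to those with `rho` strictly above `threshold`,
#' preserving the original order.
#'
#' @param candidates list of candidate entries, each a list with elements
#'   `conformation` (a [conformation()]), `prediction` (an
#'   [ensemble_prediction()]) and optionally `provenance` (a named list,
#'   e.g. sampler name, parent id, seed).
#' @param threshold non-negative rho threshold (kcal/mol/sqrt(atom)).
#' @return a `selection_batch`: list of entries, each with `conformation`,
#'   `rho` and `provenance`. May be empty.
#' @export
select_high_rho <- function(candidates, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  entries <- list()
  for (cand in candidates) {
    r <- rho(cand$prediction)
    if (r > threshold) {
      entries[[length(entries) + 1L]] <-
        list(conformation = cand$conformation, rho = r,
             provenance = cand$provenance %||% list())
    }
  }
  selection_batch(entries)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a selection batch
#'
#' @param entries list of entries (`conformation`, `rho`, `provenance`).
#' @return object of class `selection_batch`.
#' @export
selection_batch <- function(entries = list()) {
  for (e in entries) {
    if (!is.null(e$rho) && e$rho < 0) stop("rho must be non-negative")
  }
  structure(entries, class = "selection_batch")
}

#' @export
print.selection_batch <- function(x, ...) {
  cat("<selection_batch>", length(x), "structure(s)\n")
  if (length(x))
    cat("  rho:", paste(sprintf("%.4g", vapply(x, `[[`, numeric(1), "rho")),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Combine selection batches
#' @param ... `selection_batch` objects.
#' @return a single `selection_batch`.
#' @export
c.selection_batch <- function(...) {
  selection_batch(do.call(c, lapply(list(...), unclass)))
}

# ---- potential-ensemble contract -------------------------------------------
# A "potential" is a list with $energy(conf) -> Ha and $forces(conf) ->
# Na x 3 matrix (Ha/A).  A "potential_ensemble" is a list with $members
# (list of potentials), $k, and optionally $mean (an analytic mean potential).

#' Construct a potential ensemble from member potentials
#'
#' @param members list of potentials; each a list with functions
#'   `energy(conf)` (Ha) and `forces(conf)` (Na x 3, Ha/Angstrom).
#' @param mean optional analytic mean potential; if omitted, the member
#'   average is used.
#' @return object of class `potential_ensemble`.
#' @export
potential_ensemble <- function(members, mean = NULL) {
  if (length(members) < 2L) stop("an ensemble needs at least 2 members")
  structure(list(members = members, k = length(members), mean = mean),
            class = "potential_ensemble")
}

#' Per-member energies of an ensemble for one conformation
#' @param ens a [potential_ensemble()].
#' @param conf a [conformation()].
#' @return numeric vector of length `ens$k` (Ha).
#' @export
ensemble_energies <- function(ens, conf) {
  vapply(ens$members, function(m) m$energy(conf), numeric(1))
}

#' Ensemble disagreement of a potential ensemble on a conformation
#' @inheritParams ensemble_energies
#' @return rho in kcal/mol/sqrt(atom).
#' @export
ensemble_rho <- function(ens, conf) {
  rho(ensemble_energies(ens, conf), n_atoms(conf))
}

#' Mean potential of an ensemble
#'
#' Returns a single potential whose energy/forces are the member averages
#' (or the ensemble's analytic mean if it carries one).
#'
#' @param ens a [potential_ensemble()].
#' @return a potential (list with `energy` and `forces`).
#' @export
mean_potential <- function(ens) {
  if (!is.null(ens$mean)) return(ens$mean)
  list(
    energy = function(conf) mean(ensemble_energies(ens, conf)),
    forces = function(conf) {
      fs <- lapply(ens$members, function(m) m$forces(conf))
      Reduce(`+`, fs) / length(fs)
    }
  )
}
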