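# Active-learning orchestration: the dataset-growth outer loop (train
# ensemble -> sample high-disagreement structures -> label -> retrain) and
# the disagreement-driven subset selection used to re-label a dataset at a
# higher level of theory.

#' Labeled record
#'
#' The unit stored in an active-learning dataset: a conformation, its label
#' (energy), a stable identity and provenance.
#'
#' @param id unique identifier string (identity for never-label-twice).
#' @param conformation a [conformation()].
#' @param energy label (Ha), `NA` while unlabeled.
#' @param provenance named list.
#' @return list with class `al_record`.
#' @export
al_record <- function(id, conformation, energy = NA_real_,
                      provenance = list()) {
  structure(list(id = id, conformation = conformation, energy = energy,
                 provenance = provenance), class = "al_record")
}

#' Active-learning state
#'
#' @param dataset list of labeled [al_record()]s.
#' @param iteration iteration counter.
#' @param history list of per-iteration summaries.
#' @return list with class `al_state`.
#' @export
al_state <- function(dataset = list(), iteration = 0L, history = list()) {
  if (length(history) != iteration)
    stop("history length must equal the iteration index")
  structure(list(dataset = dataset, iteration = as.integer(iteration),
                 history = history), class = "al_state")
}

#' @export
print.al_state <- function(x, ...) {
  cat("<al_state> iteration", x$iteration, "-", length(x$dataset),
      "labeled records\n")
  invisible(x)
}

.log_event <- function(log_path, event) {
  if (is.null(log_path)) return(invisible())
  cat(jsonlite::toJSON(event, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = log_path, append = TRUE)
}

#' One active-learning iteration
#'
#' Trains the ensemble on the current dataset, runs every sampler, labels
#' the union of the returned batches (skipping structures already labeled,
#' by provenance id), appends the successfully labeled structures and
#' increments the iteration. Structures the labeler fails on are dropped and
#' logged; the loop continues.
#'
#' @param state an [al_state()].
#' @param trainer list with `fit = function(records) -> potential_ensemble`.
#' @param samplers list of functions `function(ensemble, seed) ->`
#'   [selection_batch()].
#' @param labeler `function(list of conformations) -> list(energy = numeric)`
#'   with `NA` marking per-structure failure.
#' @param seed integer seed; sampler `s` receives `seed + s`.
#' @param budget optional cap on labels per iteration (highest-rho entries
#'   kept).
#' @param log_path optional JSON-lines event log.
#' @return the updated [al_state()].
#' @export
al_iteration <- function(state, trainer, samplers, labeler, seed = 1L,
                         budget = NULL, log_path = NULL) {
  ensemble <- trainer$fit(state$dataset)
  entries <- list()
  batch_sizes <- integer(length(samplers))
  for (s in seq_along(samplers)) {
    batch <- samplers[[s]](ensemble, seed + s)
    batch_sizes[s] <- length(batch)
    entries <- c(entries, unclass(batch))
  }
  known <- vapply(state$dataset, `[[`, character(1), "id")
  ids <- vapply(seq_along(entries), function(i)
    entry_id(entries[[i]], seed, i), character(1))
  keep <- !(ids %in% known) & !duplicated(ids)
  entries <- entries[keep]; ids <- ids[keep]
  if (!is.null(budget) && length(entries) > budget) {
    ord <- order(vapply(entries, `[[`, numeric(1), "rho"),
                 decreasing = TRUE)[seq_len(budget)]
    ord <- sort(ord)   # keep original order among the kept
    entries <- entries[ord]; ids <- ids[ord]
  }
  n_failed <- 0L
  new_records <- list()
  if (length(entries)) {
    labels <- labeler(lapply(entries, `[[`, "conformation"))
    for (i in seq_along(entries)) {
      if (is.na(labels$energy[i])) {
        n_failed <- n_failed + 1L
        .log_event(log_path, list(event = "label_failed", id = ids[i],
                                  iteration = state$iteration + 1L))
        next
      }
      new_records[[length(new_records) + 1L]] <-
        al_record(ids[i], entries[[i]]$conformation, labels$energy[i],
                  entries[[i]]$provenance)
    }
  }
  .log_event(log_path, list(event = "iteration", index = state$iteration + 1L,
                            seed = seed, batch_sizes = batch_sizes,
                            n_labeled = length(new_records),
                            n_failed = n_failed))
  al_state(dataset = c(state$dataset, new_records),
           iteration = state$iteration + 1L,
           history = c(state$history,
                       list(list(batch_sizes = batch_sizes, seed = seed,
                                 n_labeled = length(new_records),
                                 n_failed = n_failed))))
}

entry_id <- function(entry, seed, i) {
  pid <- entry$provenance$id %||% NULL
  if (!is.null(pid)) return(as.character(pid))
  paste0(entry$provenance$sampler %||% "batch", "-", seed, "-", i)
}

#' Disagreement-driven subset selection for high-level re-labeling
#'
#' Cycle 0 labels a uniformly random fraction `init_fraction` of the source
#' at the high level; each of the `n_cycles` subsequent cycles trains an
#' ensemble on the labeled subset, computes the disagreement rho on every
#' remaining source point, selects those with `rho > threshold` (optionally
#' capped to the `cap` highest), labels them and accumulates.
#'
#' @param source list of [al_record()]s (conformations with ids; existing
#'   energies are ignored -- the high-level labeler is the ground truth
#'   here).
#' @param trainer list with `fit` (as in [al_iteration()]).
#' @param labeler_hi high-level labeler (same contract as in
#'   [al_iteration()]).
#' @param init_fraction fraction for the initial uniform draw (0 < f < 1).
#' @param n_cycles number of disagreement-driven cycles (default 4).
#' @param threshold rho selection threshold (kcal/mol/sqrt(atom)).
#' @param cap optional per-cycle cap on selections.
#' @param seed integer seed.
#' @param log_path optional JSON-lines event log.
#' @return list with `dataset` (labeled [al_record()]s) and `audit`
#'   (per-cycle selected ids and their rho values at selection time).
#' @export
ccx_subset_selection <- function(source, trainer, labeler_hi,
                                 init_fraction = 0.05, n_cycles = 4L,
                                 threshold = 1.0, cap = NULL, seed = 1L,
                                 log_path = NULL) {
  if (length(source) == 0L) stop("source dataset is empty")
  if (init_fraction <= 0 || init_fraction >= 1)
    stop("init_fraction must be in (0, 1)")
  set.seed(seed)
  ids <- vapply(source, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("source record ids must be unique")
  n0 <- max(1L, round(init_fraction * length(source)))
  labeled_idx <- sort(sample.int(length(source), n0))
  label_records <- function(idx) {
    confs <- lapply(source[idx], `[[`, "conformation")
    labels <- labeler_hi(confs)
    recs <- list()
    for (i in seq_along(idx)) {
      if (is.na(labels$energy[i])) next
      r <- source[[idx[i]]]
      r$energy <- labels$energy[i]
      recs[[length(recs) + 1L]] <- r
    }
    recs
  }
  dataset <- label_records(labeled_idx)
  audit <- list(list(cycle = 0L, selected = ids[labeled_idx], rho = NULL))
  .log_event(log_path, list(event = "ccx_init", n = length(dataset),
                            seed = seed))
  for (cycle in seq_len(n_cycles)) {
    remaining <- setdiff(seq_along(source), labeled_idx)
    if (length(remaining) == 0L || length(dataset) == 0L) {
      audit[[length(audit) + 1L]] <- list(cycle = cycle,
                                          selected = character(0),
                                          rho = numeric(0))
      next
    }
    ensemble <- trainer$fit(dataset)
    rhos <- vapply(remaining, function(i)
      ensemble_rho(ensemble, source[[i]]$conformation), numeric(1))
    sel <- remaining[rhos > threshold]
    sel_rho <- rhos[rhos > threshold]
    if (!is.null(cap) && length(sel) > cap) {
      ord <- order(sel_rho, decreasing = TRUE)[seq_len(cap)]
      sel <- sel[ord]; sel_rho <- sel_rho[ord]
    }
    if (length(sel)) {
      dataset <- c(dataset, label_records(sel))
      labeled_idx <- c(labeled_idx, sel)
    }
    audit[[length(audit) + 1L]] <- list(cycle = cycle, selected = ids[sel],
                                        rho = sel_rho)
    .log_event(log_path, list(event = "ccx_cycle", cycle = cycle,
                              n_selected = length(sel),
                              n_total = length(dataset)))
  }
  list(dataset = dataset, audit = audit)
}

# ---- shipped trainer: bootstrap-ensemble kernel ridge regression -----------

#' Kernel-ridge ensemble trainer
#'
#' A small Gaussian-kernel ridge regressor, ensembled by training each of
#' `k` members on an independent bootstrap resample of the dataset. Adequate
#' for toy surface recovery; not a production interatomic potential.
#'
#' @param featurizer `function(conformation) -> numeric vector`.
#' @param k ensemble size (default 8).
#' @param sigma Gaussian kernel bandwidth; `NULL` for the median pairwise
#'   distance heuristic.
#' @param lambda ridge regularization (default 1e-6).
#' @param seed base seed for the bootstrap resamples.
#' @return a trainer: list with `fit(records)` and `k`.
#' @export
krr_trainer <- function(featurizer, k = 8L, sigma = NULL, lambda = 1e-6,
                        seed = 1L) {
  fit_member <- function(X, y, sg, idx) {
    Xi <- X[idx, , drop = FALSE]; yi <- y[idx]
    K <- exp(-as.matrix(stats::dist(Xi))^2 / (2 * sg^2))
    alpha <- solve(K + lambda * diag(nrow(K)), yi)
    force_step <- 1e-4
    predict_x <- function(xf) {
      d2 <- colSums((t(Xi) - xf)^2)
      sum(exp(-d2 / (2 * sg^2)) * alpha)
    }
    list(
      energy = function(conf) predict_x(featurizer(conf)),
      forces = function(conf) {
        # numerical forces in feature space are not meaningful in general;
        # provide Cartesian finite differences for 1-atom toy systems only
        x <- conf$coordinates
        f <- matrix(0, nrow(x), 3)
        for (a in seq_len(nrow(x))) for (c_ in 1:3) {
          xp <- x; xp[a, c_] <- xp[a, c_] + force_step
          xm <- x; xm[a, c_] <- xm[a, c_] - force_step
          f[a, c_] <- -(predict_x(featurizer(conformation(conf$atomic_numbers, xp))) -
                        predict_x(featurizer(conformation(conf$atomic_numbers, xm)))) /
            (2 * force_step)
        }
        f
      })
  }
  list(
    k = as.integer(k),
    fit = function(records) {
      if (length(records) < 2L)
        stop("trainer needs at least 2 labeled records")
      X <- t(vapply(records, function(r) featurizer(r$conformation),
                    featurizer(records[[1]]$conformation)))
      y <- vapply(records, `[[`, numeric(1), "energy")
      sg <- sigma %||% {
        d <- as.numeric(stats::dist(X))
        m <- stats::median(d[d > 0])
        if (!is.finite(m) || m <= 0) 1 else m
      }
      members <- withr_seed(seed + length(records), lapply(seq_len(k),
        function(m) {
          idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
          fit_member(X, y, sg, unique(idx))
        }))
      potential_ensemble(members)
    })
}

#' Labeler from a ground-truth energy function
#'
#' @param energy_fn `function(conformation) -> energy (Ha)`; may return
#'   `NA` to signal a per-structure failure.
#' @return labeler function matching the [al_iteration()] contract.
#' @export
surrogate_labeler <- function(energy_fn) {
  function(confs) list(energy = vapply(confs, energy_fn, numeric(1)))
}
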