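# Composite CCSD(T)*/CBS extrapolation.
#
# The complete-basis-set limit of the Hartree-Fock energy is estimated from
# cardinal numbers 3 and 4 (cc-pVTZ / cc-pVQZ) with an exponential form in
# sqrt(N); the correlation energy with the inverse-power form in N^beta.  The
# composite total adds the MP2/CBS correlation with the cc-pVTZ -> CBS shift,
# a NormalPNO DLPNO-CCSD(T) correlation at cc-pVTZ, and a TightPNO-minus-
# NormalPNO correction evaluated at cc-pVDZ.

#' CBS extrapolation parameters
#'
#' @param alpha exponent of the Hartree-Fock extrapolation (default 5.46,
#'   optimized for cc-pV[TQ]Z).
#' @param beta exponent of the correlation extrapolation (default 3.05,
#'   optimized for cc-pV[TQ]Z).
#' @return list with class `cbs_params`.
#' @export
cbs_params <- function(alpha = 5.46, beta = 3.05) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  structure(list(alpha = alpha, beta = beta), class = "cbs_params")
}

#' Hartree-Fock complete-basis-set extrapolation (cardinals 3/4)
#'
#' `(exp(-alpha*sqrt(4))*e3 - exp(-alpha*sqrt(3))*e4) /
#'  (exp(-alpha*sqrt(4)) - exp(-alpha*sqrt(3)))`
#'
#' @param e3,e4 HF total energies (Ha) at cardinal numbers 3 and 4.
#' @param alpha positive exponent (default 5.46).
#' @return extrapolated energy (Ha); vectorized over `e3`/`e4`.
#' @export
extrap_hf <- function(e3, e4, alpha = 5.46) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!all(is.finite(e3)) || !all(is.finite(e4)))
    stop("energies must be finite")
  w4 <- exp(-alpha * 2)
  w3 <- exp(-alpha * sqrt(3))
  (w4 * e3 - w3 * e4) / (w4 - w3)
}

#' Correlation-energy complete-basis-set extrapolation (cardinals 3/4)
#'
#' `(4^beta*e4 - 3^beta*e3) / (4^beta - 3^beta)`
#'
#' @param e3,e4 correlation energies (Ha) at cardinal numbers 3 and 4.
#' @param beta positive exponent (default 3.05).
#' @return extrapolated correlation energy (Ha); vectorized.
#' @export
extrap_corr <- function(e3, e4, beta = 3.05) {
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  if (!all(is.finite(e3)) || !all(is.finite(e4)))
    stop("energies must be finite")
  w4 <- 4^beta
  w3 <- 3^beta
  (w4 * e4 - w3 * e3) / (w4 - w3)
}

#' Component energies feeding the composite extrapolation
#'
#' Cardinal numbers 2/3/4 denote cc-pVDZ/cc-pVTZ/cc-pVQZ. The composite
#' requires HF at 3 and 4, MP2 correlation at 3 and 4, NormalPNO DLPNO-CCSD(T)
#' correlation at 2 and 3, and TightPNO DLPNO-CCSD(T) correlation at 2.
#'
#' @param hf named numeric vector of HF total energies (Ha), names are
#'   cardinal numbers, e.g. `c("3" = -76.06, "4" = -76.07)`.
#' @param mp2_corr named numeric vector of MP2 correlation energies (Ha).
#' @param ccsdt_corr_npno named numeric vector of NormalPNO DLPNO-CCSD(T)
#'   correlation energies (Ha).
#' @param ccsdt_corr_tpno named numeric vector of TightPNO DLPNO-CCSD(T)
#'   correlation energies (Ha).
#' @return object of class `energy_components`.
#' @export
energy_components <- function(hf = c(), mp2_corr = c(),
                              ccsdt_corr_npno = c(), ccsdt_corr_tpno = c()) {
  chk <- function(x, what) {
    if (length(x) == 0L) return(x)
    if (is.null(names(x)) || !all(names(x) %in% c("2", "3", "4")))
      stop(what, ": cardinal keys must be in {2, 3, 4}")
    if (!all(is.finite(x))) stop(what, ": energies must be finite")
    x
  }
  structure(list(hf = chk(hf, "hf"), mp2_corr = chk(mp2_corr, "mp2_corr"),
                 ccsdt_corr_npno = chk(ccsdt_corr_npno, "ccsdt_corr_npno"),
                 ccsdt_corr_tpno = chk(ccsdt_corr_tpno, "ccsdt_corr_tpno")),
            class = "energy_components")
}

.need <- function(comp, field, cardinal) {
  v <- comp[[field]][as.character(cardinal)]
  if (is.null(v) || is.na(v))
    stop(sprintf("missing component: %s at cardinal %d", field, cardinal))
  unname(v)
}

#' Composite CCSD(T)*/CBS total energy
#'
#' Six-term composite: HF/CBS (cardinals 3/4) plus MP2/CBS correlation
#' (cardinals 3/4) minus MP2 correlation at cardinal 3, plus NormalPNO
#' DLPNO-CCSD(T) correlation at cardinal 3, plus the TightPNO-minus-NormalPNO
#' correction at cardinal 2.
#'
#' @param comp an [energy_components()] object.
#' @param params a [cbs_params()] object.
#' @return composite total energy (Ha).
#' @export
ccsdt_star_cbs <- function(comp, params = cbs_params()) {
  hf3 <- .need(comp, "hf", 3); hf4 <- .need(comp, "hf", 4)
  mp2_3 <- .need(comp, "mp2_corr", 3); mp2_4 <- .need(comp, "mp2_corr", 4)
  npno2 <- .need(comp, "ccsdt_corr_npno", 2)
  npno3 <- .need(comp, "ccsdt_corr_npno", 3)
  tpno2 <- .need(comp, "ccsdt_corr_tpno", 2)
  extrap_hf(hf3, hf4, params$alpha) +
    extrap_corr(mp2_3, mp2_4, params$beta) - mp2_3 +
    npno3 + tpno2 - npno2
}

#' Read component-energy tables
#'
#' Parses a delimited text file with columns `id`, `method`, `cardinal`,
#' `energy_Ha` (comma- or whitespace-separated, `#` comments allowed). Method
#' tags are `hf`, `mp2_corr`, `npno_ccsdt_corr`, `tpno_ccsdt_corr`.
#'
#' @param path path to the table.
#' @return named list of [energy_components()], one per record id.
#' @export
read_components <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = ",",
                           comment.char = "#", stringsAsFactors = FALSE)
  want <- c("id", "method", "cardinal", "energy_Ha")
  if (!all(want %in% names(raw)))
    stop("component table must have columns: ", paste(want, collapse = ", "))
  tagmap <- c(hf = "hf", mp2_corr = "mp2_corr",
              npno_ccsdt_corr = "ccsdt_corr_npno",
              tpno_ccsdt_corr = "ccsdt_corr_tpno")
  out <- list()
  seen <- character()
  for (r in seq_len(nrow(raw))) {
    tag <- as.character(raw$method[r])
    if (!tag %in% names(tagmap))
      stop(sprintf("row %d: unknown method tag '%s' (valid: %s)", r, tag,
                   paste(names(tagmap), collapse = ", ")))
    e <- suppressWarnings(as.numeric(raw$energy_Ha[r]))
    if (is.na(e))
      stop(sprintf("row %d: non-numeric energy '%s'", r, raw$energy_Ha[r]))
    card <- as.character(raw$cardinal[r])
    if (!card %in% c("2", "3", "4"))
      stop(sprintf("row %d: cardinal must be 2, 3 or 4", r))
    id <- as.character(raw$id[r])
    dupkey <- paste(id, tag, card, sep = "|")
    if (dupkey %in% seen)
      stop(sprintf("row %d: duplicate (id, method, cardinal) = (%s, %s, %s)",
                   r, id, tag, card))
    seen <- c(seen, dupkey)
    if (is.null(out[[id]]))
      out[[id]] <- list(hf = c(), mp2_corr = c(), ccsdt_corr_npno = c(),
                        ccsdt_corr_tpno = c())
    out[[id]][[tagmap[[tag]]]][card] <- e
  }
  lapply(out, function(x) do.call(energy_components, x))
}

#' Batch composite extrapolation of a component table
#'
#' @param components named list of [energy_components()] (as returned by
#'   [read_components()]).
#' @param params a [cbs_params()].
#' @return data.frame with columns `id` and `ccsd(t)_cbs.energy` (Ha).
#' @export
cbs_table <- function(components, params = cbs_params()) {
  vals <- vapply(components, ccsdt_star_cbs, numeric(1), params = params)
  out <- data.frame(id = names(components), energy = unname(vals),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[2] <- "ccsd(t)_cbs.energy"
  out
}
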