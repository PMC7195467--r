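#' Property schema of the conformer-property HDF5 layout
#'
#' One row per supported property key: the HDF5 dataset name, units, storage
#' dtype and array shape. `shape` is written with the placeholders `Nc`
#' (conformers in the group) and `Na` (atoms); the on-disk (C-order, as seen
#' by NumPy/h5py) shape of e.g. forces is `(Nc, Na, 3)`.
#'
#' Quadrupoles are stored as 6 independent components in the order
#' (xx, yy, zz, xy, xz, yz).
#'
#' @return data.frame with columns `key`, `units`, `dtype`
#'   (`"f8"`, `"f4"` or `"u1"`) and `shape`.
#' @export
property_schema <- function() {
  e <- function(k) data.frame(key = k, units = "Ha", dtype = "f8",
                              shape = "(Nc)", stringsAsFactors = FALSE)
  pa <- function(k, units) data.frame(key = k, units = units, dtype = "f4",
                                      shape = "(Nc,Na)", stringsAsFactors = FALSE)
  rbind(
    data.frame(key = "coordinates", units = "A", dtype = "f4",
               shape = "(Nc,Na,3)", stringsAsFactors = FALSE),
    data.frame(key = "atomic_numbers", units = "", dtype = "u1",
               shape = "(Na)", stringsAsFactors = FALSE),
    e("wb97x_dz.energy"), e("wb97x_tz.energy"), e("ccsd(t)_cbs.energy"),
    e("hf_dz.energy"), e("hf_tz.energy"), e("hf_qz.energy"),
    e("npno_ccsd(t)_dz.corr_energy"), e("npno_ccsd(t)_tz.corr_energy"),
    e("npno_ccsd(t)_qz.corr_energy"),
    e("mp2_dz.corr_energy"), e("mp2_tz.corr_energy"), e("mp2_qz.corr_energy"),
    data.frame(key = c("wb97x_dz.forces", "wb97x_tz.forces"),
               units = "Ha/A", dtype = "f4", shape = "(Nc,Na,3)",
               stringsAsFactors = FALSE),
    data.frame(key = c("wb97x_dz.dipole", "wb97x_tz.dipole"),
               units = "e A", dtype = "f4", shape = "(Nc,3)",
               stringsAsFactors = FALSE),
    data.frame(key = "wb97x_tz.quadrupole", units = "e A^2", dtype = "f4",
               shape = "(Nc,6)", stringsAsFactors = FALSE),
    pa("wb97x_dz.cm5_charges", "e"), pa("wb97x_dz.hirshfeld_charges", "e"),
    pa("wb97x_tz.mbis_charges", "e"),
    pa("wb97x_tz.mbis_dipoles", "a.u."), pa("wb97x_tz.mbis_quadrupoles", "a.u."),
    pa("wb97x_tz.mbis_octupoles", "a.u."), pa("wb97x_tz.mbis_volumes", "a.u.")
  )
}

# expected on-disk C-order dims for a key given Nc, Na; NA entries in shape
# are free.  Returns integer vector.
schema_dims <- function(shape, nc, na) {
  switch(shape,
         "(Nc,Na,3)" = c(nc, na, 3L),
         "(Na)"      = na,
         "(Nc)"      = nc,
         "(Nc,3)"    = c(nc, 3L),
         "(Nc,6)"    = c(nc, 6L),
         "(Nc,Na)"   = c(nc, na),
         stop("unknown shape spec ", shape))
}

schema_h5type <- function(dtype) {
  switch(dtype,
         f8 = "H5T_IEEE_F64LE",
         f4 = "H5T_IEEE_F32LE",
         u1 = "H5T_STD_U8LE",
         stop("unknown dtype ", dtype))
}

#' Construct a conformer group
#'
#' All conformers of one stoichiometry/isomer, with per-conformer property
#' arrays keyed by the names in [property_schema()]. Property arrays carry
#' their conformer index in the leading dimension; `NaN` marks a property
#' value missing for an individual conformer.
#'
#' @param group_key unique string identifying the isomer
#'   (e.g. `"C2H6O_00001"`).
#' @param atomic_numbers integer vector of atomic numbers (length Na, shared
#'   by every conformer).
#' @param properties named list of arrays; must contain `coordinates`
#'   (Nc x Na x 3). Shapes must match [property_schema()].
#' @return object of class `conformer_group` with fields `group_key`,
#'   `atomic_numbers`, `properties`, `n_conformers`.
#' @export
conformer_group <- function(group_key, atomic_numbers, properties) {
  stopifnot(is.character(group_key), length(group_key) == 1L)
  atomic_numbers <- as.integer(atomic_numbers)
  if (!"coordinates" %in% names(properties))
    stop("properties must contain 'coordinates'")
  schema <- property_schema()
  na <- length(atomic_numbers)
  nc <- dim(as.array(properties[["coordinates"]]))[1]
  for (key in names(properties)) {
    row <- schema[schema$key == key, ]
    if (nrow(row) == 0L)
      stop(sprintf("unknown property key '%s'; valid keys: %s", key,
                   paste(schema$key, collapse = ", ")))
    arr <- as.array(properties[[key]])
    want <- schema_dims(row$shape, nc, na)
    have <- dim(arr)
    if (length(have) != length(want) || !all(have == want))
      stop(sprintf("property '%s' has shape (%s), expected (%s)", key,
                   paste(have, collapse = ","), paste(want, collapse = ",")))
    storage.mode(arr) <- "double"
    properties[[key]] <- arr
  }
  structure(list(group_key = group_key, atomic_numbers = atomic_numbers,
                 properties = properties, n_conformers = as.integer(nc)),
            class = "conformer_group")
}

#' @export
print.conformer_group <- function(x, ...) {
  cat(sprintf("<conformer_group> %s: %d conformers, %d atoms, %d properties\n",
              x$group_key, x$n_conformers, length(x$atomic_numbers),
              length(x$properties)))
  invisible(x)
}

#' Stoichiometry-based group key
#'
#' Builds a `"C2H6O_00001"`-style group key from atomic numbers and an index.
#'
#' @param atomic_numbers integer vector of atomic numbers.
#' @param index integer isomer index.
#' @return character key.
#' @export
make_group_key <- function(atomic_numbers, index = 1L) {
  sym <- element_symbol(atomic_numbers)
  counts <- table(factor(sym, levels = c("C", "H", "N", "O")))
  counts <- counts[counts > 0]
  stoich <- paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
  sprintf("%s_%05d", stoich, as.integer(index))
}
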