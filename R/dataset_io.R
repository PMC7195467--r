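# HDF5 dataset layer: one HDF5 group per isomer, one dataset per property,
# dataset names exactly the property_schema() key strings.  Arrays are written
# transposed so that the on-disk (C-order) shapes match the documented
# (Nc, Na, 3)-style layout as seen from NumPy/h5py.

# store an R array so its C-order on-disk shape equals dim(arr)
h5_write_c_order <- function(file, name, arr, h5type) {
  arr <- as.array(arr)
  d <- dim(arr)
  if (length(d) > 1L) arr <- aperm(arr, rev(seq_along(d)))
  rhdf5::h5createDataset(file, name, dims = dim(as.array(arr)),
                         H5type = h5type)
  rhdf5::h5write(arr, file, name)
}

h5_read_c_order <- function(file, name) {
  arr <- rhdf5::h5read(file, name)
  if (is.raw(arr)) {
    arr <- array(as.integer(arr), dim = dim(as.array(arr)))
  }
  arr <- as.array(arr)
  d <- dim(arr)
  if (length(d) > 1L) arr <- aperm(arr, rev(seq_along(d)))
  arr
}

#' Write conformer groups to an HDF5 dataset file
#'
#' Writes one HDF5 group per [conformer_group()], one dataset per property,
#' using the exact key strings and dtypes of [property_schema()] (energies in
#' double precision, geometric and per-atom properties in single precision,
#' atomic numbers as unsigned 8-bit). Content round-trips bitwise through
#' [read_dataset()] for values representable in the stored dtype.
#'
#' @param groups a [conformer_group()] or list of them; `group_key`s must be
#'   unique.
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(groups, path) {
  if (inherits(groups, "conformer_group")) groups <- list(groups)
  keys <- vapply(groups, function(g) g$group_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate group_key: ", paste(unique(keys[duplicated(keys)]),
                                        collapse = ", "))
  # re-run constructor validation so schema errors name group and key
  for (g in groups) {
    tryCatch(conformer_group(g$group_key, g$atomic_numbers, g$properties),
             error = function(e) stop(sprintf("group '%s': %s", g$group_key,
                                              conditionMessage(e)),
                                      call. = FALSE))
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  schema <- property_schema()
  for (g in groups) {
    rhdf5::h5createGroup(path, g$group_key)
    h5_write_c_order(path, paste0(g$group_key, "/atomic_numbers"),
                     g$atomic_numbers, "H5T_STD_U8LE")
    for (key in names(g$properties)) {
      row <- schema[schema$key == key, ]
      h5_write_c_order(path, paste0(g$group_key, "/", key),
                       g$properties[[key]], schema_h5type(row$dtype))
    }
  }
  invisible(path)
}

#' Read an HDF5 dataset file into conformer groups
#'
#' @param path path to a file in the layout written by [write_dataset()].
#' @return named list of [conformer_group()] objects.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll())
  ls <- rhdf5::h5ls(path)
  gnames <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  out <- list()
  for (gk in gnames) {
    dsets <- ls$name[ls$group == paste0("/", gk)]
    z <- as.integer(h5_read_c_order(path, paste0(gk, "/atomic_numbers")))
    props <- list()
    for (key in setdiff(dsets, "atomic_numbers")) {
      props[[key]] <- h5_read_c_order(path, paste0(gk, "/", key))
    }
    out[[gk]] <- conformer_group(gk, z, props)
  }
  out
}

#' Validate an HDF5 dataset file against the property schema
#'
#' Checks every group and dataset in the file against [property_schema()]:
#' known keys only, exact dtypes, and exact array shapes (using `Na` from the
#' group's `atomic_numbers` and `Nc` from its `coordinates`).
#'
#' @param path path to an HDF5 file.
#' @return object of class `schema_report`: list with `valid` (logical) and
#'   `violations` (data.frame with columns `group_key`, `property_key`,
#'   `message`).
#' @export
validate_schema <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll())
  ls <- tryCatch(rhdf5::h5ls(path, all = TRUE),
                 error = function(e) stop("unreadable HDF5 file: ", path,
                                          " (", conditionMessage(e), ")",
                                          call. = FALSE))
  schema <- property_schema()
  viol <- list()
  add <- function(gk, key, msg)
    viol[[length(viol) + 1L]] <<- data.frame(group_key = gk,
                                             property_key = key,
                                             message = msg,
                                             stringsAsFactors = FALSE)
  root_dsets <- ls$name[ls$group == "/" & ls$otype == "H5I_DATASET"]
  for (nm in root_dsets) add("/", nm, "dataset outside any isomer group")
  gnames <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  parse_dims <- function(s) rev(as.integer(strsplit(s, " x ", fixed = TRUE)[[1]]))
  for (gk in gnames) {
    sub <- ls[ls$group == paste0("/", gk) & ls$otype == "H5I_DATASET", ]
    na <- NA_integer_; nc <- NA_integer_
    if (!"atomic_numbers" %in% sub$name) {
      add(gk, "atomic_numbers", "missing required dataset")
    } else {
      na <- parse_dims(sub$dim[sub$name == "atomic_numbers"])[1]
    }
    if ("coordinates" %in% sub$name) {
      cd <- parse_dims(sub$dim[sub$name == "coordinates"])
      if (length(cd) == 3L) nc <- cd[1]
    }
    for (r in seq_len(nrow(sub))) {
      key <- sub$name[r]
      row <- schema[schema$key == key, ]
      if (nrow(row) == 0L) {
        add(gk, key, "unknown property key")
        next
      }
      want_type <- schema_h5type(row$dtype)
      if (!identical(sub$dtype[r], want_type))
        add(gk, key, sprintf("dtype %s, expected %s", sub$dtype[r], want_type))
      have <- parse_dims(sub$dim[r])
      if (is.na(na) || (is.na(nc) && grepl("Nc", row$shape))) next
      want <- schema_dims(row$shape, nc, na)
      if (length(have) != length(want) || !all(have == want))
        add(gk, key, sprintf("shape (%s), expected (%s)",
                             paste(have, collapse = ","),
                             paste(want, collapse = ",")))
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(group_key = character(), property_key = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(list(valid = nrow(violations) == 0L, violations = violations),
            class = "schema_report")
}

#' @export
print.schema_report <- function(x, ...) {
  if (x$valid) {
    cat("schema: valid\n")
  } else {
    cat("schema: INVALID,", nrow(x$violations), "violation(s)\n")
    for (r in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s: %s\n", x$violations$group_key[r],
                  x$violations$property_key[r], x$violations$message[r]))
  }
  invisible(x)
}

#' Iterate a dataset file with key filtering
#'
#' For each isomer group, returns only the conformers for which every
#' requested property key is present and non-`NaN` (`NaN` is the missing-value
#' marker). `coordinates` and `atomic_numbers` are always included. Conformer
#' order is preserved; groups left with no conformer are skipped.
#'
#' @param path path to an HDF5 dataset file.
#' @param keys character vector of property keys to require (may be empty, in
#'   which case every conformer in the file is returned).
#' @return named list of buckets; each bucket is a list with
#'   `atomic_numbers`, `coordinates`, and one filtered array per requested
#'   key.
#' @export
iter_data_buckets <- function(path, keys = character()) {
  schema <- property_schema()
  bad <- setdiff(keys, setdiff(schema$key, c("coordinates", "atomic_numbers")))
  if (length(bad))
    stop(sprintf("unknown property key(s): %s\nvalid keys: %s",
                 paste(bad, collapse = ", "),
                 paste(setdiff(schema$key, c("coordinates", "atomic_numbers")),
                       collapse = ", ")))
  groups <- read_dataset(path)
  out <- list()
  for (g in groups) {
    if (!all(keys %in% names(g$properties))) next
    keep <- rep(TRUE, g$n_conformers)
    for (key in keys) {
      arr <- g$properties[[key]]
      ok <- if (length(dim(arr)) == 1L) is.finite(arr) else
        apply(arr, 1L, function(sl) all(is.finite(sl)))
      keep <- keep & ok
    }
    if (!any(keep)) next
    take <- function(arr) {
      d <- dim(arr)
      if (length(d) == 1L) as.vector(arr)[keep]
      else if (length(d) == 2L) arr[keep, , drop = FALSE]
      else arr[keep, , , drop = FALSE]
    }
    bucket <- list(atomic_numbers = g$atomic_numbers,
                   coordinates = take(g$properties[["coordinates"]]))
    for (key in keys) bucket[[key]] <- take(g$properties[[key]])
    out[[g$group_key]] <- bucket
  }
  out
}
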