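#' Read conformations from an XYZ file
#'
#' Parses the plain multi-frame XYZ dialect: an atom-count line, a comment
#' line, then one `symbol x y z` line per atom. Element symbols or bare atomic
#' numbers are accepted.
#'
#' @param path path to an XYZ file.
#' @return list of [conformation()] objects, one per frame.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  confs <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln]))) { ln <- ln + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(na) || na <= 0L)
      stop(sprintf("xyz parse error at line %d: expected an atom count, got '%s'",
                   ln, lines[ln]))
    if (ln + 1L + na > length(lines))
      stop(sprintf("xyz parse error at line %d: %d atoms declared but file ends early",
                   ln, na))
    atoms <- lines[(ln + 2L):(ln + 1L + na)]
    z <- integer(na); xyz <- matrix(0, na, 3)
    for (a in seq_len(na)) {
      tok <- strsplit(trimws(atoms[a]), "\\s+")[[1]]
      if (length(tok) < 4L)
        stop(sprintf("xyz parse error at line %d: expected 'symbol x y z'",
                     ln + 1L + a))
      zi <- suppressWarnings(as.integer(tok[1]))
      z[a] <- if (!is.na(zi)) zi else element_number(tok[1])
      co <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(co))
        stop(sprintf("xyz parse error at line %d: non-numeric coordinate",
                     ln + 1L + a))
      xyz[a, ] <- co
    }
    confs[[length(confs) + 1L]] <- conformation(z, xyz)
    ln <- ln + 2L + na
  }
  confs
}

#' Write conformations to an XYZ file
#'
#' @param confs a [conformation()] or list of them.
#' @param path output path.
#' @param comments optional character vector of per-frame comment lines.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(confs, path, comments = NULL) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(confs)) {
    conf <- confs[[f]]
    cmt <- if (!is.null(comments)) comments[[f]] else ""
    writeLines(c(as.character(n_atoms(conf)), cmt), con)
    sym <- element_symbol(conf$atomic_numbers)
    writeLines(sprintf("%-2s %16.8f %16.8f %16.8f", sym,
                       conf$coordinates[, 1], conf$coordinates[, 2],
                       conf$coordinates[, 3]), con)
  }
  invisible(path)
}
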