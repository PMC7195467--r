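# Physical constants and element data. Internal.
# Unit system used throughout: energy Ha, length Angstrom, time fs, mass amu.

HARTREE_TO_KCALMOL <- 627.5094740631
KB_HA_PER_K <- 3.166811563e-6  # Boltzmann constant, Ha/K

# 1 amu * A^2 / fs^2 expressed in Hartree (CODATA masses/energies)
AMU_A2_FS2_PER_HA <- 1.66053906660e-17 / 4.3597447222071e-18

.element_table <- data.frame(
  z      = c(1L, 6L, 7L, 8L),
  symbol = c("H", "C", "N", "O"),
  mass   = c(1.008, 12.011, 14.007, 15.999),   # amu
  rcov   = c(0.31, 0.76, 0.71, 0.66),          # covalent radius, Angstrom
  stringsAsFactors = FALSE
)

# canonical element ordering for environment labels: H < C < N < O
.element_rank <- c(H = 1L, C = 2L, N = 3L, O = 4L)

element_symbol <- function(z) {
  idx <- match(z, .element_table$z)
  if (anyNA(idx)) {
    stop("unsupported atomic number(s): ",
         paste(unique(z[is.na(idx)]), collapse = ", "),
         " (supported: H, C, N, O)")
  }
  .element_table$symbol[idx]
}

element_number <- function(symbol) {
  idx <- match(symbol, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unsupported element symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  }
  .element_table$z[idx]
}

atomic_masses <- function(z) .element_table$mass[match(z, .element_table$z)]

covalent_radii <- function(z) .element_table$rcov[match(z, .element_table$z)]
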