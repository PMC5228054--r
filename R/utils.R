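# Internal helpers: seeded evaluation, element tables, unit conversion.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing randomness in the package flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a secondary 31-bit seed from a master seed and a stream index,
# so per-epoch shuffles are reproducible but distinct.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807 + 1) %% 2147483647)
}

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

#' Convert element symbols to nuclear charges
#'
#' @param symbols Character vector of element symbols (e.g. `"C"`, `"Cl"`).
#' @return Integer vector of nuclear charges.
#' @examples
#' symbol_to_z(c("H", "C", "O"))
#' @export
symbol_to_z <- function(symbols) {
  z <- match(symbols, .ELEMENTS)
  if (anyNA(z)) {
    bad <- unique(symbols[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  as.integer(z)
}

#' Convert nuclear charges to element symbols
#'
#' @param z Integer vector of nuclear charges (1-based).
#' @return Character vector of element symbols.
#' @export
z_to_symbol <- function(z) {
  if (any(z < 1 | z > length(.ELEMENTS))) {
    stop("nuclear charge outside supported range 1..", length(.ELEMENTS), call. = FALSE)
  }
  .ELEMENTS[z]
}

# kcal/mol per Hartree and per eV; Boltzmann constant in kcal/mol/K.
HARTREE_TO_KCALMOL <- 627.509
EV_TO_KCALMOL <- 23.0609
KBOLTZ_KCALMOL_K <- 1.987204e-3
BOHR_PER_ANGSTROM <- 1 / 0.52917721067

#' Convert an energy to kcal/mol
#'
#' The package works in kcal/mol internally; labels in other units are
#' converted once at ingest.
#'
#' @param x Numeric energies.
#' @param from Source unit: `"kcal/mol"`, `"hartree"` or `"ev"`.
#' @return Energies in kcal/mol.
#' @examples
#' to_kcalmol(1, "hartree")  # 627.509
#' @export
to_kcalmol <- function(x, from = c("kcal/mol", "hartree", "ev")) {
  from <- match.arg(tolower(from), c("kcal/mol", "hartree", "ev"))
  switch(from,
    "kcal/mol" = x,
    "hartree" = x * HARTREE_TO_KCALMOL,
    "ev" = x * EV_TO_KCALMOL
  )
}
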