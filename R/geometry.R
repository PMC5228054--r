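# Molecular geometry container, distance computation and extended-XYZ I/O.

#' Construct a molecular geometry
#'
#' The network's sole input: nuclear charges plus Cartesian coordinates,
#' optionally carrying a scalar energy label in kcal/mol.
#'
#' @param Z Integer nuclear charges (all >= 1) or character element symbols.
#' @param R Numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param energy Optional scalar energy label (kcal/mol).
#' @param id Optional identifier string.
#' @return An object of class `"molecule"`.
#' @examples
#' h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
#' @export
molecule <- function(Z, R, energy = NULL, id = NULL) {
  if (is.character(Z)) Z <- symbol_to_z(Z)
  Z <- as.integer(Z)
  R <- matrix(as.numeric(R), ncol = 3)
  if (length(Z) < 1) stop("a molecule needs at least one atom", call. = FALSE)
  if (nrow(R) != length(Z)) {
    stop("length(Z) == ", length(Z), " but R has ", nrow(R), " rows", call. = FALSE)
  }
  if (any(Z < 1)) stop("nuclear charges must be >= 1", call. = FALSE)
  if (!all(is.finite(R))) stop("coordinates must be finite", call. = FALSE)
  if (!is.null(energy)) {
    energy <- as.numeric(energy)
    stopifnot(length(energy) == 1L, is.finite(energy))
  }
  structure(list(Z = Z, R = R, energy = energy, id = id), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule%s: %d atoms [%s]%s>\n",
    if (is.null(x$id)) "" else paste0(" ", x$id),
    length(x$Z),
    paste(z_to_symbol(sort(unique(x$Z))), collapse = ","),
    if (is.null(x$energy)) "" else sprintf(", E = %.4f kcal/mol", x$energy)
  ))
  invisible(x)
}

#' Construct a molecular dataset
#'
#' An ordered collection of molecules with optional train/validation/test
#' split labels and a declared energy unit (converted to kcal/mol at
#' construction).
#'
#' @param molecules List of [molecule()] objects.
#' @param split Optional character vector (`"train"`, `"val"`, `"test"`),
#'   one per molecule.
#' @param unit Unit the incoming energy labels are expressed in; labels are
#'   converted to kcal/mol.
#' @return An object of class `"mol_dataset"`.
#' @export
mol_dataset <- function(molecules, split = NULL, unit = "kcal/mol") {
  stopifnot(is.list(molecules))
  if (!all(vapply(molecules, inherits, logical(1), "molecule"))) {
    stop("all elements must be molecule objects", call. = FALSE)
  }
  if (unit != "kcal/mol") {
    molecules <- lapply(molecules, function(m) {
      if (!is.null(m$energy)) m$energy <- to_kcalmol(m$energy, unit)
      m
    })
  }
  if (!is.null(split)) {
    split <- as.character(split)
    stopifnot(length(split) == length(molecules))
    bad <- setdiff(unique(split), c("train", "val", "test"))
    if (length(bad)) stop("invalid split labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(molecules = molecules, split = split, unit = "kcal/mol"),
            class = "mol_dataset")
}

#' @export
length.mol_dataset <- function(x) length(x$molecules)

#' @export
`[.mol_dataset` <- function(x, i) {
  mol_dataset(x$molecules[i], split = if (is.null(x$split)) NULL else x$split[i])
}

#' @export
print.mol_dataset <- function(x, ...) {
  cat(sprintf("<mol_dataset: %d molecules", length(x)))
  if (!is.null(x$split)) {
    tab <- table(factor(x$split, levels = c("train", "val", "test")))
    cat(sprintf(" (train %d / val %d / test %d)", tab[1], tab[2], tab[3]))
  }
  cat(">\n")
  invisible(x)
}

#' Extract energy labels from a dataset
#'
#' @param dataset A [mol_dataset()].
#' @return Numeric vector (kcal/mol), `NA` where a molecule is unlabelled.
#' @export
dataset_energies <- function(dataset) {
  vapply(dataset$molecules, function(m) if (is.null(m$energy)) NA_real_ else m$energy,
         numeric(1))
}

#' Subset a dataset by split label
#'
#' @param dataset A [mol_dataset()] with split labels.
#' @param which One of `"train"`, `"val"`, `"test"`.
#' @return A [mol_dataset()] holding the requested split.
#' @export
dataset_split <- function(dataset, which = c("train", "val", "test")) {
  which <- match.arg(which)
  if (is.null(dataset$split)) stop("dataset carries no split labels", call. = FALSE)
  dataset[dataset$split == which]
}

#' Interatomic distance matrix
#'
#' Euclidean distances between all atom pairs. Depending only on
#' distances makes every downstream feature invariant under rotation,
#' translation and reflection of the molecule.
#'
#' @param mol A [molecule()].
#' @return Symmetric N x N matrix of distances in Angstrom (zero diagonal).
#' @examples
#' m <- molecule(c(1, 1), rbind(c(0, 0, 0), c(0, 0, 1.5)))
#' distance_matrix(m)
#' @export
distance_matrix <- function(mol) {
  D <- as.matrix(stats::dist(mol$R))
  dimnames(D) <- NULL
  diag(D) <- 0
  D
}

#' Assign random train/validation/test splits
#'
#' Seeded uniform random assignment; the same seed always produces the
#' same assignment. Split sizes are within one molecule of
#' `fraction * n`.
#'
#' @param dataset A [mol_dataset()].
#' @param fractions Length-3 numeric (train, val, test); positive, summing
#'   to 1 within 1e-9.
#' @param seed Integer seed.
#' @return The dataset with split labels attached.
#' @export
split_dataset <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 0) {
  stopifnot(length(fractions) == 3)
  if (any(fractions <= 0)) stop("split fractions must be positive", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1 (got ", sum(fractions), ")", call. = FALSE)
  }
  n <- length(dataset)
  if (n < 3) stop("need at least 3 molecules to form 3 splits (got ", n, ")", call. = FALSE)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_train <- max(1L, min(n_train, n - 2L))
  n_val <- max(1L, min(n_val, n - n_train - 1L))
  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[(n_train + n_val + 1):n]] <- "test"
  dataset$split <- split
  dataset
}

#' Read an extended-XYZ file
#'
#' Parses concatenated XYZ records (atom-count line, comment line, atom
#' lines). The plain dialect reads an optional `energy=<value>` token from
#' the comment line. The GDB-9 dialect treats the comment line as a
#' whitespace/tab-separated property list and maps a configured column to
#' the energy label, converting from its declared unit to kcal/mol.
#'
#' @param path Path to the XYZ file.
#' @param dialect `"plain"` or `"gdb9"`.
#' @param energy_column For the gdb9 dialect: 1-based index of the property
#'   field holding the target energy.
#' @param energy_unit Unit of the parsed energy (`"kcal/mol"`, `"hartree"`,
#'   `"ev"`).
#' @return A [mol_dataset()].
#' @export
read_xyz <- function(path, dialect = c("plain", "gdb9"),
                     energy_column = 2L, energy_unit = "hartree") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  molecules <- list()
  pos <- 1L
  rec <- 0L
  while (pos <= length(lines)) {
    rec <- rec + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1) {
      stop("record ", rec, ": expected an atom count at line ", pos, call. = FALSE)
    }
    if (pos + 1L + n > length(lines)) {
      stop("record ", rec, ": count line says ", n, " atoms but the file ends early",
           call. = FALSE)
    }
    comment <- lines[pos + 1L]
    atom_lines <- lines[pos + 1L + seq_len(n)]
    fields <- strsplit(trimws(atom_lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 4)) {
      stop("record ", rec, ": atom line with fewer than 4 fields", call. = FALSE)
    }
    sym <- vapply(fields, `[`, character(1), 1L)
    coords <- vapply(fields, function(f) {
      v <- suppressWarnings(as.numeric(gsub("\\*\\^", "e", f[2:4])))
      if (anyNA(v)) stop("record ", rec, ": non-numeric coordinate", call. = FALSE)
      v
    }, numeric(3))
    Z <- if (all(grepl("^[0-9]+$", sym))) as.integer(sym) else symbol_to_z(sym)
    energy <- NULL
    id <- NULL
    if (dialect == "plain") {
      m <- regmatches(comment, regexec("energy=([-+0-9.eE]+)", comment))[[1]]
      if (length(m) == 2) energy <- as.numeric(m[2])
      m <- regmatches(comment, regexec("id=([^ \t]+)", comment))[[1]]
      if (length(m) == 2) id <- m[2]
    } else {
      props <- strsplit(trimws(comment), "[ \t]+")[[1]]
      if (length(props) >= energy_column) {
        val <- suppressWarnings(as.numeric(gsub("\\*\\^", "e", props[energy_column])))
        if (!is.na(val)) energy <- to_kcalmol(val, energy_unit)
        if (length(props) >= 2 && is.na(suppressWarnings(as.numeric(props[1])))) {
          id <- paste(props[1:2], collapse = "_")
        }
      }
    }
    mol <- tryCatch(
      molecule(Z, t(coords), energy = energy, id = id),
      error = function(e) stop("record ", rec, ": ", conditionMessage(e), call. = FALSE)
    )
    molecules[[rec]] <- mol
    pos <- pos + 2L + n
    # skip blank separator lines between records
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  mol_dataset(molecules)
}

#' Write a dataset as extended XYZ
#'
#' Plain dialect: energies (kcal/mol) appear as `energy=<value>` in the
#' comment line, coordinates with 6 decimals.
#'
#' @param dataset A [mol_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(dataset, path) {
  out <- character(0)
  for (mol in dataset$molecules) {
    comment <- character(0)
    if (!is.null(mol$id)) comment <- c(comment, paste0("id=", mol$id))
    if (!is.null(mol$energy)) {
      comment <- c(comment, sprintf("energy=%.17g", mol$energy))
    }
    out <- c(
      out,
      as.character(length(mol$Z)),
      paste(comment, collapse = " "),
      sprintf("%-2s %12.6f %12.6f %12.6f",
              z_to_symbol(mol$Z), mol$R[, 1], mol$R[, 2], mol$R[, 3])
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Count molecules matching a chemical formula
#'
#' Utility for stoichiometry queries over a dataset, e.g. counting the
#' constitutional isomers of C7O2H10 present in an XYZ deposit.
#'
#' @param dataset A [mol_dataset()].
#' @param formula Hill-style formula string, e.g. `"C7O2H10"` (element
#'   order irrelevant; counts of 1 may be omitted).
#' @return Integer count of molecules with exactly that composition.
#' @export
count_formula <- function(dataset, formula) {
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  toks <- toks[nzchar(toks)]
  want <- integer(0)
  for (t in toks) {
    sym <- gsub("[0-9]", "", t)
    cnt <- gsub("[^0-9]", "", t)
    want[[sym]] <- if (nzchar(cnt)) as.integer(cnt) else 1L
  }
  want_z <- stats::setNames(as.integer(want), symbol_to_z(names(want)))
  want_z <- want_z[order(as.integer(names(want_z)))]
  sum(vapply(dataset$molecules, function(mol) {
    tab <- table(mol$Z)
    if (length(tab) != length(want_z)) return(FALSE)
    identical(as.integer(names(tab)), as.integer(names(want_z))) &&
      all(as.integer(tab) == want_z)
  }, logical(1)))
}
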