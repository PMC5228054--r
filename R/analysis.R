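# Interpretation instruments: local chemical potential grids from a probe
# atom, Gaussian cube export, an inverse-square isosurface field, and
# substructure stability scoring from the atomic energy partition.

#' Local chemical potential on a regular 3-D grid
#'
#' Evaluates the probe-atom energy Omega_M^A(r) of species `probe_Z` on a
#' regular grid around the molecule. The molecule's coefficient vectors
#' are computed once and reused for every grid point; the coupling is
#' one-way, so the molecule's own energies are untouched.
#'
#' @param mol A [molecule()].
#' @param probe_Z Nuclear charge of the probe species.
#' @param params A [dtnn_init()] parameter set (trained).
#' @param scaler An [energy_scaler()].
#' @param origin Length-3 grid origin (Angstrom).
#' @param spacing Grid spacing, scalar or length-3 (Angstrom).
#' @param shape Length-3 integer voxel counts (all >= 1).
#' @return An object of class `"probe_result"`: `probe_Z`, `origin`,
#'   `spacing`, `shape`, `values` (3-D array, kcal/mol) and `molecule`.
#' @export
chemical_potential_grid <- function(mol, probe_Z, params, scaler,
                                    origin = c(0, 0, 0), spacing = 0.5,
                                    shape = c(8L, 8L, 8L)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) {
    stop("grid shape must be three positive voxel counts", call. = FALSE)
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(origin) == 3, length(spacing) == 3, all(spacing > 0))
  history <- coeff_history(mol, params)
  probe_Z <- as.integer(probe_Z)
  if (!probe_Z %in% params$species) {
    stop("probe nuclear charge not in the embedding table: ", probe_Z, call. = FALSE)
  }
  # all grid points, x fastest (array order), evaluated as one probe batch
  pts <- as.matrix(expand.grid(
    x = origin[1] + (seq_len(shape[1]) - 1L) * spacing[1],
    y = origin[2] + (seq_len(shape[2]) - 1L) * spacing[2],
    z = origin[3] + (seq_len(shape[3]) - 1L) * spacing[3]
  ))
  n_pts <- nrow(pts)
  N <- length(mol$Z)
  # pair (point, atom) distances
  d2 <- outer(rowSums(pts^2), rowSums(mol$R^2), "+") - 2 * pts %*% t(mol$R)
  d <- sqrt(pmax(d2, 0))                               # n_pts x N
  pair_pt <- rep(seq_len(n_pts), times = N)
  pair_at <- rep(seq_len(N), each = n_pts)
  keep <- if (is.null(params$cutoff)) rep(TRUE, length(pair_pt)) else
    as.vector(d) <= params$cutoff
  pair_pt <- pair_pt[keep]; pair_at <- pair_at[keep]
  Dhat <- expand_cols(as.vector(d)[keep], params$grid)
  Sp <- Matrix::sparseMatrix(i = seq_along(pair_pt), j = pair_pt, x = 1,
                             dims = c(length(pair_pt), n_pts))
  Pc <- matrix(params$emb[, as.character(probe_Z)], params$B, n_pts)
  for (t in seq_len(params$n_passes)) {
    if (length(pair_pt)) {
      w <- inter_block(params, t)
      Cmol <- t(history[[t]])[, pair_at, drop = FALSE]
      f <- (w$W_cf %*% Cmol + w$b_f1) * (w$W_df %*% Dhat + w$b_f2)
      V <- act_fun(w$W_fc %*% f, params$activation)
      Pc <- Pc + as.matrix(V %*% Sp)
    }
  }
  O <- act_fun(params$head$W1 %*% Pc + params$head$b1, params$activation)
  omega <- scaler$E_sigma * (as.vector(params$head$W2 %*% O) + params$head$b2) +
    scaler$E_mu
  structure(
    list(probe_Z = probe_Z, origin = origin, spacing = spacing, shape = shape,
         values = array(omega, dim = shape), molecule = mol),
    class = "probe_result"
  )
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf(
    "<probe_result: %s probe on %dx%dx%d grid, Omega in [%.3f, %.3f] kcal/mol>\n",
    z_to_symbol(x$probe_Z), x$shape[1], x$shape[2], x$shape[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Inverse-square atom-sum field
#'
#' The scalar field `g(r) = sum_i 1 / ||r - r_i||^2` (units 1/Angstrom^2)
#' whose isosurfaces wrap the molecule at a roughly constant effective
#' distance; the level 3.8 1/A^2 is the conventional default for plotting
#' local chemical potentials on a molecular surface.
#'
#' @param mol A [molecule()].
#' @param r Length-3 position (Angstrom), not coincident with any atom.
#' @return Strictly positive scalar (1/Angstrom^2).
#' @examples
#' m <- molecule(1, matrix(c(0, 0, 0), 1))
#' isosurface_field(m, c(1, 0, 0))  # 1.0
#' @export
isosurface_field <- function(mol, r) {
  stopifnot(length(r) == 3, all(is.finite(r)))
  d2 <- colSums((t(mol$R) - r)^2)
  if (any(d2 < 1e-12)) {
    stop("position coincides with an atom (within 1e-6 A)", call. = FALSE)
  }
  sum(1 / d2)
}

#' Export a volumetric grid as a Gaussian cube file
#'
#' Standard cube layout: two comment lines; atom count and grid origin;
#' three axis lines (voxel counts and step vectors); one line per atom;
#' then the values with z fastest. Lengths are written in bohr (the cube
#' convention, flagged in the header comment); values stay in kcal/mol.
#'
#' @param result A `"probe_result"` (or compatible list with `origin`,
#'   `spacing`, `shape`, `values`, `molecule`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_cube <- function(result, path) {
  shape <- as.integer(result$shape)
  if (length(shape) != 3 || any(shape < 1)) {
    stop("grid shape must be three positive voxel counts", call. = FALSE)
  }
  stopifnot(all(is.finite(result$values)))
  mol <- result$molecule
  b <- BOHR_PER_ANGSTROM
  lines <- c(
    "dtnn volumetric grid (lengths in bohr, values in kcal/mol)",
    sprintf("probe_Z=%d", if (is.null(result$probe_Z)) 0L else result$probe_Z),
    sprintf("%5d %11.6f %11.6f %11.6f", length(mol$Z),
            result$origin[1] * b, result$origin[2] * b, result$origin[3] * b),
    sprintf("%5d %11.6f %11.6f %11.6f", shape[1], result$spacing[1] * b, 0, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", shape[2], 0, result$spacing[2] * b, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", shape[3], 0, 0, result$spacing[3] * b),
    sprintf("%5d %11.6f %11.6f %11.6f %11.6f", mol$Z, as.numeric(mol$Z),
            mol$R[, 1] * b, mol$R[, 2] * b, mol$R[, 3] * b)
  )
  # z-fastest value order, 6 per line
  idx <- expand.grid(z = seq_len(shape[3]), y = seq_len(shape[2]),
                     x = seq_len(shape[1]))
  vals <- result$values[cbind(idx$x, idx$y, idx$z)]
  chunks <- split(vals, ceiling(seq_along(vals) / 6))
  lines <- c(lines, vapply(chunks, function(v) paste(sprintf("%13.6e", v),
                                                     collapse = " "),
                           character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Gaussian cube file written by [export_cube()]
#'
#' @param path Path to a cube file.
#' @return List with `origin`, `spacing`, `shape`, `values` (3-D array,
#'   x slowest), `Z` and `R` of the embedded molecule; lengths converted
#'   back to Angstrom.
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num <- function(s) as.numeric(strsplit(trimws(s), "[ \t]+")[[1]])
  hdr <- num(lines[3])
  n_atoms <- as.integer(hdr[1])
  b <- BOHR_PER_ANGSTROM
  origin <- hdr[2:4] / b
  ax <- lapply(4:6, function(i) num(lines[i]))
  shape <- vapply(ax, function(a) as.integer(a[1]), integer(1))
  spacing <- c(ax[[1]][2], ax[[2]][3], ax[[3]][4]) / b
  at <- t(vapply(lines[6 + seq_len(n_atoms)], num, numeric(5)))
  dimnames(at) <- NULL
  vals <- unlist(lapply(lines[-(seq_len(6 + n_atoms))], num), use.names = FALSE)
  stopifnot(length(vals) == prod(shape))
  values <- array(0, dim = shape)
  idx <- expand.grid(z = seq_len(shape[3]), y = seq_len(shape[2]),
                     x = seq_len(shape[1]))
  values[cbind(idx$x, idx$y, idx$z)] <- vals
  list(origin = origin, spacing = spacing, shape = shape, values = values,
       Z = as.integer(at[, 1]), R = at[, 3:5, drop = FALSE] / b)
}

#' Energy of a substructure from the atomic partition
#'
#' Because the molecular energy is a sum of per-atom contributions, any
#' atom subset (an aromatic ring, a methyl group, ...) has a well-defined
#' energy: the sum of its members' contributions.
#'
#' @param mol A [molecule()].
#' @param atomic_energies Numeric per-atom energies (kcal/mol), as
#'   returned in `molecular_energy(...)$atomic`.
#' @param atom_indices Integer subset of atom indices (1-based, unique).
#' @return An object of class `"substructure_score"`: `id`,
#'   `atom_indices`, `score` (kcal/mol).
#' @export
substructure_energy <- function(mol, atomic_energies, atom_indices) {
  stopifnot(length(atomic_energies) == length(mol$Z))
  atom_indices <- as.integer(atom_indices)
  if (anyDuplicated(atom_indices)) stop("duplicate atom indices", call. = FALSE)
  if (length(atom_indices) &&
      (min(atom_indices) < 1 || max(atom_indices) > length(mol$Z))) {
    stop("atom index out of range 1..", length(mol$Z), call. = FALSE)
  }
  structure(
    list(id = if (is.null(mol$id)) "" else mol$id,
         atom_indices = atom_indices,
         score = sum(atomic_energies[atom_indices])),
    class = "substructure_score"
  )
}

#' Rank molecules by substructure energy
#'
#' Stable ascending order by score with ties broken lexicographically by
#' molecule id; returns the k most stable (lowest energy) and k least
#' stable (highest energy) entries.
#'
#' @param scores List of [substructure_energy()] results.
#' @param k Number of extremes to return from each end (`k <= length`).
#' @return List with `lowest` and `highest`, each a list of k scores.
#' @export
rank_by_substructure <- function(scores, k) {
  n <- length(scores)
  if (k > n) stop("k = ", k, " exceeds the ", n, " available scores", call. = FALSE)
  vals <- vapply(scores, function(s) s$score, numeric(1))
  ids <- vapply(scores, function(s) s$id, character(1))
  ord <- order(vals, ids)
  list(lowest = scores[ord[seq_len(k)]],
       highest = scores[rev(ord)[seq_len(k)]])
}

#' Find all-carbon six-membered rings from a bond list
#'
#' Convenience selector for aromatic-ring scoring: given caller-supplied
#' bonds, returns every simple 6-cycle whose members are all carbon. No
#' bond perception is performed.
#'
#' @param mol A [molecule()].
#' @param bonds Two-column integer matrix of bonded atom pairs (1-based).
#' @return List of integer vectors (atom indices of each ring), each
#'   starting at its smallest member; empty list if none.
#' @export
carbon_six_rings <- function(mol, bonds) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  carbons <- which(mol$Z == 6L)
  keep <- bonds[, 1] %in% carbons & bonds[, 2] %in% carbons
  bonds <- bonds[keep, , drop = FALSE]
  if (nrow(bonds) < 6) return(list())
  g <- igraph::graph_from_edgelist(apply(bonds, 2, as.character), directed = FALSE)
  ring <- igraph::make_ring(6)
  iso <- igraph::subgraph_isomorphisms(ring, g)
  seen <- character(0)
  out <- list()
  for (m in iso) {
    ids <- as.integer(igraph::V(g)$name[m])
    key <- paste(sort(ids), collapse = "-")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rot <- which.min(ids)
      out[[length(out) + 1L]] <- c(ids[rot:length(ids)], ids[seq_len(rot - 1L)])
    }
  }
  out
}
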