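#' Atomic system container
#'
#' Holds the positions R, atomic numbers Z, total charge Q and total spin S of
#' a molecular structure, with an optional periodic cell. Positions are in
#' Angstrom; charge in elementary charges; spin is carried as a dimensionless
#' multiplicity-like scalar (it conditions the semilocal model and is otherwise
#' metadata).
#'
#' @param positions N x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @param numbers Integer vector (length N) of atomic numbers; must be drawn
#'   from the 8 supported elements (H, C, N, O, F, P, S, Cl).
#' @param charge Total charge Q in elementary charges (integer-valued).
#' @param spin Total spin S (dimensionless scalar).
#' @param cell Optional 3 x 3 matrix of cell vectors (rows), Angstrom.
#' @param pbc Logical vector of length 3 (or single logical, recycled).
#' @param info Optional named list of extra per-system metadata (e.g. per-atom
#'   arrays attached by [read_extxyz()], residue metadata from [read_pdb()]).
#' @return An object of class `atomic_system`.
#' @examples
#' water <- atomic_system(
#'   positions = rbind(c(0, 0, 0), c(0.9572, 0, 0),
#'                     c(-0.2399872, 0.9266272, 0)),
#'   numbers = c(8L, 1L, 1L))
#' water
#' @export
atomic_system <- function(positions, numbers, charge = 0, spin = 0,
                          cell = NULL, pbc = FALSE, info = list()) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  numbers <- as.integer(numbers)
  if (length(numbers) != nrow(positions)) {
    stop("length(numbers) must equal nrow(positions)")
  }
  bad <- setdiff(unique(numbers), supported_elements())
  if (length(bad)) {
    stop("unsupported atomic number(s) ", paste(bad, collapse = ", "),
         "; supported elements are H, C, N, O, F, P, S, Cl")
  }
  if (length(pbc) == 1L) pbc <- rep(as.logical(pbc), 3L)
  pbc <- as.logical(pbc)
  if (length(pbc) != 3L) stop("pbc must be a logical vector of length 3")
  if (any(pbc)) {
    if (is.null(cell)) stop("a cell is required when any pbc flag is TRUE")
    cell <- as.matrix(cell)
    if (!all(dim(cell) == c(3L, 3L))) stop("cell must be a 3 x 3 matrix")
    if (abs(det(cell)) < 1e-10) stop("cell is singular")
  } else if (!is.null(cell)) {
    cell <- as.matrix(cell)
  }
  structure(list(positions = positions, numbers = numbers,
                 charge = charge, spin = spin,
                 cell = cell, pbc = pbc, info = info),
            class = "atomic_system")
}

#' @export
print.atomic_system <- function(x, ...) {
  comp <- table(element_symbol(x$numbers))
  formula <- paste0(names(comp), ifelse(comp > 1, comp, ""), collapse = "")
  cat("<atomic_system> ", n_atoms(x), " atoms [", formula, "]",
      "  Q=", x$charge, " S=", x$spin,
      if (any(x$pbc)) " periodic" else "", "\n", sep = "")
  invisible(x)
}

#' Number of atoms
#' @param system An `atomic_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$positions)

#' Rigid-body transform of a system (mainly for invariance tests)
#' @param system An `atomic_system`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The transformed `atomic_system`.
#' @export
transform_system <- function(system, rotation = diag(3), translation = c(0, 0, 0)) {
  system$positions <- system$positions %*% t(rotation) +
    matrix(translation, n_atoms(system), 3, byrow = TRUE)
  if (!is.null(system$cell)) system$cell <- system$cell %*% t(rotation)
  system
}

# Perpendicular widths of a cell (distance between opposite faces), Angstrom.
# For cell rows a1,a2,a3: width_k = V / |a_i x a_j|.
.cell_widths <- function(cell) {
  v <- abs(det(cell))
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  c(v / sqrt(sum(cr(cell[2, ], cell[3, ])^2)),
    v / sqrt(sum(cr(cell[3, ], cell[1, ])^2)),
    v / sqrt(sum(cr(cell[1, ], cell[2, ])^2)))
}

# Minimum-image displacements for a matrix of raw displacements (rows).
# Returns list(disp, shifts): disp = raw + shifts %*% cell.
.minimum_image <- function(disp, cell, pbc) {
  frac <- disp %*% solve(cell)
  shifts <- -round(frac)
  shifts[, !pbc] <- 0
  list(disp = disp + shifts %*% cell, shifts = shifts)
}
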