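#' Build a half neighbor list
#'
#' Enumerates all atom pairs (i < j) with |r_ij| <= cutoff, storing the
#' displacement vectors r_j - r_i (minimum image under periodic boundary
#' conditions). Pairs are ordered lexicographically by (i, j). Under pbc the
#' cutoff must not exceed half the smallest perpendicular cell width, so that
#' the minimum-image convention is unambiguous.
#'
#' @param system An [atomic_system()].
#' @param cutoff Pair cutoff in Angstrom (> 0; may be `Inf` for isolated
#'   systems).
#' @return An object of class `neighbor_table`: list with integer vectors `i`,
#'   `j` (1-based, i < j), matrix `rij` (displacements, Angstrom), vector `d`
#'   (distances), `shifts` (integer image shifts) and `cutoff`.
#' @examples
#' s <- atomic_system(rbind(c(0, 0, 0), c(3, 0, 0)), c(1L, 1L))
#' build_neighbor_table(s, 4.5)$d
#' @export
build_neighbor_table <- function(system, cutoff) {
  stopifnot(inherits(system, "atomic_system"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  n <- n_atoms(system)
  periodic <- any(system$pbc)
  if (periodic) {
    if (!is.finite(cutoff)) stop("cutoff must be finite for periodic systems")
    wmin <- min(.cell_widths(system$cell)[system$pbc])
    if (cutoff > wmin / 2 + 1e-9) {
      stop(sprintf(paste0("cutoff %.4g Angstrom violates the minimum-image bound: ",
                          "it must be <= half the smallest perpendicular cell ",
                          "width (%.4g / 2 = %.4g Angstrom)"),
                   cutoff, wmin, wmin / 2))
    }
  }
  if (n < 2L) {
    return(structure(list(i = integer(0), j = integer(0),
                          rij = matrix(numeric(0), 0, 3), d = numeric(0),
                          shifts = matrix(0L, 0, 3), cutoff = cutoff),
                     class = "neighbor_table"))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ii <- idx[, 1]; jj <- idx[, 2]
  disp <- system$positions[jj, , drop = FALSE] - system$positions[ii, , drop = FALSE]
  shifts <- matrix(0L, length(ii), 3)
  if (periodic) {
    mi <- .minimum_image(disp, system$cell, system$pbc)
    disp <- mi$disp
    shifts <- mi$shifts
  }
  d <- sqrt(rowSums(disp^2))
  keep <- d <= cutoff
  ord <- order(ii[keep], jj[keep])
  sel <- which(keep)[ord]
  structure(list(i = ii[sel], j = jj[sel],
                 rij = disp[sel, , drop = FALSE], d = d[sel],
                 shifts = shifts[sel, , drop = FALSE], cutoff = cutoff),
            class = "neighbor_table")
}

#' @export
print.neighbor_table <- function(x, ...) {
  cat("<neighbor_table> ", length(x$i), " pairs, cutoff ", x$cutoff, " Angstrom\n",
      sep = "")
  invisible(x)
}

# Scatter per-pair radial force magnitudes into per-atom force vectors.
# dEdr: derivative of energy with respect to pair distance; forces are the
# negative gradient. Returns N x 3 matrix.
.pair_forces <- function(nbr, dEdr, n) {
  f <- matrix(0, n, 3)
  if (!length(nbr$i)) return(f)
  unit <- nbr$rij / nbr$d
  # dE/dR_j = dEdr * unit ; dE/dR_i = -dEdr * unit ; force = -gradient
  contrib <- unit * dEdr
  for (k in 1:3) {
    f[, k] <- f[, k] + tapply2(nbr$i, contrib[, k], n) - tapply2(nbr$j, contrib[, k], n)
  }
  f
}

# fast grouped sum: sum 'val' into bins 1..n by index
tapply2 <- function(index, val, n) {
  out <- numeric(n)
  s <- rowsum(val, group = index)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
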