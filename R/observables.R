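#' Trajectory container
#'
#' An ordered list of frames with constant atom count/ordering, a uniform
#' frame interval, and optional per-frame velocities.
#'
#' @param frames List of [atomic_system()] objects.
#' @param frame_interval Time between stored frames (fs).
#' @param velocities Optional list of N x 3 velocity matrices (Angstrom/fs).
#' @param metadata Optional named list (selections etc.).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, frame_interval, velocities = NULL,
                       metadata = list()) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  z0 <- frames[[1]]$numbers
  for (f in frames) {
    if (!identical(f$numbers, z0)) {
      stop("all frames must share atom count and ordering")
    }
  }
  structure(list(frames = frames, frame_interval = frame_interval,
                 velocities = velocities, metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$frames), " frames x ",
      n_atoms(x$frames[[1]]), " atoms, interval ", x$frame_interval, " fs\n",
      sep = "")
  invisible(x)
}

.select_species <- function(system, species) {
  if (is.character(species)) species <- element_number(species)
  which(system$numbers == species)
}

#' Radial distribution function
#'
#' Volume-normalized pair histogram `g_AB(r)` for a species pair in periodic
#' frames; tends to 1 at large r for a homogeneous fluid.
#'
#' @param traj A [trajectory()] of periodic frames.
#' @param species_pair Length-2 vector of element symbols or atomic numbers.
#' @param r_max Histogram range (Angstrom); must respect the minimum-image
#'   bound.
#' @param bin_width Bin width (Angstrom).
#' @return data.frame with bin centers `r` and `g`.
#' @export
rdf <- function(traj, species_pair, r_max, bin_width = 0.1) {
  if (!any(traj$frames[[1]]$pbc)) {
    stop("rdf requires periodic frames (bulk normalization is undefined otherwise)")
  }
  breaks <- seq(0, r_max, by = bin_width)
  counts <- numeric(length(breaks) - 1)
  nfr <- length(traj$frames)
  for (fr in traj$frames) {
    a <- .select_species(fr, species_pair[1])
    b <- .select_species(fr, species_pair[2])
    if (!length(a) || !length(b)) stop("empty species selection")
    pairs <- expand.grid(i = a, j = b)
    if (species_pair[1] == species_pair[2]) pairs <- pairs[pairs$i != pairs$j, ]
    disp <- fr$positions[pairs$j, , drop = FALSE] -
      fr$positions[pairs$i, , drop = FALSE]
    disp <- .minimum_image(disp, fr$cell, fr$pbc)$disp
    d <- sqrt(rowSums(disp^2))
    counts <- counts + graphics::hist(d[d < r_max], breaks = breaks,
                                      plot = FALSE)$counts
  }
  fr1 <- traj$frames[[1]]
  v <- abs(det(fr1$cell))
  na <- length(.select_species(fr1, species_pair[1]))
  nb <- length(.select_species(fr1, species_pair[2]))
  npairs <- if (species_pair[1] == species_pair[2]) na * (na - 1) else na * nb
  rc <- (breaks[-1] + breaks[-length(breaks)]) / 2
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  g <- counts / nfr / (npairs / v) / shell
  data.frame(r = rc, g = g)
}

# unwrap periodic coordinates by accumulating minimum-image increments
.unwrap <- function(traj, selection) {
  nfr <- length(traj$frames)
  pos <- traj$frames[[1]]$positions[selection, , drop = FALSE]
  out <- vector("list", nfr)
  out[[1]] <- pos
  for (k in seq_len(nfr - 1)) {
    f0 <- traj$frames[[k]]; f1 <- traj$frames[[k + 1]]
    inc <- f1$positions[selection, , drop = FALSE] -
      f0$positions[selection, , drop = FALSE]
    if (any(f1$pbc)) inc <- .minimum_image(inc, f1$cell, f1$pbc)$disp
    pos <- pos + inc
    out[[k + 1]] <- pos
  }
  out
}

#' Self-diffusion coefficient from the mean-squared displacement
#'
#' Unwraps coordinates, averages the MSD over all time origins, and fits
#' `MSD(t) = 6 D t + c` by least squares over the requested lag window.
#'
#' @param traj A [trajectory()].
#' @param selection Atom indices (default: all atoms).
#' @param fit_window Length-2 vector of lag times (fs) bounding the fit.
#' @return List with `D` (Angstrom^2/ps), `msd` (data.frame lag/msd) and the
#'   fit's `r_squared` (a poor value flags non-diffusive, e.g. ballistic,
#'   motion).
#' @export
self_diffusion <- function(traj, selection = NULL, fit_window = NULL) {
  nfr <- length(traj$frames)
  if (is.null(selection)) selection <- seq_len(n_atoms(traj$frames[[1]]))
  pos <- .unwrap(traj, selection)
  lags <- seq_len(nfr - 1)
  msd <- vapply(lags, function(lag) {
    s <- 0
    orig <- seq_len(nfr - lag)
    for (t0 in orig) {
      dr <- pos[[t0 + lag]] - pos[[t0]]
      s <- s + mean(rowSums(dr^2))
    }
    s / length(orig)
  }, numeric(1))
  tlag <- lags * traj$frame_interval
  if (is.null(fit_window)) fit_window <- range(tlag)
  sel <- tlag >= fit_window[1] & tlag <= fit_window[2]
  if (sum(sel) < 2) stop("fit window selects fewer than 2 lag points")
  fit <- stats::lm(msd[sel] ~ tlag[sel])
  slope <- stats::coef(fit)[2]                       # Angstrom^2/fs
  list(D = as.numeric(slope) / 6 * 1000,             # Angstrom^2/ps
       msd = data.frame(lag = tlag, msd = msd),
       r_squared = summary(fit)$r.squared)
}

#' Dihedral angle of four points
#'
#' Standard atan2 convention, degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedral index quadruples from residue metadata
#'
#' Uses `info$atom_names` / `info$res_ids` (as attached by [read_pdb()] or
#' the peptide fixtures) to assemble phi = C(i-1)-N-CA-C and
#' psi = N-CA-C-N(i+1) index quadruples.
#'
#' @param system An [atomic_system()] with residue metadata.
#' @return List with integer matrices `phi` and `psi` (rows = residues).
#' @export
backbone_dihedrals <- function(system) {
  info <- system$info
  if (is.null(info$atom_names) || is.null(info$res_ids)) {
    stop("backbone metadata (atom_names, res_ids) missing; read from PDB or a fixture")
  }
  nm <- info$atom_names; rid <- info$res_ids
  find <- function(r, a) {
    k <- which(rid == r & nm == a)
    if (length(k) == 1L) k else NA_integer_
  }
  resids <- sort(unique(rid))
  phi <- psi <- NULL
  for (r in resids) {
    n_ <- find(r, "N"); ca <- find(r, "CA"); c_ <- find(r, "C")
    cp <- find(r - 1L, "C"); nn <- find(r + 1L, "N")
    if (!anyNA(c(cp, n_, ca, c_))) phi <- rbind(phi, c(cp, n_, ca, c_))
    if (!anyNA(c(n_, ca, c_, nn))) psi <- rbind(psi, c(n_, ca, c_, nn))
  }
  list(phi = phi, psi = psi)
}

#' Ramachandran free-energy surface by Boltzmann inversion
#'
#' Histograms (phi, psi) over frames and residues and inverts,
#' `F = -k_B T ln p`, shifting the minimum to zero; empty bins are `+Inf`.
#'
#' @param traj A [trajectory()].
#' @param quadruples List with `phi`, `psi` index matrices (see
#'   [backbone_dihedrals()]); taken from the first frame's metadata when
#'   `NULL`.
#' @param temperature Temperature (K) for the inversion.
#' @param bins Number of bins per axis over (-180, 180].
#' @return List with `phi_centers`, `psi_centers`, `fes` (kcal/mol matrix) and
#'   the raw `counts`.
#' @export
ramachandran_fes <- function(traj, quadruples = NULL, temperature = 300,
                             bins = 36) {
  if (is.null(quadruples)) quadruples <- backbone_dihedrals(traj$frames[[1]])
  if (is.null(quadruples$phi) || is.null(quadruples$psi)) {
    stop("backbone metadata insufficient to define phi/psi dihedrals")
  }
  nres <- min(nrow(quadruples$phi), nrow(quadruples$psi))
  phi <- psi <- NULL
  for (fr in traj$frames) {
    p <- fr$positions
    for (r in seq_len(nres)) {
      q1 <- quadruples$phi[r, ]; q2 <- quadruples$psi[r, ]
      phi <- c(phi, dihedral_angle(p[q1[1], ], p[q1[2], ], p[q1[3], ], p[q1[4], ]))
      psi <- c(psi, dihedral_angle(p[q2[1], ], p[q2[2], ], p[q2[3], ], p[q2[4], ]))
    }
  }
  fes_from_angles(phi, psi, temperature, bins)
}

#' Free-energy surface from raw angle samples
#'
#' The Boltzmann-inversion core of [ramachandran_fes()], exposed for synthetic
#' angle samples.
#'
#' @param phi,psi Angle samples in degrees.
#' @param temperature Temperature (K).
#' @param bins Bins per axis.
#' @return See [ramachandran_fes()].
#' @export
fes_from_angles <- function(phi, psi, temperature = 300, bins = 36) {
  breaks <- seq(-180, 180, length.out = bins + 1)
  ix <- findInterval(phi, breaks, rightmost.closed = TRUE)
  iy <- findInterval(psi, breaks, rightmost.closed = TRUE)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  p <- counts / sum(counts)
  fes <- -ff_constants$kb_kcal * temperature * log(p)
  fes[counts == 0] <- Inf
  fes <- fes - min(fes)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(phi_centers = centers, psi_centers = centers, fes = fes, counts = counts)
}

# Kabsch optimal-superposition RMSD between two N x 3 coordinate sets
.kabsch_rmsd <- function(a, b) {
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((bc - ac %*% t(rot))^2)))
}

#' Mean RMSD between conformations separated by a time lag
#'
#' For each lag `dt`, averages the optimal-superposition (Kabsch) RMSD over
#' all frame pairs (t, t + dt). Hydrogens are excluded by default.
#'
#' @param traj A [trajectory()].
#' @param lags Integer vector of lags in frames.
#' @param selection Atom indices (default: all non-hydrogen atoms).
#' @return data.frame with `lag_frames`, `lag_fs`, `rmsd`.
#' @export
rmsd_lag <- function(traj, lags, selection = NULL) {
  nfr <- length(traj$frames)
  if (any(lags >= nfr)) {
    stop("lag must be smaller than the trajectory length (", nfr, " frames)")
  }
  if (is.null(selection)) selection <- which(traj$frames[[1]]$numbers != 1L)
  out <- vapply(lags, function(lag) {
    v <- vapply(seq_len(nfr - lag), function(t0) {
      .kabsch_rmsd(traj$frames[[t0]]$positions[selection, , drop = FALSE],
                   traj$frames[[t0 + lag]]$positions[selection, , drop = FALSE])
    }, numeric(1))
    mean(v)
  }, numeric(1))
  data.frame(lag_frames = lags, lag_fs = lags * traj$frame_interval, rmsd = out)
}

#' Vibrational power spectrum from the velocity autocorrelation
#'
#' Mass-weighted velocity autocorrelation function, Hann-windowed and
#' Fourier-transformed; the abscissa is reported in wavenumbers (cm^-1) up to
#' the Nyquist limit `1/(2 c dt)`.
#'
#' @param traj A [trajectory()] carrying velocities.
#' @param window `"hann"` (default) or `"none"`.
#' @return data.frame with `wavenumber` (cm^-1) and `intensity` (arbitrary
#'   units).
#' @export
power_spectrum <- function(traj, window = c("hann", "none")) {
  window <- match.arg(window)
  if (is.null(traj$velocities)) stop("power_spectrum requires velocities")
  nfr <- length(traj$velocities)
  m <- atomic_mass(traj$frames[[1]]$numbers)
  v <- traj$velocities
  nlag <- nfr %/% 2
  vacf <- numeric(nlag)
  for (lag in 0:(nlag - 1)) {
    s <- 0
    for (t0 in seq_len(nfr - lag)) {
      s <- s + sum(m * rowSums(v[[t0]] * v[[t0 + lag]]))
    }
    vacf[lag + 1] <- s / (nfr - lag)
  }
  w <- if (window == "hann") 0.5 * (1 + cos(pi * (0:(nlag - 1)) / nlag)) else 1
  spec <- Re(stats::fft(c(vacf * w, rev(vacf * w)[-c(1, nlag)])))
  keep <- seq_len(nlag)
  dt <- traj$frame_interval
  freq <- (keep - 1) / (length(spec) * dt)          # 1/fs
  data.frame(wavenumber = freq / ff_constants$c_cm_fs, intensity = spec[keep])
}

#' Deuterium-order-style C-H bond order parameters
#'
#' `S_CD = <(3 cos^2 theta - 1)/2>` over frames and over the pairs assigned to
#' each carbon, with theta the angle between the C-H vector and the bilayer
#' normal.
#'
#' @param traj A [trajectory()].
#' @param pairs 2-column integer matrix of (carbon, hydrogen) atom indices.
#' @param carbons Optional grouping vector (one entry per pair row; defaults
#'   to the carbon index) defining the per-carbon averages.
#' @param normal Bilayer normal (default z).
#' @return data.frame with `carbon` and `s_cd`.
#' @export
lipid_order_parameters <- function(traj, pairs, carbons = NULL,
                                   normal = c(0, 0, 1)) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop("empty C-H pair list")
  if (is.null(carbons)) carbons <- pairs[, 1]
  normal <- normal / sqrt(sum(normal^2))
  acc <- numeric(nrow(pairs)); nacc <- 0
  for (fr in traj$frames) {
    vec <- fr$positions[pairs[, 2], , drop = FALSE] -
      fr$positions[pairs[, 1], , drop = FALSE]
    cosq <- (vec %*% normal) / sqrt(rowSums(vec^2))
    acc <- acc + (3 * cosq^2 - 1) / 2
    nacc <- nacc + 1
  }
  val <- acc / nacc
  agg <- tapply(val, carbons, mean)
  data.frame(carbon = names(agg), s_cd = as.numeric(agg), row.names = NULL)
}

# quadratic (three-point) interpolation of a histogram peak position
.peak_interp <- function(centers, dens, k) {
  if (k == 1 || k == length(dens)) return(centers[k])
  y1 <- dens[k - 1]; y2 <- dens[k]; y3 <- dens[k + 1]
  denom <- y1 - 2 * y2 + y3
  if (abs(denom) < 1e-12) return(centers[k])
  centers[k] + 0.5 * (y1 - y3) / denom * (centers[2] - centers[1])
}

#' Bilayer thickness and area per lipid
#'
#' Bins the headgroup number density along z (bin width 0.5 Angstrom by
#' default), locates the two leaflet maxima with quadratic sub-bin
#' interpolation to get the head-to-head thickness D_HH, and reports the
#' time-averaged area per lipid `<Lx Ly> / (n_lipids / 2)`.
#'
#' @param traj A [trajectory()] of periodic frames with the bilayer normal
#'   along z.
#' @param headgroup Atom indices of the headgroup reference atoms.
#' @param n_lipids Total lipid count (both leaflets).
#' @param bin_width Density-profile bin width (Angstrom).
#' @return List with `d_hh` (Angstrom), `area_per_lipid` (Angstrom^2) and the
#'   density `profile` data.frame.
#' @export
bilayer_metrics <- function(traj, headgroup, n_lipids, bin_width = 0.5) {
  fr1 <- traj$frames[[1]]
  if (!any(fr1$pbc)) stop("bilayer_metrics requires periodic frames")
  lz <- fr1$cell[3, 3]
  breaks <- seq(0, lz, by = bin_width)
  if (breaks[length(breaks)] < lz) breaks <- c(breaks, lz)
  counts <- numeric(length(breaks) - 1)
  area <- 0
  for (fr in traj$frames) {
    z <- fr$positions[headgroup, 3] %% fr$cell[3, 3]
    counts <- counts + graphics::hist(z, breaks = breaks, plot = FALSE)$counts
    area <- area + fr$cell[1, 1] * fr$cell[2, 2]
  }
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # local maxima of the profile
  n <- length(counts)
  ismax <- which(counts > c(-Inf, counts[-n]) & counts >= c(counts[-1], -Inf) &
                   counts > 0)
  if (length(ismax) < 2) {
    stop("headgroup density profile is unimodal: not a bilayer")
  }
  top2 <- ismax[order(counts[ismax], decreasing = TRUE)][1:2]
  peaks <- sort(vapply(top2, function(k) .peak_interp(centers, counts, k),
                       numeric(1)))
  list(d_hh = diff(peaks),
       area_per_lipid = (area / length(traj$frames)) / (n_lipids / 2),
       profile = data.frame(z = centers, count = counts))
}
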