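# Molecular dynamics trajectory metrics: Kabsch superposition, RMSD, RMSF,
# radius of gyration, Shrake-Rupley SASA, geometric hydrogen-bond counts,
# PCA over selected atoms and free energy landscapes.
#
# Units: nanometres throughout; SASA in nm^2; free energy in kT.

.selectionIndex <- function(traj, selection) {
  atoms <- traj@atoms
  if (is.null(selection) || identical(selection, "all")) return(seq_len(nrow(atoms)))
  if (is.character(selection) && length(selection) == 1L) {
    col <- c(backbone = "backbone", c1p = "c1p", "c1'" = "c1p")[tolower(selection)]
    if (is.na(col)) stop("unknown selection: ", selection)
    idx <- which(atoms[[col]])
    if (!length(idx)) stop("selection '", selection, "' matches no atoms")
    return(idx)
  }
  if (is.logical(selection)) return(which(selection))
  as.integer(selection)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (reflections excluded) and translation that
#' minimize the root mean square deviation of `mobile` from `reference`
#' over the selected atoms, and applies it to all of `mobile`.
#'
#' @param mobile,reference Numeric `n x 3` coordinate matrices.
#' @param selection Optional index vector of atoms used for the fit
#'   (default: all); at least 3 non-collinear atoms.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (over the selection, after superposition) and `transformed` (all of
#'   `mobile`, superposed).
#' @export
kabschSuperpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
    nrow(mobile) == nrow(reference))
  sel <- if (is.null(selection)) seq_len(nrow(mobile)) else selection
  if (length(sel) < 3L) stop("need at least 3 atoms in the fit selection")
  p <- mobile[sel, , drop = FALSE]
  q <- reference[sel, , drop = FALSE]
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2L, pc); q0 <- sweep(q, 2L, qc)
  sv <- svd(crossprod(p0, q0))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) fit selection")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transformed <- sweep(sweep(mobile, 2L, pc) %*% t(rot), 2L, qc, "+")
  dev <- transformed[sel, , drop = FALSE] - q
  list(rotation = rot, translation = qc - as.vector(rot %*% pc),
    rmsd = sqrt(mean(rowSums(dev^2))), transformed = transformed)
}

# Superpose every frame of a trajectory onto reference coords (n x 3).
.fitFrames <- function(traj, reference, selection) {
  out <- traj@coords
  for (f in seq_len(dim(out)[1])) {
    out[f, , ] <- kabschSuperpose(out[f, , ], reference, selection)$transformed
  }
  out
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is optimally superposed (Kabsch, over the selection) onto
#' the reference frame before computing the RMSD over the same selection.
#'
#' @param traj A [Trajectory-class].
#' @param reference_frame Frame index used as reference (default 1).
#' @param selection Atom selection (`"backbone"`, `"c1p"`, `"all"`, or
#'   indices); default sugar-phosphate backbone.
#' @return data.frame `frame`, `value` (nm), with attributes `mean`, `sd`.
#' @export
rmsdSeries <- function(traj, reference_frame = 1L, selection = "backbone") {
  stopifnot(methods::is(traj, "Trajectory"))
  sel <- .selectionIndex(traj, selection)
  ref <- traj@coords[reference_frame, , ]
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    kabschSuperpose(traj@coords[f, , ], ref, sel)$rmsd
  }, numeric(1))
  .metricSeries("RMSD", vals)
}

.metricSeries <- function(name, vals) {
  out <- data.frame(frame = seq_along(vals), value = vals)
  attr(out, "metric") <- name
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- stats::sd(vals)
  out
}

#' Per-atom root mean square fluctuation
#'
#' RMSF of each selected atom around its time-mean position.  With
#' `fit = TRUE` frames are first superposed onto frame 1 (over the
#' selection), the mean structure computed, and frames re-fitted once onto
#' that mean before the fluctuations are measured.
#'
#' @param traj A [Trajectory-class] with at least 2 frames (a single frame
#'   returns zeros with a warning).
#' @param selection Atom selection; default ribose C1' atoms.
#' @param fit Superpose frames before measuring (default TRUE).
#' @return Numeric vector of per-atom RMSF (nm), one per selected atom.
#' @export
rmsf <- function(traj, selection = "c1p", fit = TRUE) {
  stopifnot(methods::is(traj, "Trajectory"))
  sel <- .selectionIndex(traj, selection)
  nf <- nFrames(traj)
  if (nf < 2L) {
    warning("single-frame trajectory: RMSF is zero")
    return(rep(0, length(sel)))
  }
  coords <- traj@coords
  if (fit) {
    coords <- .fitFrames(traj, coords[1, , ], sel)
    mean_struct <- apply(coords, c(2, 3), mean)
    tmp <- traj; tmp@coords <- coords
    coords <- .fitFrames(tmp, mean_struct, sel)
  }
  x <- coords[, sel, , drop = FALSE]
  mu <- apply(x, c(2, 3), mean)
  sq <- vapply(seq_along(sel), function(a) {
    mean(rowSums(sweep(x[, a, , drop = TRUE], 2L, mu[a, ])^2))
  }, numeric(1))
  sqrt(sq)
}

#' Mass-weighted radius of gyration per frame
#'
#' `Rg = sqrt(sum m_i |r_i - r_cm|^2 / sum m_i)`.
#'
#' @param traj A [Trajectory-class] with atom masses set.
#' @return data.frame `frame`, `value` (nm), with `mean`/`sd` attributes.
#' @export
radiusOfGyration <- function(traj) {
  stopifnot(methods::is(traj, "Trajectory"))
  m <- traj@atoms$mass
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    xyz <- traj@coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    cm <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2L, cm)^2)) / sum(m))
  }, numeric(1))
  .metricSeries("Rg", vals)
}

# Deterministic near-uniform sphere points (golden-section spiral).
.spherePoints <- function(n) {
  k <- seq_len(n) - 0.5
  theta <- acos(1 - 2 * k / n)
  phi <- pi * (1 + sqrt(5)) * k
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Solvent-accessible surface area per frame (Shrake-Rupley)
#'
#' Each atom's sphere of radius `vdW + probe` is sampled with a
#' deterministic spiral point set; points falling inside any neighbouring
#' sphere are buried, and the accessible fraction scales the sphere area.
#'
#' @param traj A [Trajectory-class] with atom `radius` set (nm).
#' @param probe_radius Solvent probe radius, default 0.14 nm (water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return data.frame `frame`, `value` (nm^2), with `mean`/`sd` attributes.
#' @export
sasa <- function(traj, probe_radius = 0.14, n_points = 960L) {
  stopifnot(methods::is(traj, "Trajectory"))
  pts <- .spherePoints(n_points)
  rad <- traj@atoms$radius + probe_radius
  n_atoms <- nrow(traj@atoms)
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    xyz <- matrix(traj@coords[f, , ], ncol = 3L)
    total <- 0
    for (a in seq_len(n_atoms)) {
      d2 <- rowSums(sweep(xyz, 2L, xyz[a, ])^2)
      nb <- which(d2 < (rad + rad[a])^2 & seq_len(n_atoms) != a)
      sphere <- sweep(pts * rad[a], 2L, xyz[a, ], "+")
      acc <- rep(TRUE, n_points)
      for (b in nb) {
        acc[acc] <- rowSums(sweep(sphere[acc, , drop = FALSE], 2L,
          xyz[b, ])^2) > rad[b]^2
        if (!any(acc)) break
      }
      total <- total + 4 * pi * rad[a]^2 * mean(acc)
    }
    total
  }, numeric(1))
  .metricSeries("SASA", vals)
}

#' Geometric hydrogen-bond count per frame
#'
#' Counts donor-hydrogen-acceptor triples with donor-acceptor distance
#' `<= d_max` and hydrogen-donor-acceptor angle `<= angle_max` (the
#' convention of standard MD analysis tools).  Hydrogens are attached to
#' their donor via the `bonded_to` atom column, or, when absent, to the
#' nearest donor in frame 1.  The `"base_pairing"` filter restricts both
#' donor and acceptor to atoms flagged `base_pairing` (canonical, wobble
#' and Hoogsteen edge atoms in RNA).
#'
#' @param traj A [Trajectory-class] with donor/hydrogen/acceptor flags.
#' @param d_max Donor-acceptor distance cutoff, default 0.35 nm.
#' @param angle_max H-D-A angle cutoff in degrees, default 30.
#' @param pair_filter `"all"` or `"base_pairing"`.
#' @return data.frame `frame`, `value` (count), with `mean`/`sd`
#'   attributes.
#' @export
hbondCount <- function(traj, d_max = 0.35, angle_max = 30,
    pair_filter = c("all", "base_pairing")) {
  stopifnot(methods::is(traj, "Trajectory"))
  pair_filter <- match.arg(pair_filter)
  atoms <- traj@atoms
  hyd <- which(atoms$hydrogen)
  don_ok <- atoms$donor
  acc_ok <- atoms$acceptor
  if (pair_filter == "base_pairing") {
    don_ok <- don_ok & atoms$base_pairing
    acc_ok <- acc_ok & atoms$base_pairing
  }
  if (!length(hyd) || !any(don_ok) || !any(acc_ok)) {
    warning("no donor/hydrogen/acceptor triples available")
    return(.metricSeries(paste0("Hbonds_", pair_filter), rep(0, nFrames(traj))))
  }
  donor_of <- atoms$bonded_to[hyd]
  if (anyNA(donor_of)) {
    ref <- matrix(traj@coords[1, , ], ncol = 3L)
    donors_all <- which(atoms$donor)
    for (i in which(is.na(donor_of))) {
      d2 <- rowSums(sweep(ref[donors_all, , drop = FALSE], 2L, ref[hyd[i], ])^2)
      donor_of[i] <- donors_all[which.min(d2)]
    }
  }
  acceptors <- which(acc_ok)
  cos_max <- cos(angle_max * pi / 180)
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    xyz <- matrix(traj@coords[f, , ], ncol = 3L)
    count <- 0L
    for (i in seq_along(hyd)) {
      d <- donor_of[i]
      if (!don_ok[d]) next
      vda <- sweep(xyz[acceptors, , drop = FALSE], 2L, xyz[d, ])
      dist_da <- sqrt(rowSums(vda^2))
      vdh <- xyz[hyd[i], ] - xyz[d, ]
      nh <- sqrt(sum(vdh^2))
      cosang <- (vda %*% vdh) / (dist_da * nh)
      ok <- acceptors != d & dist_da <= d_max & cosang >= cos_max & dist_da > 0
      count <- count + sum(ok)
    }
    as.numeric(count)
  }, numeric(1))
  .metricSeries(paste0("Hbonds_", pair_filter), vals)
}

#' Principal component analysis of atomic fluctuations
#'
#' Frames are superposed (onto frame 1 and then once onto the mean
#' structure) over the selection, flattened to a frames x 3k matrix and
#' decomposed with [stats::prcomp()].  Projections are mean-centred and
#' eigenvalues non-increasing.
#'
#' @param traj A [Trajectory-class] with at least 2 frames.
#' @param selection Atom selection; default ribose C1' atoms.
#' @param fit Superpose frames before the decomposition (default TRUE).
#' @return List with `mean` (k x 3 mean structure), `eigenvalues`,
#'   `eigenvectors`, `projections` (frames x components),
#'   `variance_fraction`.
#' @export
pcaTrajectory <- function(traj, selection = "c1p", fit = TRUE) {
  stopifnot(methods::is(traj, "Trajectory"))
  if (nFrames(traj) < 2L) stop("need at least 2 frames for PCA")
  sel <- .selectionIndex(traj, selection)
  coords <- traj@coords
  if (fit) {
    coords <- .fitFrames(traj, coords[1, , ], sel)
    tmp <- traj; tmp@coords <- coords
    coords <- .fitFrames(tmp, apply(coords, c(2, 3), mean), sel)
  }
  x <- coords[, sel, , drop = FALSE]
  flat <- matrix(aperm(x, c(1, 3, 2)), nrow = dim(x)[1])  # frames x (3k)
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(mean = apply(x, c(2, 3), mean), eigenvalues = ev,
    eigenvectors = pc$rotation, projections = pc$x,
    variance_fraction = ev / sum(ev))
}

#' Free energy landscape over the first two principal components
#'
#' Bins the (PC1, PC2) projections into a 2D histogram and converts
#' occupancy to free energy `G = -ln(count / max count)` in kT units; the
#' modal bin has `G = 0` and unsampled bins are `NA`.
#'
#' @param pca_result Result of [pcaTrajectory()] (or any list with a
#'   `projections` matrix).
#' @param bins Number of bins per axis (default 32).
#' @return List with `G` (bins x bins matrix, kT), `counts`, `x_breaks`,
#'   `y_breaks`.
#' @export
felGrid <- function(pca_result, bins = 32L) {
  proj <- pca_result$projections
  stopifnot(ncol(proj) >= 2L)
  bx <- seq(min(proj[, 1]), max(proj[, 1]), length.out = bins + 1L)
  by <- seq(min(proj[, 2]), max(proj[, 2]), length.out = bins + 1L)
  ix <- pmin(findInterval(proj[, 1], bx, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(proj[, 2], by, rightmost.closed = TRUE), bins)
  counts <- matrix(0L, bins, bins)
  for (f in seq_len(nrow(proj))) {
    counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1L
  }
  g <- -log(counts / max(counts))
  g[counts == 0L] <- NA_real_
  list(G = g, counts = counts, x_breaks = bx, y_breaks = by)
}

#' Superpose and concatenate trajectories
#'
#' Every frame of every trajectory is superposed onto a shared reference
#' structure (over the selection) before concatenation; frame provenance
#' labels record the trajectory of origin.
#'
#' @param trajs List of [Trajectory-class] objects with identical atom
#'   counts.
#' @param reference Reference coordinates (n x 3); default frame 1 of the
#'   first trajectory.
#' @param selection Atom selection used for the fit; default backbone.
#' @return A [Trajectory-class] with the atoms of the first trajectory and
#'   all frames, `provenance` labelling each frame's source.
#' @export
concatFitted <- function(trajs, reference = NULL, selection = "backbone") {
  stopifnot(length(trajs) >= 1L)
  n_atoms <- vapply(trajs, function(t) dim(t@coords)[2], integer(1))
  if (length(unique(n_atoms)) != 1L) stop("atom-count mismatch across trajectories")
  if (is.null(reference)) reference <- trajs[[1]]@coords[1, , ]
  labels <- if (!is.null(names(trajs)) && all(nzchar(names(trajs)))) {
    names(trajs)
  } else sprintf("traj%d", seq_along(trajs))
  sel <- .selectionIndex(trajs[[1]], selection)
  pieces <- lapply(trajs, function(t) .fitFrames(t, reference, sel))
  total <- sum(vapply(pieces, function(p) dim(p)[1], integer(1)))
  coords <- array(0, dim = c(total, unname(n_atoms[1]), 3L))
  prov <- character(total)
  at <- 0L
  for (i in seq_along(pieces)) {
    nf <- dim(pieces[[i]])[1]
    coords[at + seq_len(nf), , ] <- pieces[[i]]
    prov[at + seq_len(nf)] <- labels[i]
    at <- at + nf
  }
  Trajectory(coords, trajs[[1]]@atoms, provenance = prov)
}

#' Read a trajectory from coordinate and atom-metadata tables
#'
#' The coordinate table has columns `frame`, `atom`, `x`, `y`, `z`
#' (whitespace- or comma-separated); the atom table carries the metadata
#' columns of [Trajectory()].
#'
#' @param coords_path Coordinate table file.
#' @param atoms_path Optional atom metadata CSV.
#' @return A [Trajectory-class].
#' @export
readTrajectory <- function(coords_path, atoms_path = NULL) {
  tab <- utils::read.table(coords_path, header = TRUE,
    sep = if (grepl("\\.csv$", coords_path)) "," else "")
  frames <- sort(unique(tab$frame))
  atoms_idx <- sort(unique(tab$atom))
  coords <- array(NA_real_, dim = c(length(frames), length(atoms_idx), 3L))
  fi <- match(tab$frame, frames); ai <- match(tab$atom, atoms_idx)
  coords[cbind(fi, ai, 1L)] <- tab$x
  coords[cbind(fi, ai, 2L)] <- tab$y
  coords[cbind(fi, ai, 3L)] <- tab$z
  atoms <- if (!is.null(atoms_path)) utils::read.csv(atoms_path) else NULL
  Trajectory(coords, atoms)
}

#' Write a trajectory to coordinate and atom-metadata tables
#'
#' @param traj A [Trajectory-class].
#' @param coords_path Output coordinate CSV (`frame, atom, x, y, z`).
#' @param atoms_path Optional output CSV for atom metadata.
#' @return Invisibly, `coords_path`.
#' @export
writeTrajectory <- function(traj, coords_path, atoms_path = NULL) {
  d <- dim(traj@coords)
  grid <- expand.grid(atom = seq_len(d[2]), frame = seq_len(d[1]))
  out <- data.frame(frame = grid$frame, atom = grid$atom,
    x = as.vector(t(traj@coords[, , 1])),
    y = as.vector(t(traj@coords[, , 2])),
    z = as.vector(t(traj@coords[, , 3])))
  utils::write.csv(out, coords_path, row.names = FALSE, quote = FALSE)
  if (!is.null(atoms_path)) {
    utils::write.csv(traj@atoms, atoms_path, row.names = FALSE, quote = FALSE)
  }
  invisible(coords_path)
}
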