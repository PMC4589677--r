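# Helix axis vectors and inter-chain crossing angles.

#' Define a helical segment
#'
#' @param chain chain identifier (single character).
#' @param residues inclusive residue range, \code{c(first, last)} or
#'   \code{"first-last"}; at least 4 residues.
#' @param atoms atom names used for the axis (default \code{"backbone"}).
#' @return a [HelixDefinition-class].
#' @examples
#' helixDefinition("A", "120-132")   # the C-terminal Jalpha helix
#' @export
helixDefinition <- function(chain, residues, atoms = "backbone") {
  atoms <- as.character(atoms)
  if (any(atoms == "backbone"))
    atoms <- unique(c(.BACKBONE, atoms[atoms != "backbone"]))
  new("HelixDefinition", chain = as.character(chain),
      residueRange = parseResidueRange(residues), atomNames = atoms)
}

# Axis of an ordered list of per-residue centroids by the bisector
# construction: for an ideal helix the curvature bisectors
# f_i = c_{i-1} + c_{i+1} - 2 c_i are exactly perpendicular to the axis
# (the axial components of the second difference cancel for a uniform
# rise), so cross products of successive bisectors recover the axis
# exactly for any helix of >= 4 residues, short or long, independent of
# radius and twist. Estimates from all consecutive bisector pairs are
# sign-aligned with the N-to-C chord and averaged. A near-straight
# segment (vanishing curvature) falls back to the principal axis of the
# centroids, which is exact in that degenerate case.
.axisFromCentroids <- function(cent) {
  R <- nrow(cent)
  chord <- cent[R, ] - cent[1, ]
  f <- cent[seq_len(R - 2L), , drop = FALSE] +
       cent[seq.int(3L, R), , drop = FALSE] -
       2 * cent[seq.int(2L, R - 1L), , drop = FALSE]
  nf <- nrow(f)
  cr <- matrix(NA_real_, nf - 1L, 3L)
  for (i in seq_len(nf - 1L)) cr[i, ] <- cross3(f[i, ], f[i + 1L, ])
  norms <- sqrt(rowSums(cr^2))
  scale <- max(sqrt(rowSums(f^2)))
  if (all(norms <= 1e-10 * max(scale^2, 1))) {
    # degenerate curvature: straight segment; principal axis of centroids
    cc <- sweep(cent, 2L, colMeans(cent))
    sv <- svd(cc, nu = 0L)
    if (sv$d[1] < 1e-10)
      stop("degenerate helix: zero-variance atom cloud", call. = FALSE)
    ax <- sv$v[, 1L]
    if (sum(ax * chord) < 0) ax <- -ax
    return(unitVector(ax))
  }
  keep <- norms > 1e-10 * max(scale^2, 1)
  u <- cr[keep, , drop = FALSE] / norms[keep]
  s <- sign(u %*% chord)
  s[s == 0] <- 1
  ax <- colSums(u * as.vector(s))
  if (sqrt(sum(ax^2)) < 1e-10)
    stop("degenerate helix: inconsistent axis estimates", call. = FALSE)
  unitVector(ax)
}

#' Helix axis vector for one frame
#'
#' Estimates the axis of a helical segment as a unit vector oriented from
#' the N-terminal toward the C-terminal end. The selected atoms are
#' grouped into per-residue centroids and the axis is built from the
#' curvature bisectors of consecutive centroid triples (exact for ideal
#' helices of four residues and up, and equivariant under rigid motions);
#' a straight, curvature-free segment falls back to the principal axis of
#' the centroids. A zero-variance atom cloud is an error.
#'
#' @param trajectory a [Trajectory-class].
#' @param helix a [HelixDefinition-class].
#' @param frame 1-based frame index.
#' @return numeric(3) unit vector.
#' @export
helixAxis <- function(trajectory, helix, frame = 1L) {
  stopifnot(is(trajectory, "Trajectory"), is(helix, "HelixDefinition"))
  idx <- resolveSelection(trajectory@topology, helix)
  X <- trajectory@coords[idx, , frame, drop = TRUE]
  a <- trajectory@topology@atoms[idx, , drop = FALSE]
  # residue index order defines N -> C (PDB numbering increases toward C)
  res <- factor(a$resid, levels = sort(unique(a$resid)))
  if (nlevels(res) < 4L)
    stop("helix axis needs at least 4 resolved residues", call. = FALSE)
  cent <- apply(X, 2L, function(col) tapply(col, res, mean))
  .axisFromCentroids(cent)
}

#' Crossing angle between two axis vectors
#'
#' Orientation-aware angle in degrees within [0, 180]: anti-parallel axes
#' give 180, not 0. Non-unit inputs are normalised with a warning.
#'
#' @param a,b numeric(3) axis vectors.
#' @return numeric(1), degrees.
#' @examples
#' crossingAngle(c(0, 0, 1), c(0, 1, 0))   # 90
#' @export
crossingAngle <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (abs(na - 1) > 1e-6 || abs(nb - 1) > 1e-6) {
    warning("non-unit axis vector(s) normalised", call. = FALSE)
    a <- a / na; b <- b / nb
  } else {
    a <- a / na; b <- b / nb
  }
  acos(pmin(1, pmax(-1, sum(a * b)))) * 180 / pi
}

#' Crossing-angle distribution of two helices over a trajectory
#'
#' Computes the inter-helix crossing angle in every raw frame (no
#' superposition is applied: the angle between two axes of the same frame
#' is invariant under rigid motions of that frame), and returns the raw
#' per-frame series with a frequency histogram over [0, 180] degrees.
#' Mean and standard deviation are taken from the raw series; statistics
#' recomputed from the binned frequencies are reported alongside for
#' comparison with frequency-distribution-derived summaries.
#'
#' @param trajectory a [Trajectory-class].
#' @param helixA,helixB [HelixDefinition-class] objects (typically the
#'   same helix on the two chains of a dimer).
#' @param binWidth histogram bin width, degrees (default 1).
#' @return an [AngleDistribution-class].
#' @export
crossingAngleDistribution <- function(trajectory, helixA, helixB,
                                      binWidth = 1) {
  stopifnot(is(trajectory, "Trajectory"), binWidth > 0)
  nf <- nFrames(trajectory)
  ang <- numeric(nf)
  for (f in seq_len(nf)) {
    ang[f] <- crossingAngle(helixAxis(trajectory, helixA, f),
                            helixAxis(trajectory, helixB, f))
  }
  breaks <- seq(0, 180, by = binWidth)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  h <- graphics::hist(ang, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  counts <- as.integer(h$counts)
  mids <- h$mids
  n <- sum(counts)
  bm <- sum(mids * counts) / n
  bsd <- if (n > 1L) sqrt(sum(counts * (mids - bm)^2) / (n - 1L)) else 0
  new("AngleDistribution", angles = ang, breaks = breaks, counts = counts,
      mean = mean(ang), sd = stats::sd(ang), binnedMean = bm,
      binnedSd = bsd)
}
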