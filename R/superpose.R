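# Rigid-body superposition and RMSD/RMSF profiling.

.asCoordMatrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must be an n x 3 matrix",
                          call. = FALSE)
  storage.mode(x) <- "double"
  x
}

.checkNonDegenerate <- function(x, what) {
  d <- svd(scale(x, scale = FALSE), nu = 0, nv = 0)$d
  if (length(d) < 2L || d[2] < 1e-8 * max(d[1], 1))
    stop("degenerate ", what, " coordinate set: points are collinear",
         call. = FALSE)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation \eqn{R} and translation \eqn{t} minimising the
#' root-mean-square deviation between \code{mobile} and \code{reference}
#' over all rigid motions, via singular value decomposition of the
#' cross-covariance matrix. Reflections are excluded by flipping the sign
#' of the smallest singular vector when the raw optimum is improper, so
#' \code{det(R) = +1} always.
#'
#' @param mobile,reference \code{n x 3} coordinate matrices with matched
#'   rows, \code{n >= 3}, not collinear.
#' @return a [FitResult-class] with the transform mapping \code{mobile}
#'   onto \code{reference} and the minimised RMSD (Angstrom).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(18), 6, 3)
#' fit <- kabschFit(x, x)           # identity, rmsd 0
#' fit@rmsd
#' @export
kabschFit <- function(mobile, reference) {
  P <- .asCoordMatrix(mobile)
  Q <- .asCoordMatrix(reference)
  if (nrow(P) != nrow(Q))
    stop("mobile and reference must have the same number of points",
         call. = FALSE)
  if (nrow(P) < 3L)
    stop("superposition needs at least 3 points", call. = FALSE)
  .checkNonDegenerate(P, "mobile")
  .checkNonDegenerate(Q, "reference")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tr <- as.vector(cq - R %*% cp)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  new("FitResult", rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param x an \code{n x 3} coordinate matrix.
#' @param fit a [FitResult-class] from [kabschFit()].
#' @return the transformed \code{n x 3} matrix.
#' @export
applyFit <- function(x, fit) {
  stopifnot(is(fit, "FitResult"))
  sweep(.asCoordMatrix(x) %*% t(fit@rotation), 2L, fit@translation, "+")
}

#' Superpose every frame of a trajectory onto a reference
#'
#' Each frame receives its own least-squares fit, computed on the atoms of
#' \code{fitSelection} against the same atoms of \code{reference}; the
#' transform is then applied to all atoms of the frame. This is the
#' chain-selective superposition used to expose inter-subunit motion: fit
#' on chain A, and displacements of chain B remain visible.
#'
#' @param trajectory a [Trajectory-class].
#' @param fitSelection an [AtomSelection-class] naming the fit atoms
#'   (default: all atoms).
#' @param reference full-atom \code{n x 3} coordinate matrix (default:
#'   the first frame).
#' @return a new [Trajectory-class] with transformed coordinates.
#' @export
superposeTrajectory <- function(trajectory, fitSelection = NULL,
                                reference = NULL) {
  stopifnot(is(trajectory, "Trajectory"))
  idx <- if (is.null(fitSelection)) seq_len(nAtoms(trajectory))
         else resolveSelection(trajectory@topology, fitSelection)
  ref <- if (is.null(reference)) frameCoords(trajectory, 1L)
         else .asCoordMatrix(reference)
  if (nrow(ref) != nAtoms(trajectory))
    stop("reference must have one row per trajectory atom", call. = FALSE)
  refSel <- ref[idx, , drop = FALSE]
  cc <- trajectory@coords
  for (f in seq_len(nFrames(trajectory))) {
    fit <- kabschFit(cc[idx, , f], refSel)
    cc[, , f] <- applyFit(cc[, , f], fit)
  }
  Trajectory(trajectory@topology, cc, trajectory@frameInterval)
}

# Fit frames to their own time-average structure: fit to frame 1, average,
# refit to the average (one refinement iteration). Used by rmsf() and dccm().
.superposeToMean <- function(trajectory, fitSelection = NULL) {
  tr <- superposeTrajectory(trajectory, fitSelection)
  avg <- averageStructure(tr)
  superposeTrajectory(tr, fitSelection, reference = avg)
}

#' Average structure of a trajectory
#'
#' Per-atom arithmetic mean of the coordinates over all frames ("the
#' average position" that displacement-based statistics are referred to).
#'
#' @param trajectory a [Trajectory-class].
#' @param selection optional [AtomSelection-class]; default all atoms.
#' @return an \code{n x 3} coordinate matrix.
#' @export
averageStructure <- function(trajectory, selection = NULL) {
  stopifnot(is(trajectory, "Trajectory"))
  idx <- if (is.null(selection)) seq_len(nAtoms(trajectory))
         else resolveSelection(trajectory@topology, selection)
  apply(trajectory@coords[idx, , , drop = FALSE], c(1L, 2L), mean)
}

# residue grouping of a set of atom indices, order of first appearance
.residueGroups <- function(topology, idx) {
  a <- topology@atoms[idx, , drop = FALSE]
  key <- paste(a$chain, a$resid, sep = ":")
  split(idx, factor(key, levels = unique(key)))
}

#' Per-residue RMSD profile against a reference structure
#'
#' Frames are first superposed on \code{fitSelection} (against
#' \code{reference}); then, for every residue of \code{measureSelection},
#' the RMSD over that residue's atoms and all frames versus the reference
#' is reported: \eqn{\sqrt{\langle |x - x_{ref}|^2 \rangle}} with the mean
#' running over frames and the residue's atoms. The standard use is fitting
#' on the backbone of chain A and measuring chain B, which turns
#' inter-subunit rearrangement into per-residue displacement.
#'
#' @param trajectory a [Trajectory-class].
#' @param measureSelection an [AtomSelection-class] of measured atoms.
#' @param reference full-atom \code{n x 3} matrix (default first frame).
#' @param fitSelection optional [AtomSelection-class] of fit atoms; NULL
#'   fits on all atoms.
#' @return a data.frame with columns \code{chain}, \code{resid},
#'   \code{value} (Angstrom).
#' @export
perResidueRMSD <- function(trajectory, measureSelection, reference = NULL,
                           fitSelection = NULL) {
  stopifnot(is(trajectory, "Trajectory"))
  ref <- if (is.null(reference)) frameCoords(trajectory, 1L)
         else .asCoordMatrix(reference)
  tr <- superposeTrajectory(trajectory, fitSelection, reference = ref)
  midx <- resolveSelection(tr@topology, measureSelection)
  groups <- .residueGroups(tr@topology, midx)
  nf <- nFrames(tr)
  value <- vapply(groups, function(ii) {
    ss <- 0
    for (f in seq_len(nf))
      ss <- ss + sum((tr@coords[ii, , f] - ref[ii, , drop = FALSE])^2)
    sqrt(ss / (length(ii) * nf))
  }, numeric(1))
  keys <- do.call(rbind, strsplit(names(groups), ":", fixed = TRUE))
  data.frame(chain = keys[, 1L], resid = as.integer(keys[, 2L]),
             value = unname(value), stringsAsFactors = FALSE)
}

# frame-wise RMSD of a set of atoms against a reference, optionally with a
# per-frame fit on fitIdx
.framewiseRMSD <- function(cc, ref, measureIdx, fitIdx = NULL) {
  nf <- dim(cc)[3L]
  out <- numeric(nf)
  refM <- ref[measureIdx, , drop = FALSE]
  for (f in seq_len(nf)) {
    X <- cc[, , f]
    if (!is.null(fitIdx)) {
      fit <- kabschFit(X[fitIdx, , drop = FALSE],
                       ref[fitIdx, , drop = FALSE])
      X <- applyFit(X, fit)
    }
    out[f] <- sqrt(mean(rowSums((X[measureIdx, , drop = FALSE] - refM)^2)))
  }
  out
}

#' Region RMSD summary table across trajectories
#'
#' For every trajectory and region, the time average of the frame-wise
#' backbone RMSD against the trajectory's own reference (by default its
#' starting structure), plus per-state "Average" rows (arithmetic mean
#' across the trajectories of each state). Two fitting conventions are
#' provided, since either may be meant by a published region RMSD:
#' \describe{
#'   \item{\code{fit = "region"}}{each frame is fitted on the region's own
#'     atoms before measuring it (default for region rows);}
#'   \item{\code{fit = "global"}}{each frame is fitted once on
#'     \code{globalFitSelection} (e.g. the full-dimer backbone) and regions
#'     are measured without refitting.}
#' }
#'
#' @param trajectories named list of [Trajectory-class] objects.
#' @param states character vector, one of \code{"dark"}/\code{"light"} per
#'   trajectory (any labels are allowed; averages are grouped by label).
#' @param regions named list of [AtomSelection-class] regions (see
#'   [lovRegions()] for the standard set).
#' @param fit \code{"region"} or \code{"global"}.
#' @param globalFitSelection selection used when \code{fit = "global"}
#'   (default: backbone of all atoms).
#' @param references optional list of full-atom reference matrices, one per
#'   trajectory; default is each trajectory's first frame.
#' @return a data.frame with columns \code{label}, \code{state},
#'   \code{region}, \code{rmsd}; per-state average rows have label
#'   \code{"Average"}.
#' @export
regionRMSDSummary <- function(trajectories, states, regions,
                              fit = c("region", "global"),
                              globalFitSelection = NULL,
                              references = NULL) {
  fit <- match.arg(fit)
  stopifnot(length(trajectories) == length(states))
  labels <- names(trajectories) %||% as.character(seq_along(trajectories))
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named list", call. = FALSE)
  rows <- list()
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    ref <- if (is.null(references)) frameCoords(tr, 1L)
           else .asCoordMatrix(references[[i]])
    gIdx <- NULL
    if (fit == "global") {
      gsel <- globalFitSelection %||% atomSelection(atoms = "backbone")
      gIdx <- resolveSelection(tr@topology, gsel)
    }
    for (rn in names(regions)) {
      midx <- resolveSelection(tr@topology, regions[[rn]])
      fitIdx <- if (fit == "region") midx else gIdx
      rw <- mean(.framewiseRMSD(tr@coords, ref, midx, fitIdx))
      rows[[length(rows) + 1L]] <- data.frame(
        label = labels[i], state = states[i], region = rn, rmsd = rw,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  for (st in unique(states)) {
    sub <- out[out$state == st, , drop = FALSE]
    avg <- stats::aggregate(rmsd ~ region, data = sub, FUN = mean)
    rows[[length(rows) + 1L]] <- data.frame(
      label = "Average", state = st, region = avg$region, rmsd = avg$rmsd,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard LOV-domain region definitions
#'
#' The region set used for dimeric short-LOV analyses, in PpSB1-LOV
#' numbering: the full dimer backbone; the LOV core (residues 20-119); the
#' N-terminal A'alpha helix (3-13); the C-terminal Jalpha helix (120-132);
#' and the Hbeta (94-104) and Ibeta (109-117) strands. All regions select
#' backbone atoms on the given chains. The core boundary is configurable
#' because, unlike the helix and strand ranges, it is a topology-derived
#' convention.
#'
#' @param chains chain identifiers to include (default both chains A, B).
#' @param core inclusive residue range of the LOV core.
#' @return named list of [AtomSelection-class] objects.
#' @export
lovRegions <- function(chains = c("A", "B"), core = c(20, 119)) {
  list(
    full = atomSelection(chains = chains, atoms = "backbone"),
    core = atomSelection(chains = chains, residues = core,
                         atoms = "backbone"),
    "A'alpha" = atomSelection(chains = chains, residues = c(3, 13),
                              atoms = "backbone"),
    Jalpha = atomSelection(chains = chains, residues = c(120, 132),
                           atoms = "backbone"),
    Hbeta = atomSelection(chains = chains, residues = c(94, 104),
                          atoms = "backbone"),
    Ibeta = atomSelection(chains = chains, residues = c(109, 117),
                          atoms = "backbone"))
}

#' Root-mean-square fluctuation profile
#'
#' Per-residue RMSF about the time-average structure: for each selected
#' atom, the mean squared displacement from its average position over all
#' frames; the residue value is the square root of the mean over the
#' residue's atoms. With \code{fitSelection} given, frames are first
#' superposed onto their time-average structure (fit to frame 1, average,
#' refit to the average) so that global drift does not inflate the
#' fluctuations; with \code{fitSelection = NULL} no fitting is performed
#' (the mode in which isotropic noise of per-coordinate sigma gives the
#' closed form RMSF = sigma * sqrt(3)).
#'
#' @param trajectory a [Trajectory-class] with at least 2 frames.
#' @param selection an [AtomSelection-class] of measured atoms (default
#'   backbone of everything).
#' @param fitSelection optional fit selection, or NULL for no fitting.
#' @return a data.frame with columns \code{chain}, \code{resid},
#'   \code{value} (Angstrom).
#' @export
rmsf <- function(trajectory, selection = NULL, fitSelection = NULL) {
  stopifnot(is(trajectory, "Trajectory"))
  if (nFrames(trajectory) < 2L)
    stop("RMSF is undefined for a single frame", call. = FALSE)
  tr <- if (is.null(fitSelection)) trajectory
        else .superposeToMean(trajectory, fitSelection)
  sel <- selection %||% atomSelection(atoms = "backbone")
  idx <- resolveSelection(tr@topology, sel)
  avg <- apply(tr@coords[idx, , , drop = FALSE], c(1L, 2L), mean)
  nf <- nFrames(tr)
  msd <- numeric(length(idx))
  for (f in seq_len(nf))
    msd <- msd + rowSums((tr@coords[idx, , f] - avg)^2)
  msd <- msd / nf
  groups <- .residueGroups(tr@topology, idx)
  pos <- match(unlist(groups, use.names = FALSE), idx)
  grp <- rep(seq_along(groups), lengths(groups))
  value <- sqrt(tapply(msd[pos], grp, mean))
  keys <- do.call(rbind, strsplit(names(groups), ":", fixed = TRUE))
  data.frame(chain = keys[, 1L], resid = as.integer(keys[, 2L]),
             value = as.numeric(value), stringsAsFactors = FALSE)
}

#' Signed difference of two per-residue profiles
#'
#' Element-wise \code{light - dark} on matched (chain, residue) keys; by
#' this convention negative values flag residues with larger changes in
#' the dark state. Key sets must match exactly; mismatches are an error
#' listing the offending keys.
#'
#' @param light,dark data.frames with columns \code{chain}, \code{resid},
#'   \code{value} as returned by [perResidueRMSD()] or [rmsf()].
#' @return a data.frame of the same shape; \code{value} is signed.
#' @export
rmsdDifferenceProfile <- function(light, dark) {
  kl <- paste(light$chain, light$resid, sep = ":")
  kd <- paste(dark$chain, dark$resid, sep = ":")
  if (!setequal(kl, kd) || length(kl) != length(kd)) {
    miss <- c(setdiff(kl, kd), setdiff(kd, kl))
    stop("profile key sets differ; unmatched keys: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  m <- match(kl, kd)
  data.frame(chain = light$chain, resid = light$resid,
             value = light$value - dark$value[m],
             stringsAsFactors = FALSE)
}
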