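# Geometric hydrogen-bond and salt-bridge analysis.
#
# An H-bond is counted in a frame iff the donor-acceptor distance is at
# most the distance cutoff AND the donor-hydrogen...acceptor angle lies in
# the angle window; a salt bridge iff the cation-anion distance is at most
# its cutoff. All bounds are inclusive.

#' Geometric interaction criteria
#'
#' Defaults are the moderate hydrogen-bond cutoffs in common use (3.2
#' Angstrom donor-acceptor distance, 130-180 degree donor-hydrogen-acceptor
#' angle) and a 5 Angstrom cation-anion cutoff for salt bridges measured at
#' the carboxylate carbon, deliberately generous to be insensitive to
#' carboxylate OE1/OE2 rotation. \code{secondaryContactThreshold} is a
#' supplementary, looser distance (not an H-bond criterion) under which the
#' fraction of frames is reported, to quantify weak electrostatic contacts
#' that sit above the H-bond cutoff.
#'
#' @param maxDonorAcceptorDistance Angstrom, > 0.
#' @param angleRange degrees, \code{c(min, max)} within [0, 180].
#' @param saltBridgeCutoff Angstrom, > 0.
#' @param secondaryContactThreshold Angstrom; loose-contact reporting only.
#' @return a list with class \code{"GeometricCriteria"}.
#' @export
geometricCriteria <- function(maxDonorAcceptorDistance = 3.2,
                              angleRange = c(130, 180),
                              saltBridgeCutoff = 5.0,
                              secondaryContactThreshold = 4.0) {
  stopifnot(maxDonorAcceptorDistance > 0, saltBridgeCutoff > 0,
            length(angleRange) == 2L)
  if (!(angleRange[1] >= 0 && angleRange[1] <= angleRange[2] &&
        angleRange[2] <= 180))
    stop("angleRange must satisfy 0 <= min <= max <= 180", call. = FALSE)
  structure(list(maxDonorAcceptorDistance = maxDonorAcceptorDistance,
                 angleRange = as.numeric(angleRange),
                 saltBridgeCutoff = saltBridgeCutoff,
                 secondaryContactThreshold = secondaryContactThreshold),
            class = "GeometricCriteria")
}

#' Define a hydrogen-bond specification
#'
#' A named donor-hydrogen-acceptor triple. Each hydrogen is a separate
#' specification: an amide with two protons (e.g. a glutamine NE2 with 1HE
#' and 2HE) contributes two specs whose occupancies are reported
#' separately.
#'
#' @param label short unique name for reports.
#' @param donor,hydrogen,acceptor atom keys \code{"chain:resid:atom"}.
#' @return a list with class \code{"HBondSpec"}.
#' @examples
#' hbondSpec("Q116-FMN-O4", donor = "A:116:NE2",
#'           hydrogen = "A:116:2HE", acceptor = "A:140:O4")
#' @export
hbondSpec <- function(label, donor, hydrogen, acceptor) {
  keys <- lapply(list(donor, hydrogen, acceptor), parseAtomKey)
  ks <- vapply(keys, formatAtomKey, character(1))
  if (anyDuplicated(ks))
    stop("donor, hydrogen and acceptor must be three distinct atoms",
         call. = FALSE)
  structure(list(label = as.character(label), donor = keys[[1L]],
                 hydrogen = keys[[2L]], acceptor = keys[[3L]]),
            class = "HBondSpec")
}

#' Define a salt-bridge specification
#'
#' A cation-anion atom pair, e.g. a lysine NZ against a glutamate CD
#' (measuring at the carboxylate carbon rather than OE1/OE2 avoids
#' ambiguity from carboxylate rotation). Intra- and inter-subunit bridges
#' are distinct specs: K117(A)-E96(A) versus K117(A)-E96(B).
#'
#' @param label short unique name for reports.
#' @param cation,anion atom keys \code{"chain:resid:atom"}.
#' @return a list with class \code{"SaltBridgeSpec"}.
#' @examples
#' saltBridgeSpec("K117A-E96B", cation = "A:117:NZ", anion = "B:96:CD")
#' @export
saltBridgeSpec <- function(label, cation, anion) {
  keys <- lapply(list(cation, anion), parseAtomKey)
  if (identical(formatAtomKey(keys[[1L]]), formatAtomKey(keys[[2L]])))
    stop("cation and anion must be distinct atoms", call. = FALSE)
  structure(list(label = as.character(label), cation = keys[[1L]],
                 anion = keys[[2L]]),
            class = "SaltBridgeSpec")
}

#' Per-frame distance between two atoms
#'
#' Euclidean distance in Angstrom, one value per frame in frame order.
#' Symmetric in its atom pair.
#'
#' @param trajectory a [Trajectory-class].
#' @param a,b atom keys \code{"chain:resid:atom"}.
#' @return numeric vector, length \code{nFrames(trajectory)}.
#' @export
distanceSeries <- function(trajectory, a, b) {
  stopifnot(is(trajectory, "Trajectory"))
  ia <- atomIndex(trajectory@topology, a)
  ib <- atomIndex(trajectory@topology, b)
  d <- trajectory@coords[ia, , , drop = TRUE] -
       trajectory@coords[ib, , , drop = TRUE]
  if (is.null(dim(d))) return(sqrt(sum(d^2)))  # single frame
  sqrt(colSums(d^2))
}

#' Per-frame donor-hydrogen-acceptor angle
#'
#' The angle at the hydrogen between the H-to-donor and H-to-acceptor
#' vectors, in degrees within [0, 180]. A frame in which the hydrogen
#' coincides with the donor or acceptor has no defined angle; such frames
#' are reported as \code{NA} with a warning naming them, never silently
#' dropped.
#'
#' @param trajectory a [Trajectory-class].
#' @param donor,hydrogen,acceptor atom keys.
#' @return numeric vector of degrees, length \code{nFrames(trajectory)}.
#' @export
angleSeries <- function(trajectory, donor, hydrogen, acceptor) {
  stopifnot(is(trajectory, "Trajectory"))
  top <- trajectory@topology
  id <- atomIndex(top, donor)
  ih <- atomIndex(top, hydrogen)
  ia <- atomIndex(top, acceptor)
  cc <- trajectory@coords
  nf <- nFrames(trajectory)
  U <- matrix(cc[id, , ] - cc[ih, , ], nrow = 3L)   # H -> D, 3 x T
  V <- matrix(cc[ia, , ] - cc[ih, , ], nrow = 3L)   # H -> A
  nu <- sqrt(colSums(U^2)); nv <- sqrt(colSums(V^2))
  bad <- nu == 0 | nv == 0
  cosang <- colSums(U * V) / (nu * nv)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (any(bad)) {
    ang[bad] <- NA_real_
    warning("undefined D-H-A angle (coincident atoms) in frame(s): ",
            paste(utils::head(which(bad), 5L), collapse = ", "),
            if (sum(bad) > 5L) " ..." else "", call. = FALSE)
  }
  ang[seq_len(nf)]
}

.occupancyFrameWindow <- function(n, skipFrames) {
  if (skipFrames < 0 || skipFrames >= n)
    stop("skipFrames must be in [0, nFrames)", call. = FALSE)
  seq.int(skipFrames + 1L, n)
}

#' Hydrogen-bond occupancy statistics
#'
#' For each specification, the fraction of analysed frames in which the
#' donor-acceptor distance is at most the cutoff AND the
#' donor-hydrogen-acceptor angle falls inside the angle window (all bounds
#' inclusive). Occupancy is reported as a percentage at 0.1 precision,
#' together with the satisfying-frame count, the mean distance and mean
#' angle, and the loose-contact fraction (share of frames under
#' \code{secondaryContactThreshold}; informational, not part of the H-bond
#' criterion).
#'
#' @param trajectory a [Trajectory-class].
#' @param specs a list of [hbondSpec()] objects (a single spec is
#'   accepted).
#' @param criteria a [geometricCriteria()] list.
#' @param skipFrames number of leading frames excluded from the statistics
#'   (default 0: every saved frame is analysed).
#' @return a data.frame with one row per spec: \code{label}, \code{donor},
#'   \code{hydrogen}, \code{acceptor}, \code{count}, \code{frames},
#'   \code{occupancy} (percent), \code{meanDistance}, \code{meanAngle},
#'   \code{contactFraction}.
#' @export
hbondOccupancy <- function(trajectory, specs,
                           criteria = geometricCriteria(),
                           skipFrames = 0L) {
  stopifnot(is(trajectory, "Trajectory"))
  if (inherits(specs, "HBondSpec")) specs <- list(specs)
  frames <- .occupancyFrameWindow(nFrames(trajectory), skipFrames)
  top <- trajectory@topology
  rows <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "HBondSpec"))
    hEl <- top@atoms$element[atomIndex(top, sp$hydrogen)]
    if (toupper(hEl) != "H")
      stop("hydrogen atom of spec '", sp$label, "' has element '", hEl,
           "', expected H", call. = FALSE)
    d <- distanceSeries(trajectory, sp$donor, sp$acceptor)[frames]
    a <- angleSeries(trajectory, sp$donor, sp$hydrogen,
                     sp$acceptor)[frames]
    sat <- !is.na(a) & d <= criteria$maxDonorAcceptorDistance &
      a >= criteria$angleRange[1] & a <= criteria$angleRange[2]
    data.frame(label = sp$label,
               donor = formatAtomKey(sp$donor),
               hydrogen = formatAtomKey(sp$hydrogen),
               acceptor = formatAtomKey(sp$acceptor),
               count = sum(sat), frames = length(frames),
               occupancy = round(100 * sum(sat) / length(frames), 1L),
               meanDistance = mean(d), meanAngle = mean(a, na.rm = TRUE),
               contactFraction =
                 mean(d <= criteria$secondaryContactThreshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Salt-bridge occupancy statistics
#'
#' A frame counts iff the cation-anion distance is at most the salt-bridge
#' cutoff (inclusive). Occupancy is a percentage at 0.1 precision.
#'
#' @inheritParams hbondOccupancy
#' @param specs a list of [saltBridgeSpec()] objects (a single spec is
#'   accepted).
#' @return a data.frame with one row per spec: \code{label}, \code{cation},
#'   \code{anion}, \code{count}, \code{frames}, \code{occupancy},
#'   \code{meanDistance}.
#' @export
saltBridgeOccupancy <- function(trajectory, specs,
                                criteria = geometricCriteria(),
                                skipFrames = 0L) {
  stopifnot(is(trajectory, "Trajectory"))
  if (inherits(specs, "SaltBridgeSpec")) specs <- list(specs)
  frames <- .occupancyFrameWindow(nFrames(trajectory), skipFrames)
  rows <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "SaltBridgeSpec"))
    d <- distanceSeries(trajectory, sp$cation, sp$anion)[frames]
    sat <- d <= criteria$saltBridgeCutoff
    data.frame(label = sp$label,
               cation = formatAtomKey(sp$cation),
               anion = formatAtomKey(sp$anion),
               count = sum(sat), frames = length(frames),
               occupancy = round(100 * sum(sat) / length(frames), 1L),
               meanDistance = mean(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
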