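#' @import methods
NULL

.BACKBONE <- c("N", "CA", "C", "O")

#' Topology: the atom identity table of a structure
#'
#' A \code{Topology} holds the ordered atom records of a (possibly dimeric)
#' protein structure: one row per atom with chain identifier, 1-based residue
#' index, residue name, PDB atom name and element symbol. Atom order is the
#' file/build order and is stable; the triple (chain, residue, atom name)
#' is unique.
#'
#' @slot atoms a \code{data.frame} with character columns \code{chain},
#'   \code{resname}, \code{name}, \code{element} and integer column
#'   \code{resid}.
#'
#' @seealso [readTopology()], [buildDimerTopology()], [resolveSelection()]
#' @export
setClass("Topology", slots = c(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("chain", "resid", "resname", "name", "element")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("topology must contain at least one atom")
  if (!is.numeric(a$resid)) return("resid must be numeric")
  if (anyNA(a$chain) || anyNA(a$resid) || anyNA(a$name))
    return("chain, resid and name must not contain NA")
  key <- paste(a$chain, a$resid, a$name, sep = ":")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    return(paste0("duplicate atom key: ", dup))
  }
  TRUE
})

#' Trajectory: a topology plus ordered coordinate frames
#'
#' Coordinates are stored as an \code{n_atoms x 3 x n_frames} array in
#' Angstrom. The optional \code{frameInterval} records the time spacing of
#' saved snapshots in picoseconds; no analysis depends on it.
#'
#' @slot topology a [Topology-class] object.
#' @slot coords numeric array, \code{n_atoms x 3 x n_frames}, Angstrom.
#' @slot frameInterval numeric(1), picoseconds between frames (may be NA).
#'
#' @seealso [readTrajectory()], [generateTrajectory()]
#' @export
setClass("Trajectory",
         slots = c(topology = "Topology", coords = "array",
                   frameInterval = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@topology@atoms))
    return(sprintf("coords have %d atoms but topology has %d",
                   d[1], nrow(object@topology@atoms)))
  if (d[3] < 1L) return("trajectory must contain at least one frame")
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (length(object@frameInterval) != 1L)
    return("frameInterval must be a single number (possibly NA)")
  TRUE
})

#' AtomSelection: a declarative atom subset
#'
#' Selects atoms by any combination of chain identifiers, an inclusive
#' 1-based residue range and a set of atom names. Empty slots mean "no
#' restriction". The alias \code{"backbone"} expands to N, CA, C, O.
#'
#' @slot chains character vector of chain ids (length 0 = all chains).
#' @slot residueRange integer vector of length 0 (all) or 2 (first, last).
#' @slot atomNames character vector of atom names (length 0 = all).
#'
#' @seealso [atomSelection()], [resolveSelection()]
#' @export
setClass("AtomSelection",
         slots = c(chains = "character", residueRange = "integer",
                   atomNames = "character"))

setValidity("AtomSelection", function(object) {
  rr <- object@residueRange
  if (!(length(rr) %in% c(0L, 2L)))
    return("residueRange must be empty or c(first, last)")
  if (length(rr) == 2L && rr[1] > rr[2])
    return("residueRange first must not exceed last")
  TRUE
})

#' HelixDefinition: a helical segment of one chain
#'
#' @slot chain character(1) chain identifier.
#' @slot residueRange integer(2), inclusive 1-based residue range;
#'   at least 4 residues are required for a stable axis estimate.
#' @slot atomNames atom names used for the axis (default backbone).
#'
#' @seealso [helixDefinition()], [helixAxis()]
#' @export
setClass("HelixDefinition",
         slots = c(chain = "character", residueRange = "integer",
                   atomNames = "character"))

setValidity("HelixDefinition", function(object) {
  if (length(object@chain) != 1L) return("chain must be a single identifier")
  rr <- object@residueRange
  if (length(rr) != 2L || rr[1] > rr[2])
    return("residueRange must be c(first, last) with first <= last")
  if (rr[2] - rr[1] + 1L < 4L)
    return("a helix needs at least 4 residues for axis estimation")
  TRUE
})

# Shared shape for residue-by-residue square matrices (DCCM and differences).
#' @export
setClass("ResidueMatrix",
         representation("VIRTUAL", keys = "data.frame",
                        values = "matrix"))

.validResidueMatrix <- function(object, lo, hi, what) {
  k <- object@keys
  if (!all(c("chain", "resid") %in% names(k)))
    return("keys must have columns chain and resid")
  v <- object@values
  if (nrow(v) != ncol(v)) return("value matrix must be square")
  if (nrow(v) != nrow(k)) return("value matrix size must match keys")
  ok <- !is.na(v)
  if (any(v[ok] < lo - 1e-9 | v[ok] > hi + 1e-9))
    return(sprintf("%s entries must lie in [%g, %g]", what, lo, hi))
  if (any(abs(v - t(v)) > 1e-12, na.rm = TRUE) ||
      !identical(is.na(v), is.na(t(v))))
    return(sprintf("%s must be symmetric", what))
  TRUE
}

#' CorrelationMatrix: a dynamic cross-correlation matrix
#'
#' Symmetric residue-by-residue matrix of normalised displacement
#' correlations. Entries lie in [-1, +1]; the diagonal is +1 for every
#' residue with nonzero fluctuation. Residues with exactly zero fluctuation
#' yield undefined correlations which are stored as \code{NA} (masked),
#' never silently zero.
#'
#' @slot keys data.frame with columns \code{chain}, \code{resid}, in matrix
#'   row/column order.
#' @slot values numeric square matrix.
#'
#' @seealso [dccm()], [averageDCCM()], [differenceDCCM()]
#' @export
setClass("CorrelationMatrix", contains = "ResidueMatrix")

setValidity("CorrelationMatrix", function(object) {
  ok <- .validResidueMatrix(object, -1, 1, "correlation")
  if (!isTRUE(ok)) return(ok)
  dg <- diag(object@values)
  if (any(abs(dg[!is.na(dg)] - 1) > 1e-9))
    return("diagonal must be +1 for residues with nonzero fluctuation")
  TRUE
})

#' DifferenceMatrix: a between-state correlation difference
#'
#' Element-wise difference of two [CorrelationMatrix-class] objects
#' (conventionally light minus dark); entries lie in [-2, +2]. Swapping the
#' two input states negates the matrix.
#'
#' @slot keys data.frame with columns \code{chain}, \code{resid}.
#' @slot values numeric square matrix.
#' @export
setClass("DifferenceMatrix", contains = "ResidueMatrix")

setValidity("DifferenceMatrix", function(object) {
  .validResidueMatrix(object, -2, 2, "difference")
})

#' AngleDistribution: per-frame helix crossing angles with summary
#'
#' Holds the raw per-frame crossing-angle series in degrees, a frequency
#' histogram over [0, 180] degrees, and the mean and standard deviation.
#' Mean and SD are computed from the raw series; binned (frequency-
#' distribution) statistics are carried alongside for comparison.
#'
#' @slot angles numeric per-frame angle series, degrees in [0, 180].
#' @slot breaks histogram bin edges, degrees.
#' @slot counts integer bin counts; sums to the number of frames.
#' @slot mean,sd numeric(1), from the raw series.
#' @slot binnedMean,binnedSd numeric(1), from bin midpoints and counts.
#' @export
setClass("AngleDistribution",
         slots = c(angles = "numeric", breaks = "numeric",
                   counts = "integer", mean = "numeric", sd = "numeric",
                   binnedMean = "numeric", binnedSd = "numeric"))

setValidity("AngleDistribution", function(object) {
  a <- object@angles
  if (any(a < -1e-9 | a > 180 + 1e-9, na.rm = TRUE))
    return("angles must lie in [0, 180] degrees")
  if (sum(object@counts) != sum(!is.na(a)))
    return("histogram counts must sum to the number of measured frames")
  if (!is.na(object@sd) && object@sd < 0) return("sd must be >= 0")
  TRUE
})

#' FitResult: a rigid-body superposition transform
#'
#' The proper rotation and translation minimising the RMSD between a mobile
#' and a reference coordinate set, plus the minimised RMSD. Reflections are
#' excluded: \code{det(rotation) = +1}.
#'
#' @slot rotation 3x3 proper orthogonal matrix.
#' @slot translation numeric(3), Angstrom.
#' @slot rmsd numeric(1), Angstrom, >= 0.
#'
#' @seealso [kabschFit()], [applyFit()]
#' @export
setClass("FitResult",
         slots = c(rotation = "matrix", translation = "numeric",
                   rmsd = "numeric"))

setValidity("FitResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = +1)")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthogonal")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})
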