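#' @rdname Trajectory-class
#' @param x an object.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname Topology-class
#' @param x an object.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname Trajectory-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Trajectory-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Extract coordinates
#'
#' \code{coords(x)} returns the full coordinate array
#' (\code{n_atoms x 3 x n_frames}); \code{frameCoords(x, frame)} returns the
#' \code{n_atoms x 3} matrix of one frame.
#'
#' @param x a [Trajectory-class].
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @param frame 1-based frame index.
#' @export
setGeneric("frameCoords", function(x, frame = 1L) standardGeneric("frameCoords"))

#' @rdname ResidueMatrix-class
#' @param x an object.
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' @rdname ResidueMatrix-class
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))

#' Extract a block of a residue-by-residue matrix
#'
#' Returns the requested block of a correlation or difference matrix, in the
#' requested row/column order, as a base matrix with residue-key dimnames
#' (for example rows = chain A residues 90-134 against columns = all of
#' chain B, the layout used for inter-chain difference maps).
#'
#' @param x a [CorrelationMatrix-class] or [DifferenceMatrix-class].
#' @param rows,cols character vectors of residue keys \code{"chain:resid"}
#'   (e.g. \code{"A:116"}), or selection lists \code{list(chain=, resid=)}.
#' @return a numeric matrix block with residue-key dimnames.
#' @export
setGeneric("subMatrix", function(x, rows, cols) standardGeneric("subMatrix"))

#' @rdname AngleDistribution-class
#' @param x an object.
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
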