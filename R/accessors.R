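#' Construct a Trajectory
#'
#' @param topology a [Topology-class].
#' @param coords numeric array \code{n_atoms x 3 x n_frames} (Angstrom); a
#'   single \code{n_atoms x 3} matrix is promoted to a one-frame trajectory.
#' @param frameInterval picoseconds between frames (metadata only).
#' @return a [Trajectory-class].
#' @export
Trajectory <- function(topology, coords, frameInterval = NA_real_) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  new("Trajectory", topology = topology, coords = coords,
      frameInterval = as.numeric(frameInterval))
}

#' @rdname Trajectory-class
#' @aliases topology,Trajectory-method
#' @export
setMethod("topology", "Trajectory", function(x) x@topology)

#' @rdname Topology-class
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

#' @rdname Topology-class
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' @rdname Trajectory-class
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @rdname Trajectory-class
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1L])

#' @rdname Trajectory-class
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3L])

#' @rdname Trajectory-class
#' @export
setMethod("frameInterval", "Trajectory", function(x) x@frameInterval)

#' @rdname coords
#' @export
setMethod("coords", "Trajectory", function(x) x@coords)

#' @rdname coords
#' @export
setMethod("frameCoords", "Trajectory", function(x, frame = 1L) {
  stopifnot(frame >= 1L, frame <= nFrames(x))
  x@coords[, , frame, drop = TRUE]
})

#' @rdname ResidueMatrix-class
#' @export
setMethod("residueKeys", "ResidueMatrix", function(x) x@keys)

#' @rdname ResidueMatrix-class
#' @export
setMethod("matrixValues", "ResidueMatrix", function(x) {
  v <- x@values
  kn <- paste(x@keys$chain, x@keys$resid, sep = ":")
  dimnames(v) <- list(kn, kn)
  v
})

#' @rdname AngleDistribution-class
#' @export
setMethod("angles", "AngleDistribution", function(x) x@angles)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  ch <- table(a$chain)
  cat(sprintf("Topology: %d atoms, %d chain(s) [%s], %d residues\n",
              nrow(a), length(ch),
              paste(names(ch), collapse = ","),
              length(unique(paste(a$chain, a$resid)))))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d atoms x %d frame(s)", nAtoms(object),
              nFrames(object)))
  if (!is.na(object@frameInterval))
    cat(sprintf(", %g ps/frame", object@frameInterval))
  cat("\n")
  show(object@topology)
})

setMethod("show", "AtomSelection", function(object) {
  f <- function(v, what)
    if (length(v) == 0L) paste0(what, "=all")
    else paste0(what, "=", paste(v, collapse = ","))
  cat("AtomSelection:", f(object@chains, "chains"),
      if (length(object@residueRange))
        sprintf("residues=%d-%d", object@residueRange[1],
                object@residueRange[2]) else "residues=all",
      f(object@atomNames, "atoms"), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  v <- object@values
  cat(sprintf("CorrelationMatrix: %d x %d residues, %d masked entries\n",
              nrow(v), ncol(v), sum(is.na(v))))
})

setMethod("show", "DifferenceMatrix", function(object) {
  v <- object@values
  cat(sprintf("DifferenceMatrix: %d x %d residues, range [%.3f, %.3f]\n",
              nrow(v), ncol(v), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "AngleDistribution", function(object) {
  cat(sprintf(
    "AngleDistribution: n = %d, mean = %.2f deg, sd = %.2f deg\n",
    length(object@angles), object@mean, object@sd))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: rmsd = %.4f A\n", object@rmsd))
})
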