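# Dynamic cross-correlation matrices of per-residue displacements.

# Per-residue representative coordinates: nres x 3 x nframes.
.representativeCoords <- function(trajectory, representation, selection) {
  top <- trajectory@topology
  idx <- if (is.null(selection)) seq_len(nAtoms(trajectory))
         else resolveSelection(top, selection)
  a <- top@atoms[idx, , drop = FALSE]
  if (representation == "CA") {
    sub <- idx[a$name == "CA"]
    if (length(sub) == 0L)
      stop("no CA atoms in the analysis selection", call. = FALSE)
    keys <- residueTable(top, sub)
    P <- trajectory@coords[sub, , , drop = FALSE]
  } else {
    bb <- idx[a$name %in% .BACKBONE]
    if (length(bb) == 0L)
      stop("no backbone atoms in the analysis selection", call. = FALSE)
    groups <- .residueGroups(top, bb)
    keys <- residueTable(top, bb)
    nf <- nFrames(trajectory)
    P <- array(NA_real_, dim = c(length(groups), 3L, nf))
    for (g in seq_along(groups)) {
      gi <- groups[[g]]
      P[g, , ] <- apply(trajectory@coords[gi, , , drop = FALSE],
                        c(2L, 3L), mean)
    }
  }
  list(P = P, keys = keys)
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' The normalised covariance of per-residue displacement vectors about
#' their time-average positions:
#' \deqn{DCCM_{ij} = \frac{\langle \vec d_i \cdot \vec d_j \rangle}
#'   {\sqrt{\langle d_i^2 \rangle \langle d_j^2 \rangle}}}
#' where \eqn{\vec d_i(t)} is the displacement of residue i's
#' representative point from its average position and the angle brackets
#' average over all frames. Values range from -1 (perfectly
#' anti-correlated) through 0 (uncorrelated) to +1 (perfectly correlated);
#' the diagonal is +1 by self-correlation. The square-root normalisation
#' is what guarantees that range and unit diagonal (Cauchy-Schwarz).
#'
#' Residues are represented by their CA atom by default; a backbone-
#' centroid mode is provided. When \code{fitSelection} is given, frames
#' are first superposed onto their time-average structure (fit to frame 1,
#' average, refit; one refinement iteration) so that a global rigid drift
#' is not reported as spurious correlation. Residues with exactly zero
#' fluctuation have no defined correlation: their rows/columns are masked
#' as \code{NA} with a warning, never silently set to 0.
#'
#' @param trajectory a [Trajectory-class] with at least 2 frames.
#' @param representation \code{"CA"} (default) or \code{"centroid"}
#'   (backbone centroid per residue).
#' @param fitSelection optional [AtomSelection-class] to superpose on
#'   before the analysis; NULL analyses raw frames.
#' @param selection optional [AtomSelection-class] restricting the residues
#'   analysed.
#' @return a [CorrelationMatrix-class].
#' @export
dccm <- function(trajectory, representation = c("CA", "centroid"),
                 fitSelection = NULL, selection = NULL) {
  stopifnot(is(trajectory, "Trajectory"))
  representation <- match.arg(representation)
  if (nFrames(trajectory) < 2L)
    stop("DCCM is undefined for a single frame", call. = FALSE)
  tr <- if (is.null(fitSelection)) trajectory
        else .superposeToMean(trajectory, fitSelection)
  rep <- .representativeCoords(tr, representation, selection)
  P <- rep$P
  nres <- dim(P)[1L]
  nf <- dim(P)[3L]
  Dx <- P[, 1L, ] - rowMeans(P[, 1L, , drop = TRUE])
  Dy <- P[, 2L, ] - rowMeans(P[, 2L, , drop = TRUE])
  Dz <- P[, 3L, ] - rowMeans(P[, 3L, , drop = TRUE])
  num <- (tcrossprod(Dx) + tcrossprod(Dy) + tcrossprod(Dz)) / nf
  v <- diag(num)                       # <d_i^2>
  still <- v <= 0
  if (any(still)) {
    kk <- paste(rep$keys$chain[still], rep$keys$resid[still], sep = ":")
    warning("zero-fluctuation residue(s) masked in DCCM: ",
            paste(utils::head(kk, 8L), collapse = ", "),
            if (sum(still) > 8L) " ..." else "", call. = FALSE)
  }
  den <- sqrt(outer(v, v))
  M <- num / den
  M[still, ] <- NA_real_
  M[, still] <- NA_real_
  M <- pmin(pmax(M, -1), 1)            # clip floating-point overshoot
  diag(M)[!still] <- 1                 # self-correlation is exactly +1
  M <- (M + t(M)) / 2                  # enforce exact symmetry
  new("CorrelationMatrix", keys = rep$keys, values = M)
}

.checkSameKeys <- function(keyList) {
  ref <- keyList[[1L]]
  for (i in seq_along(keyList)[-1L]) {
    k <- keyList[[i]]
    if (nrow(k) != nrow(ref) || any(k$chain != ref$chain) ||
        any(k$resid != ref$resid))
      stop("matrices have different residue key sets/ordering",
           call. = FALSE)
  }
  ref
}

#' Average several correlation matrices
#'
#' Element-wise arithmetic mean over matrices with identical residue keys
#' (e.g. combining the matrices of replicate dark-state runs into one
#' average dark-state matrix). Masked (\code{NA}) entries propagate
#' sensibly: each cell averages over the inputs in which it is defined,
#' and stays masked only where it is masked everywhere.
#'
#' @param matrices a list of [CorrelationMatrix-class] objects.
#' @return a [CorrelationMatrix-class].
#' @export
averageDCCM <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  keys <- .checkSameKeys(lapply(matrices, function(m) m@keys))
  arr <- vapply(matrices, function(m) m@values,
                matrix(0, nrow(keys), nrow(keys)))
  s <- apply(arr, c(1L, 2L), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  new("CorrelationMatrix", keys = keys, values = s)
}

#' Difference of two state-averaged correlation matrices
#'
#' Element-wise \code{light - dark}. By this sign convention a positive
#' entry means higher correlation in the light state (or stronger
#' anti-correlation in the dark state); swapping the arguments negates the
#' matrix.
#'
#' @param light,dark [CorrelationMatrix-class] objects with matching keys.
#' @return a [DifferenceMatrix-class].
#' @export
differenceDCCM <- function(light, dark) {
  stopifnot(is(light, "CorrelationMatrix"), is(dark, "CorrelationMatrix"))
  keys <- .checkSameKeys(list(light@keys, dark@keys))
  new("DifferenceMatrix", keys = keys,
      values = light@values - dark@values)
}

.keyIndices <- function(x, keys) {
  have <- paste(x@keys$chain, x@keys$resid, sep = ":")
  if (is.list(keys) && !is.null(keys$chain)) {
    sel <- x@keys$chain %in% keys$chain
    if (!is.null(keys$resid))
      sel <- sel & x@keys$resid >= keys$resid[1] &
             x@keys$resid <= keys$resid[2]
    return(which(sel))
  }
  i <- match(as.character(keys), have)
  if (anyNA(i))
    stop("unknown residue key(s): ",
         paste(keys[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' @rdname subMatrix
#' @export
setMethod("subMatrix", "ResidueMatrix", function(x, rows, cols) {
  v <- matrixValues(x)
  v[.keyIndices(x, rows), .keyIndices(x, cols), drop = FALSE]
})
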