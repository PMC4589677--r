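# PDB input/output. Parsing and formatting of ATOM/HETATM records is
# delegated to bio3d; the wrappers add the contracts this pipeline relies
# on: per-model atom-count validation, insertion-code rejection, first-
# altLoc-kept policy and duplicate-key detection.

# Quick line-level scan of a PDB file: model boundaries and atom counts.
# Catches malformed records (with their line number) before handing the
# file to the parser, and mismatched per-model atom counts (naming the
# model) that would otherwise surface as an opaque dimension error.
.scanPdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  isAtom <- rec == "ATOM  " | rec == "HETATM"
  isModel <- startsWith(rec, "MODEL")
  if (!any(isAtom))
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  bad <- which(isAtom & nchar(lines) < 54L)
  if (length(bad) == 0L) {
    xs <- suppressWarnings(as.numeric(substr(lines[isAtom], 31L, 38L)))
    ys <- suppressWarnings(as.numeric(substr(lines[isAtom], 39L, 46L)))
    zs <- suppressWarnings(as.numeric(substr(lines[isAtom], 47L, 54L)))
    badc <- which(is.na(xs) | is.na(ys) | is.na(zs))
    if (length(badc)) bad <- which(isAtom)[badc]
  }
  if (length(bad))
    stop(sprintf("malformed ATOM/HETATM record at line %d of %s",
                 bad[1L], path), call. = FALSE)
  if (any(isModel)) {
    modelId <- cumsum(isModel)
    counts <- tabulate(modelId[isAtom], nbins = max(modelId))
    serials <- trimws(substr(lines[isModel], 7L, 26L))
    if (length(unique(counts)) > 1L) {
      ref <- counts[1L]
      off <- which(counts != ref)[1L]
      stop(sprintf(
        "inconsistent atom count in model %s of %s: %d atoms, expected %d",
        serials[off], path, counts[off], ref), call. = FALSE)
    }
    nModels <- max(modelId)
  } else {
    nModels <- 1L
  }
  list(nModels = nModels)
}

# Convert a bio3d atom table (plus xyz) into a Topology, applying the
# alternate-location policy and key validation.
.topologyFromBio3d <- function(pdb) {
  a <- pdb$atom
  if (any(!is.na(a$insert) & nzchar(a$insert)))
    stop("insertion codes are not supported; found code '",
         a$insert[which(!is.na(a$insert) & nzchar(a$insert))[1L]],
         "' (renumber the structure before analysis)", call. = FALSE)
  keep <- seq_len(nrow(a))
  alt <- a$alt
  hasAlt <- !is.na(alt) & nzchar(alt)
  if (any(hasAlt)) {
    firstAlt <- alt[hasAlt][1L]
    keep <- which(!hasAlt | alt == firstAlt)
    warning(sprintf(
      "alternate locations present: keeping altLoc '%s', dropping %d atom(s)",
      firstAlt, nrow(a) - length(keep)), call. = FALSE)
  }
  a <- a[keep, , drop = FALSE]
  if (anyNA(a$chain))
    stop("atoms without a chain identifier are not supported", call. = FALSE)
  element <- a$elesy
  noEl <- is.na(element) | !nzchar(trimws(element))
  if (any(noEl)) # fall back to the first letter of the atom name
    element[noEl] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", a$elety[noEl])
  top <- new("Topology", atoms = data.frame(
    chain = as.character(a$chain),
    resid = as.integer(a$resno),
    resname = as.character(a$resid),
    name = as.character(a$elety),
    element = toupper(trimws(element)),
    stringsAsFactors = FALSE))
  validObject(top)
  list(topology = top, keep = keep)
}

#' Read a topology from a PDB file
#'
#' Captures all ATOM and HETATM records (so cofactors such as FMN are
#' retained) of the first model with chain, residue and atom-name identity.
#' Insertion codes are rejected; for alternate locations the first altLoc
#' is kept and the rest dropped with a warning.
#'
#' @param path a PDB file.
#' @return a [Topology-class].
#' @export
readTopology <- function(path) {
  .scanPdb(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  .topologyFromBio3d(pdb)$topology
}

#' Read a multi-model PDB trajectory
#'
#' One frame per MODEL block (a file without MODEL records is a one-frame
#' trajectory, usable as a reference structure). The topology is taken from
#' the first model; a model with a deviating atom count is rejected with an
#' error naming that model.
#'
#' @param path a (multi-model) PDB file.
#' @param frameInterval optional time between frames, picoseconds
#'   (metadata only).
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, frameInterval = NA_real_) {
  info <- .scanPdb(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  tk <- .topologyFromBio3d(pdb)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (length(tk$keep) != nrow(tk$topology@atoms) ||
      ncol(xyz) != 3L * nrow(pdb$atom)) {
    xyz <- xyz[, bio3d::atom2xyz(tk$keep), drop = FALSE]
  }
  n <- nrow(tk$topology@atoms)
  nf <- nrow(xyz)
  cc <- array(NA_real_, dim = c(n, 3L, nf))
  for (f in seq_len(nf))
    cc[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  Trajectory(tk$topology, cc, frameInterval)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Every frame is written as one MODEL/ENDMDL block in standard PDB column
#' layout (coordinates at three decimals, the PDB precision); a round-trip
#' through [readTrajectory()] recovers topology and coordinates exactly at
#' that precision.
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTrajectory <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  a <- trajectory@topology@atoms
  n <- nrow(a)
  nf <- nFrames(trajectory)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3L * n)
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(trajectory@coords[, , f]))
  # standard amino acids as ATOM, anything else (FMN, waters) as HETATM
  type <- ifelse(a$resname %in% bio3d::aa.table$aa3, "ATOM", "HETATM")
  if (nf > 1L) {
    bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz, type = type,
                     resno = a$resid, resid = a$resname, elety = a$name,
                     chain = a$chain, elesy = a$element,
                     eleno = seq_len(n))
  } else {
    # force an explicit MODEL/ENDMDL pair for single-frame files
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    bio3d::write.pdb(pdb = NULL, file = tmp, xyz = xyz, type = type,
                     resno = a$resid, resid = a$resname, elety = a$name,
                     chain = a$chain, elesy = a$element,
                     eleno = seq_len(n), end = FALSE)
    body <- readLines(tmp, warn = FALSE)
    writeLines(c("MODEL        1", body, "ENDMDL", "END"), path)
  }
  invisible(path)
}
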