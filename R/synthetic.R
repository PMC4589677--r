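# Synthetic dimer topologies and trajectories with known ground truth.
#
# The generator emulates the layout of a dimeric short-LOV protein: two
# chains, ideal alpha-helical geometry, probe side chains (Gln-like amide
# with two protons, Lys-like NZ, Glu-like carboxylate), planted correlated
# displacement modes, per-frame hydrogen-bond geometry schedules,
# controllable inter-chain helix orientation, and isotropic Gaussian
# noise. No physics: no force field, integrator, solvent or periodic
# boundaries.

.DECORATIONS <- list(
  gln = data.frame(name = c("NE2", "OE1", "1HE", "2HE"),
                   element = c("N", "O", "H", "H"),
                   r = c(4.5, 4.3, 5.2, 5.2),
                   daz = c(0, 25, -12, 10) * pi / 180,
                   dz = c(0, 0.8, -0.3, 0.5),
                   stringsAsFactors = FALSE),
  lys = data.frame(name = "NZ", element = "N", r = 5.0, daz = 0, dz = 0,
                   stringsAsFactors = FALSE),
  glu = data.frame(name = c("CD", "OE1", "OE2"),
                   element = c("C", "O", "O"),
                   r = c(4.3, 5.0, 5.0),
                   daz = c(0, 15, -15) * pi / 180,
                   dz = c(0, 0.5, -0.5),
                   stringsAsFactors = FALSE))

.DECO_RESNAME <- c(gln = "GLN", lys = "LYS", glu = "GLU")

# ideal alpha-helix parameters: rise per residue (A), twist per residue
.HELIX_RISE <- 1.5
.HELIX_TWIST <- 100 * pi / 180

# intra-residue backbone placement (radius A, azimuth offset, z offset)
.BB_GEOM <- data.frame(name = c("N", "CA", "C", "O"),
                       element = c("N", "C", "C", "O"),
                       r = c(1.46, 2.30, 1.64, 2.00),
                       daz = c(-28, 0, 28, 45) * pi / 180,
                       dz = c(-0.45, 0, 0.45, 0.70),
                       stringsAsFactors = FALSE)

#' Build a synthetic dimer topology
#'
#' Two chains labelled A and B; every residue carries the backbone atoms
#' N, CA, C, O, and decorated residues additionally carry a Gln-like amide
#' (NE2, OE1, 1HE, 2HE), a Lys-like NZ, or a Glu-like carboxylate (CD,
#' OE1, OE2). Atom order is deterministic: chains A then B, residues in
#' index order, backbone before decoration atoms. The same configuration
#' always yields an identical topology.
#'
#' @param chainLengths named integer vector \code{c(A = nA, B = nB)};
#'   lengths must cover every decorated residue index.
#' @param decorations list of \code{list(chain =, resid =, type =)} with
#'   type one of \code{"gln"}, \code{"lys"}, \code{"glu"}; at most one
#'   decoration per residue.
#' @return a [Topology-class].
#' @examples
#' top <- buildDimerTopology(c(A = 20, B = 20))
#' nAtoms(top)   # 160 = 2 chains x 20 residues x 4 backbone atoms
#' @export
buildDimerTopology <- function(chainLengths = c(A = 20L, B = 20L),
                               decorations = list()) {
  if (is.null(names(chainLengths)) || !all(nzchar(names(chainLengths))))
    names(chainLengths) <- LETTERS[seq_along(chainLengths)]
  deco <- list()
  for (d in decorations) {
    if (!all(c("chain", "resid", "type") %in% names(d)))
      stop("each decoration needs chain, resid and type", call. = FALSE)
    if (!d$type %in% names(.DECORATIONS))
      stop("unknown decoration type: ", d$type, call. = FALSE)
    if (!d$chain %in% names(chainLengths))
      stop("decoration names unknown chain: ", d$chain, call. = FALSE)
    if (d$resid < 1L || d$resid > chainLengths[[d$chain]])
      stop(sprintf("decoration %s:%d outside chain length %d",
                   d$chain, d$resid, chainLengths[[d$chain]]),
           call. = FALSE)
    key <- paste(d$chain, d$resid, sep = ":")
    if (!is.null(deco[[key]]))
      stop("overlapping decorations on residue ", key, call. = FALSE)
    deco[[key]] <- d$type
  }
  rows <- list()
  for (ch in names(chainLengths)) {
    for (ri in seq_len(chainLengths[[ch]])) {
      type <- deco[[paste(ch, ri, sep = ":")]]
      resname <- if (is.null(type)) "ALA" else .DECO_RESNAME[[type]]
      geo <- .BB_GEOM[, c("name", "element")]
      if (!is.null(type))
        geo <- rbind(geo, .DECORATIONS[[type]][, c("name", "element")])
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resid = ri, resname = resname,
        name = geo$name, element = geo$element, stringsAsFactors = FALSE)
    }
  }
  top <- new("Topology", atoms = do.call(rbind, rows))
  validObject(top)
  top
}

# Deterministic base coordinates: each chain is one continuous ideal
# alpha-helix along +z (so every helical sub-segment is an ideal helix);
# chain B is offset along +x to form a parallel dimer.
.baseCoordinates <- function(topology, chainOffset = 12) {
  a <- topology@atoms
  chains <- unique(a$chain)
  X <- matrix(NA_real_, nrow(a), 3L)
  geomAll <- rbind(.BB_GEOM,
                   do.call(rbind, unname(.DECORATIONS)))
  for (ci in seq_along(chains)) {
    rows <- which(a$chain == chains[ci])
    resid <- a$resid[rows]
    gi <- match(paste(a$resname[rows], a$name[rows]),
                c(paste("ALA", .BB_GEOM$name),
                  paste("GLN", .BB_GEOM$name),
                  paste("LYS", .BB_GEOM$name),
                  paste("GLU", .BB_GEOM$name),
                  paste("GLN", .DECORATIONS$gln$name),
                  paste("LYS", .DECORATIONS$lys$name),
                  paste("GLU", .DECORATIONS$glu$name)))
    geomTab <- rbind(.BB_GEOM, .BB_GEOM, .BB_GEOM, .BB_GEOM,
                     .DECORATIONS$gln, .DECORATIONS$lys,
                     .DECORATIONS$glu)
    g <- geomTab[gi, , drop = FALSE]
    az <- (resid - 1L) * .HELIX_TWIST + g$daz
    z <- (resid - 1L) * .HELIX_RISE + g$dz
    X[rows, ] <- cbind(g$r * cos(az) + (ci - 1L) * chainOffset,
                       g$r * sin(az), z)
  }
  X
}

.amplitudeSeries <- function(amp, nFrames) {
  type <- amp$type %||% "sinusoid"
  switch(type,
    constant = rep(amp$value %||% 1, nFrames),
    sinusoid = (amp$amplitude %||% 1) *
      sin(2 * pi * seq_len(nFrames) / (amp$period %||% 16) +
            (amp$phase %||% 0)),
    gaussian = stats::rnorm(nFrames, 0, amp$sigma %||% 1),
    stop("unknown amplitude type: ", type, call. = FALSE))
}

# Place hydrogen and acceptor relative to a donor at the origin so that
# |D-A| = dist and the D-H...A angle (at the hydrogen) equals angleDeg,
# with |D-H| = 1.0 A. Returns 3-vectors relative to the donor.
.hbondTemplate <- function(dist, angleDeg) {
  angleAt <- function(beta) {
    H <- c(cos(beta), sin(beta), 0)
    A <- c(dist, 0, 0)
    u <- -H; v <- A - H
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  # angle decreases monotonically from 180 (H on the D-A segment) to 0
  beta <- stats::uniroot(function(b) angleAt(b) - angleDeg,
                         c(1e-9, pi - 1e-9), tol = 1e-12)$root
  list(hydrogen = c(cos(beta), sin(beta), 0),
       acceptor = c(dist, 0, 0))
}

.validateDirections <- function(dir, n) {
  if (is.null(dim(dir))) dir <- matrix(dir, nrow = n, ncol = 3L,
                                       byrow = TRUE)
  if (nrow(dir) != n || ncol(dir) != 3L)
    stop("mode directions must be a 3-vector or an n x 3 matrix",
         call. = FALSE)
  norms <- sqrt(rowSums(dir^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("mode direction vectors must be unit norm", call. = FALSE)
  dir
}

#' Describe the motion content of a synthetic trajectory
#'
#' A \code{MotionSpec} bundles everything [generateTrajectory()] needs:
#' frame count and spacing, planted displacement modes, hydrogen-bond /
#' salt-bridge geometry schedules, an inter-chain helix orientation
#' schedule, isotropic noise, and the seed.
#'
#' @param nFrames number of frames, >= 2.
#' @param frameInterval snapshot spacing, ps (metadata; default 25).
#' @param noiseSigma isotropic Gaussian noise, Angstrom per Cartesian
#'   coordinate, >= 0; applied after all deterministic displacements,
#'   independently per atom and coordinate, from one seeded generator.
#' @param modes list of planted modes, each
#'   \code{list(atoms =, direction =, amplitude =)}: \code{atoms} is a
#'   character vector of atom keys or an [AtomSelection-class];
#'   \code{direction} a unit 3-vector (recycled) or per-atom matrix;
#'   \code{amplitude} one of \code{list(type = "constant", value =)},
#'   \code{list(type = "sinusoid", amplitude =, period =, phase =)},
#'   \code{list(type = "gaussian", sigma =)}. The mode displacement
#'   \code{a(t) * direction} is added to the base coordinates, so two
#'   atoms sharing one mode with equal directions are perfectly
#'   correlated (+1), with opposite directions perfectly anti-correlated
#'   (-1), and with orthogonal directions uncorrelated (0).
#' @param hbondSchedule list of \code{list(spec =, fraction =)} where
#'   \code{spec} is an [hbondSpec()] or [saltBridgeSpec()] and
#'   \code{fraction} (in [0, 1]) is the target share of frames whose
#'   geometry satisfies the default criteria. Realisation is
#'   deterministic: the first \code{round(fraction * nFrames)} frames get
#'   the satisfied template (H-bonds: D-A 2.9 Angstrom, angle 165 deg;
#'   bridges: 4.5 Angstrom), the rest the violated template (3.5 Angstrom
#'   / 120 deg; bridges: 5.5 Angstrom) - comfortably inside/outside the
#'   cutoffs so boundary rounding cannot flip labels.
#' @param helixOrientation \code{NULL}, or \code{list(helixA =, helixB =,
#'   angle =)} with two [helixDefinition()]s and an angle schedule
#'   \code{list(type = "constant", value =)} or \code{list(type =
#'   "gaussian", mean =, sd =)} in degrees: chain B is rigidly rotated
#'   each frame so the two helix axes cross at the scheduled angle.
#' @param seed integer seed; identical (topology, spec, seed) yield
#'   bit-identical trajectories.
#' @return a list with class \code{"MotionSpec"}.
#' @export
motionSpec <- function(nFrames, frameInterval = 25, noiseSigma = 0,
                       modes = list(), hbondSchedule = list(),
                       helixOrientation = NULL, seed = 1L) {
  stopifnot(nFrames >= 2L, noiseSigma >= 0)
  for (s in hbondSchedule) {
    if (is.null(s$spec) || is.null(s$fraction))
      stop("each schedule entry needs spec and fraction", call. = FALSE)
    if (s$fraction < 0 || s$fraction > 1)
      stop("schedule fraction must be in [0, 1]", call. = FALSE)
  }
  for (m in modes) {
    if (is.null(m$atoms) || is.null(m$direction))
      stop("each mode needs atoms and direction", call. = FALSE)
  }
  structure(list(nFrames = as.integer(nFrames),
                 frameInterval = frameInterval, noiseSigma = noiseSigma,
                 modes = modes, hbondSchedule = hbondSchedule,
                 helixOrientation = helixOrientation,
                 seed = as.integer(seed)),
            class = "MotionSpec")
}

.resolveModeAtoms <- function(topology, atoms) {
  if (is(atoms, "AtomSelection")) return(resolveSelection(topology, atoms))
  vapply(atoms, function(k) atomIndex(topology, k), integer(1),
         USE.NAMES = FALSE)
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Builds deterministic base coordinates (each chain one continuous ideal
#' alpha-helix, rise 1.5 Angstrom and 100 degrees per residue, chains
#' side by side), then applies, in order: the helix-orientation rotation
#' of chain B, planted mode displacements, hydrogen-bond/salt-bridge
#' geometry overrides, and finally isotropic Gaussian noise. All
#' randomness comes from one generator seeded with \code{spec$seed}; the
#' caller's RNG state is left untouched.
#'
#' @param topology a [Topology-class], typically from
#'   [buildDimerTopology()].
#' @param spec a [motionSpec()].
#' @return a list with elements \code{trajectory} (a
#'   [Trajectory-class]) and \code{manifest}: the realised ground truth
#'   (scheduled occupancies with exact satisfied-frame counts, analytic
#'   pairwise correlations per mode, realised helix-angle mean/SD, the
#'   closed-form noise RMSF), each entry tagged with its provenance
#'   (\code{constructed} or \code{analytic}).
#' @export
generateTrajectory <- function(topology, spec) {
  stopifnot(is(topology, "Topology"), inherits(spec, "MotionSpec"))
  # seed an isolated RNG stream, restoring the caller's state on exit
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  nf <- spec$nFrames
  base <- .baseCoordinates(topology)
  n <- nrow(base)
  cc <- array(base, dim = c(n, 3L, nf))
  manifest <- list(nFrames = nf, frameInterval = spec$frameInterval,
                   noiseSigma = spec$noiseSigma, seed = spec$seed,
                   files = list(), groundTruth = list())

  # --- inter-chain helix orientation -------------------------------------
  if (!is.null(spec$helixOrientation)) {
    ho <- spec$helixOrientation
    stopifnot(is(ho$helixA, "HelixDefinition"),
              is(ho$helixB, "HelixDefinition"))
    sched <- ho$angle
    theta <- switch(sched$type %||% "constant",
      constant = rep(sched$value, nf),
      gaussian = stats::rnorm(nf, sched$mean, sched$sd),
      stop("unknown angle schedule type: ", sched$type, call. = FALSE))
    theta <- pmin(pmax(theta, 0), 180)
    chainB <- ho$helixB@chain
    rowsB <- which(topology@atoms$chain == chainB)
    pivIdx <- resolveSelection(topology, ho$helixB)
    pivot <- colMeans(base[pivIdx, , drop = FALSE])
    for (f in seq_len(nf)) {
      R <- rotationAboutAxis(c(1, 0, 0), theta[f] * pi / 180)
      shifted <- sweep(base[rowsB, , drop = FALSE], 2L, pivot)
      cc[rowsB, , f] <- sweep(shifted %*% t(R), 2L, pivot, "+")
    }
    manifest$groundTruth$helixAngles <- list(
      schedule = sched, realizedMean = mean(theta),
      realizedSd = stats::sd(theta), provenance = "constructed")
  }

  # --- planted displacement modes ----------------------------------------
  modeTruth <- list()
  for (mi in seq_along(spec$modes)) {
    m <- spec$modes[[mi]]
    idx <- .resolveModeAtoms(topology, m$atoms)
    dir <- .validateDirections(m$direction, length(idx))
    a <- .amplitudeSeries(m$amplitude %||% list(type = "sinusoid"), nf)
    for (k in seq_along(idx))
      cc[idx[k], , ] <- cc[idx[k], , ] + outer(dir[k, ], a)
    # analytic pairwise correlation: dot products of unit directions,
    # exact when atoms share this one mode and noise is zero
    modeTruth[[mi]] <- list(
      atoms = idx, directionDots = tcrossprod(dir),
      provenance = "analytic (single shared mode, zero noise)")
  }
  if (length(modeTruth)) manifest$groundTruth$modes <- modeTruth

  # --- hydrogen-bond / salt-bridge schedules -----------------------------
  hbTruth <- list()
  satHB <- .hbondTemplate(2.9, 165)
  violHB <- .hbondTemplate(3.5, 120)
  for (si in seq_along(spec$hbondSchedule)) {
    s <- spec$hbondSchedule[[si]]
    k <- round(s$fraction * nf)
    sat <- seq_len(nf) <= k
    if (inherits(s$spec, "HBondSpec")) {
      iD <- atomIndex(topology, s$spec$donor)
      iH <- atomIndex(topology, s$spec$hydrogen)
      iA <- atomIndex(topology, s$spec$acceptor)
      for (f in seq_len(nf)) {
        tpl <- if (sat[f]) satHB else violHB
        cc[iH, , f] <- cc[iD, , f] + tpl$hydrogen
        cc[iA, , f] <- cc[iD, , f] + tpl$acceptor
      }
    } else if (inherits(s$spec, "SaltBridgeSpec")) {
      iC <- atomIndex(topology, s$spec$cation)
      iA <- atomIndex(topology, s$spec$anion)
      for (f in seq_len(nf)) {
        d <- if (sat[f]) 4.5 else 5.5
        cc[iA, , f] <- cc[iC, , f] + c(d, 0, 0)
      }
    } else stop("schedule spec must be an HBondSpec or SaltBridgeSpec",
                call. = FALSE)
    hbTruth[[si]] <- list(
      label = s$spec$label, targetFraction = s$fraction,
      satisfiedFrames = k, occupancyPercent = 100 * k / nf,
      provenance = "constructed")
  }
  if (length(hbTruth)) manifest$groundTruth$interactions <- hbTruth

  # --- isotropic noise ----------------------------------------------------
  if (spec$noiseSigma > 0) {
    cc <- cc + array(stats::rnorm(length(cc), 0, spec$noiseSigma),
                     dim = dim(cc))
    manifest$groundTruth$noiseRMSF <- list(
      expected = spec$noiseSigma * sqrt(3),
      provenance = "analytic (isotropic noise, no fitting)")
  }

  list(trajectory = Trajectory(topology, cc, spec$frameInterval),
       manifest = manifest)
}

#' Write a fixture (trajectory + manifest) to disk
#'
#' Writes the trajectory as a multi-model PDB and the ground-truth
#' manifest as a human-readable YAML file, and returns the manifest with
#' the generated file paths recorded.
#'
#' @param generated the list returned by [generateTrajectory()].
#' @param dir output directory (created if needed).
#' @param basename file stem for the two outputs.
#' @return invisibly, the manifest (with \code{files} filled in).
#' @export
writeFixture <- function(generated, dir, basename = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(basename, ".pdb"))
  man <- file.path(dir, paste0(basename, "_manifest.yaml"))
  writeTrajectory(generated$trajectory, pdb)
  manifest <- generated$manifest
  manifest$files <- list(trajectory = pdb, manifest = man)
  yaml::write_yaml(manifest, man)
  invisible(manifest)
}
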