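# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# A bare topology from explicit atom rows (chain, resid, name, element).
makeTopology <- function(chain, resid, name, element = NULL,
                         resname = "ALA") {
  if (is.null(element))
    element <- sub("^[0-9]*([A-Za-z]).*$", "\\1", name)
  new("Topology", atoms = data.frame(
    chain = chain, resid = as.integer(resid),
    resname = rep_len(resname, length(name)),
    name = name, element = element, stringsAsFactors = FALSE))
}

# A trajectory from a list of n x 3 coordinate matrices.
makeTraj <- function(top, frames, frameInterval = NA_real_) {
  cc <- array(NA_real_, dim = c(nrow(atoms(top)), 3L, length(frames)))
  for (f in seq_along(frames)) cc[, , f] <- frames[[f]]
  Trajectory(top, cc, frameInterval)
}

# Standard 2 x 20 residue backbone-only dimer.
dimer20 <- function() buildDimerTopology(c(A = 20L, B = 20L))

# One formatted PDB ATOM/HETATM line (standard columns).
pdbLine <- function(serial, name, resn, chain, resid, x, y, z,
                    alt = " ", icode = " ", record = "ATOM",
                    element = NULL) {
  if (is.null(element)) element <- substr(sub("^[0-9]+", "", name), 1, 1)
  nm <- if (nchar(name) < 4 && !grepl("^[0-9]", name))
    sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resn, chain, resid, icode,
          x, y, z, 1, 0, element)
}

# Rotation about a unit axis (Rodrigues form), independent of the package.
rotationAboutAxisForTest <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# A rotation matrix from three Euler angles (z-y-z convention).
eulerRotation <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# Independent brute-force rigid-fit oracle: coarse grid over Euler angles
# followed by Nelder-Mead refinement; translation handled by centering.
bruteForceFitRMSD <- function(P, Q, gridStep = 20) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rmsdFor <- function(ang) {
    R <- eulerRotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  gs <- gridStep * pi / 180
  best <- NULL; bestVal <- Inf
  for (a in seq(0, 2 * pi - gs / 2, by = gs))
    for (b in seq(0, pi, by = gs))
      for (cc in seq(0, 2 * pi - gs / 2, by = gs)) {
        v <- rmsdFor(c(a, b, cc))
        if (v < bestVal) { bestVal <- v; best <- c(a, b, cc) }
      }
  opt <- stats::optim(best, rmsdFor, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}
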