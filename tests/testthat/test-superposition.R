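test_that("kabschFit recovers identity and rigid motions", {
  set.seed(10)
  X <- matrix(rnorm(30), 10, 3)
  f0 <- kabschFit(X, X)
  expect_equal(f0@rmsd, 0, tolerance = 1e-10)
  expect_equal(f0@rotation, diag(3), tolerance = 1e-9)
  expect_equal(f0@translation, c(0, 0, 0), tolerance = 1e-9)

  # reference rotated 90 deg about z and translated (1,2,3)
  R <- eulerRotation(pi / 2, 0, 0)
  Y <- X %*% t(R) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  f <- kabschFit(X, Y)
  expect_lt(f@rmsd, 1e-6)
  expect_equal(applyFit(X, f), Y, tolerance = 1e-9)
  expect_equal(det(f@rotation), 1, tolerance = 1e-9)
})

test_that("kabschFit rmsd is invariant under rigid motions of the mobile set", {
  set.seed(11)
  X <- matrix(rnorm(24), 8, 3)
  Y <- X + matrix(rnorm(24, sd = 0.3), 8, 3)
  base <- kabschFit(X, Y)@rmsd
  for (k in 1:5) {
    R <- eulerRotation(runif(1, 0, 2 * pi), runif(1, 0, pi),
                       runif(1, 0, 2 * pi))
    Xm <- X %*% t(R) + matrix(runif(3, -5, 5), 8, 3, byrow = TRUE)
    expect_equal(kabschFit(Xm, Y)@rmsd, base, tolerance = 1e-6)
  }
})

test_that("kabschFit matches a brute-force rotation-search oracle", {
  set.seed(12)
  for (k in 1:3) {
    P <- matrix(rnorm(18), 6, 3)
    Q <- matrix(rnorm(18), 6, 3)
    expect_equal(kabschFit(P, Q)@rmsd, bruteForceFitRMSD(P, Q),
                 tolerance = 1e-3)
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(kabschFit(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))   # collinear
  set.seed(1)
  expect_error(kabschFit(line, matrix(rnorm(15), 5, 3)), "collinear")
})

test_that("superposeTrajectory pins fitted atoms and co-transforms the rest", {
  top <- dimer20()
  g <- generateTrajectory(top, motionSpec(nFrames = 4, seed = 1))
  base <- coords(g$trajectory)

  # frames that are rigid motions of frame 1: full-atom fit restores them
  frames <- lapply(1:4, function(f) {
    R <- eulerRotation(0.3 * f, 0.1 * f, 0.2)
    base[, , 1] %*% t(R) + matrix(c(f, -f, 2), nrow(base), 3,
                                  byrow = TRUE)
  })
  tr <- makeTraj(top, frames)
  sup <- superposeTrajectory(tr, reference = frames[[1]])
  for (f in 1:4)
    expect_lt(max(abs(frameCoords(sup, f) - frames[[1]])), 1e-6)

  # fit on chain A only: chain B displacement survives
  idxB <- resolveSelection(top, atomSelection(chains = "B"))
  frames2 <- lapply(1:4, function(f) {
    X <- base[, , 1]
    X[idxB, 1] <- X[idxB, 1] + f        # chain B drifts along x
    X
  })
  tr2 <- makeTraj(top, frames2)
  sup2 <- superposeTrajectory(tr2, atomSelection(chains = "A"),
                              reference = frames2[[1]])
  idxA <- resolveSelection(top, atomSelection(chains = "A"))
  expect_lt(max(abs(frameCoords(sup2, 3)[idxA, ] -
                      frames2[[1]][idxA, ])), 1e-9)
  expect_equal(frameCoords(sup2, 3)[idxB, 1] - frames2[[1]][idxB, 1],
               rep(2, length(idxB)), tolerance = 1e-9)

  # idempotence
  sup3 <- superposeTrajectory(sup, reference = frames[[1]])
  expect_lt(max(abs(coords(sup3) - coords(sup))), 1e-6)
})

test_that("averageStructure is the per-atom mean over frames", {
  top <- buildDimerTopology(c(A = 4L, B = 4L))
  g <- generateTrajectory(top, motionSpec(nFrames = 2, seed = 1))
  X <- frameCoords(g$trajectory, 1)
  d <- matrix(0.5, nrow(X), 3)
  tr <- makeTraj(top, list(X + d, X - d))
  expect_equal(averageStructure(tr), X, tolerance = 1e-12)

  # seeded noisy fixture vs direct mean
  g2 <- generateTrajectory(top, motionSpec(nFrames = 30, noiseSigma = 0.7,
                                           seed = 8))
  direct <- apply(coords(g2$trajectory), c(1, 2), mean)
  expect_equal(averageStructure(g2$trajectory), direct,
               tolerance = 1e-12)
})

test_that("perResidueRMSD localises displacement to the moved residue", {
  top <- dimer20()
  g <- generateTrajectory(top, motionSpec(nFrames = 3, seed = 1))
  X <- frameCoords(g$trajectory, 1)

  # static trajectory: all zeros
  prof0 <- perResidueRMSD(makeTraj(top, list(X, X, X)),
                          atomSelection(chains = "B"))
  expect_lt(max(prof0$value), 1e-9)

  # residue B:7 displaced +1 A along x in every frame, fit on chain A
  idx7 <- resolveSelection(top, atomSelection(chains = "B",
                                              residues = c(7, 7)))
  frames <- lapply(1:3, function(f) { Y <- X; Y[idx7, 1] <- Y[idx7, 1] + 1; Y })
  prof <- perResidueRMSD(makeTraj(top, frames),
                         atomSelection(chains = "B"), reference = X,
                         fitSelection = atomSelection(chains = "A"))
  expect_equal(prof$value[prof$resid == 7], 1, tolerance = 1e-9)
  expect_lt(max(prof$value[prof$resid != 7]), 1e-9)
})

test_that("perResidueRMSD equals a naive double-loop recomputation", {
  top <- buildDimerTopology(c(A = 5L, B = 5L))
  g <- generateTrajectory(top, motionSpec(nFrames = 12, noiseSigma = 0.4,
                                          seed = 21))
  tr <- g$trajectory
  ref <- frameCoords(tr, 1)
  sel <- atomSelection(chains = "B", atoms = "backbone")
  fitSel <- atomSelection(chains = "A", atoms = "backbone")
  prof <- perResidueRMSD(tr, sel, reference = ref, fitSelection = fitSel)

  # oracle: explicit per-frame fit and per-residue accumulation
  fitIdx <- resolveSelection(topology(tr), fitSel)
  mIdx <- resolveSelection(topology(tr), sel)
  a <- atoms(tr)
  for (r in unique(a$resid[mIdx])) {
    ii <- mIdx[a$resid[mIdx] == r]
    ss <- 0
    for (f in seq_len(nFrames(tr))) {
      X <- frameCoords(tr, f)
      ft <- kabschFit(X[fitIdx, ], ref[fitIdx, ])
      Xf <- applyFit(X, ft)
      ss <- ss + sum((Xf[ii, ] - ref[ii, ])^2)
    }
    oracle <- sqrt(ss / (length(ii) * nFrames(tr)))
    expect_equal(prof$value[prof$resid == r], oracle,
                 tolerance = 1e-9)
  }
})

test_that("regionRMSDSummary averages frame-wise RMSD and adds state rows", {
  top <- dimer20()
  g <- generateTrajectory(top, motionSpec(nFrames = 3, seed = 1))
  X <- frameCoords(g$trajectory, 1)
  static <- makeTraj(top, list(X, X, X))
  regions <- list(seg = atomSelection(chains = "B", residues = c(5, 8),
                                      atoms = "backbone"))

  # three static trajectories: all zeros
  s0 <- regionRMSDSummary(list(a = static, b = static, c = static),
                          rep("dark", 3), regions)
  expect_lt(max(s0$rmsd), 1e-9)

  # one trajectory with constant 2 A frame-wise region RMSD
  idx <- resolveSelection(top, regions$seg)
  moved <- lapply(1:3, function(f) { Y <- X; Y[idx, 1] <- Y[idx, 1] + 2; Y })
  tr2 <- makeTraj(top, moved)
  s <- regionRMSDSummary(list(m = tr2, a = static, b = static),
                         rep("dark", 3), regions, fit = "global",
                         globalFitSelection = atomSelection(chains = "A"),
                         references = list(X, X, X))
  expect_equal(s$rmsd[s$label == "m"], 2, tolerance = 1e-9)
  expect_equal(s$rmsd[s$label == "Average"], 2 / 3, tolerance = 1e-9)

  expect_error(regionRMSDSummary(list(static), "dark",
                                 list(atomSelection(chains = "A"))),
               "named list")
})

test_that("region-local fitting matches an independent frame loop", {
  top <- dimer20()
  g <- generateTrajectory(top, motionSpec(nFrames = 8, noiseSigma = 0.5,
                                          seed = 31))
  tr <- g$trajectory
  regions <- lovRegions(core = c(5, 15))["core"]
  s <- regionRMSDSummary(list(x = tr), "dark", regions)

  idx <- resolveSelection(topology(tr), regions$core)
  ref <- frameCoords(tr, 1)
  vals <- vapply(seq_len(nFrames(tr)), function(f) {
    X <- frameCoords(tr, f)[idx, ]
    ft <- kabschFit(X, ref[idx, ])
    sqrt(mean(rowSums((applyFit(X, ft) - ref[idx, ])^2)))
  }, numeric(1))
  expect_equal(s$rmsd[s$label == "x"], mean(vals), tolerance = 1e-9)
})

test_that("rmsf reproduces closed forms and is translation-invariant", {
  top <- buildDimerTopology(c(A = 4L, B = 4L))
  g <- generateTrajectory(top, motionSpec(nFrames = 2, seed = 1))
  X <- frameCoords(g$trajectory, 1)

  expect_error(rmsf(Trajectory(top, X)), "single frame")

  # static: zero everywhere
  expect_true(all(rmsf(makeTraj(top, list(X, X)))$value == 0))

  # two frames at +/- delta along x: RMSF = delta
  d <- matrix(0, nrow(X), 3); d[, 1] <- 0.8
  r <- rmsf(makeTraj(top, list(X + d, X - d)))
  expect_equal(r$value, rep(0.8, nrow(r)), tolerance = 1e-12)

  # global translation of all frames is removed by fitting
  g2 <- generateTrajectory(top, motionSpec(nFrames = 10, noiseSigma = 0.3,
                                           seed = 4))
  r1 <- rmsf(g2$trajectory, fitSelection = atomSelection(atoms = "backbone"))
  shifted <- coords(g2$trajectory) + 5
  r2 <- rmsf(Trajectory(top, shifted),
             fitSelection = atomSelection(atoms = "backbone"))
  expect_equal(r1$value, r2$value, tolerance = 1e-9)
})

test_that("profile differences are signed light minus dark", {
  p <- data.frame(chain = "B", resid = 1:3, value = c(1, 2, 3))
  q <- data.frame(chain = "B", resid = 1:3, value = c(1, 2, 3))
  expect_true(all(rmsdDifferenceProfile(p, q)$value == 0))

  q$value <- c(3, 2, 1)
  d <- rmsdDifferenceProfile(p, q)
  expect_equal(d$value, c(-2, 0, 2))   # negative = larger dark change

  q2 <- data.frame(chain = "B", resid = 2:4, value = 1:3)
  expect_error(rmsdDifferenceProfile(p, q2), "B:1")
})
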