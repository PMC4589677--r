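# A minimal donor/hydrogen/acceptor trajectory with exact geometry per
# frame: D at the origin, A and H placed explicitly.
dhaTraj <- function(frames) {
  top <- makeTopology(chain = rep("A", 3), resid = c(1, 1, 2),
                      name = c("NE2", "2HE", "O4"),
                      element = c("N", "H", "O"))
  makeTraj(top, frames)
}

# place H at the origin with D and A symmetric about it, so the D-H...A
# angle is exactly angleDeg and the D-A distance exactly dist
dhaFrame <- function(dist, angleDeg) {
  half <- angleDeg / 2 * pi / 180
  L <- dist / (2 * sin(half))
  D <- L * c(cos(half), sin(half), 0)
  A <- L * c(cos(-half), sin(-half), 0)
  rbind(D, c(0, 0, 0), A)               # rows: donor, hydrogen, acceptor
}

test_that("distanceSeries gives exact Euclidean distances, symmetrically", {
  f <- rbind(c(0, 0, 0), c(1, 1, 1), c(3, 4, 0))
  tr <- dhaTraj(list(f, f))
  expect_equal(distanceSeries(tr, "A:1:NE2", "A:2:O4"), c(5, 5))  # 3-4-5
  expect_equal(distanceSeries(tr, "A:2:O4", "A:1:NE2"),
               distanceSeries(tr, "A:1:NE2", "A:2:O4"))
  f2 <- rbind(c(1, 2, 3), c(0, 0, 0), c(1, 2, 3))
  expect_equal(distanceSeries(dhaTraj(list(f2)), "A:1:NE2", "A:2:O4"), 0)
  expect_error(distanceSeries(tr, "A:9:XX", "A:2:O4"), "A:9:XX")
})

test_that("distanceSeries matches direct recomputation on a seeded fixture", {
  top <- buildDimerTopology(c(A = 6L, B = 6L))
  g <- generateTrajectory(top, motionSpec(nFrames = 25, noiseSigma = 0.6,
                                          seed = 13))
  tr <- g$trajectory
  d <- distanceSeries(tr, "A:2:CA", "B:5:CA")
  i <- atomIndex(topology(tr), "A:2:CA")
  j <- atomIndex(topology(tr), "B:5:CA")
  direct <- vapply(seq_len(nFrames(tr)), function(f)
    sqrt(sum((frameCoords(tr, f)[i, ] - frameCoords(tr, f)[j, ])^2)),
    numeric(1))
  expect_equal(d, direct, tolerance = 1e-12)
})

test_that("angleSeries computes the D-H...A angle at the hydrogen", {
  # collinear with H between D and A: 180 degrees
  f180 <- rbind(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0))
  expect_equal(angleSeries(dhaTraj(list(f180)),
                           "A:1:NE2", "A:1:2HE", "A:2:O4"), 180)
  # right angle at the hydrogen
  f90 <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 2, 0))
  expect_equal(angleSeries(dhaTraj(list(f90)),
                           "A:1:NE2", "A:1:2HE", "A:2:O4"), 90)
  # constructed 165-degree fixture template
  f165 <- dhaFrame(2.9, 165)
  expect_equal(angleSeries(dhaTraj(list(f165)),
                           "A:1:NE2", "A:1:2HE", "A:2:O4"), 165,
               tolerance = 1e-6)
})

test_that("coincident atoms give NA angles with a warning, not a drop", {
  bad <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  good <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 2, 0))
  tr <- dhaTraj(list(good, bad, good))
  expect_warning(a <- angleSeries(tr, "A:1:NE2", "A:1:2HE", "A:2:O4"),
                 "frame")
  expect_equal(length(a), 3L)
  expect_true(is.na(a[2]))
  expect_equal(a[c(1, 3)], c(90, 90))
})

test_that("H-bond occupancy applies inclusive 3.2 A / 130-180 deg criteria", {
  spec <- hbondSpec("probe", "A:1:NE2", "A:1:2HE", "A:2:O4")

  # constant D-A = 3.30 A at a good angle: excluded by the distance cutoff
  tr330 <- dhaTraj(replicate(4, dhaFrame(3.30, 170), simplify = FALSE))
  expect_equal(hbondOccupancy(tr330, spec)$occupancy, 0)

  # 2.9 A at 129 degrees: excluded; at exactly 130 degrees: included
  tr129 <- dhaTraj(replicate(4, dhaFrame(2.9, 129), simplify = FALSE))
  expect_equal(hbondOccupancy(tr129, spec)$occupancy, 0)
  tr130 <- dhaTraj(replicate(4, dhaFrame(2.9, 130), simplify = FALSE))
  expect_equal(hbondOccupancy(tr130, spec)$occupancy, 100)

  # scheduled 50/100 fixture
  mixed <- dhaTraj(c(replicate(50, dhaFrame(2.9, 165), simplify = FALSE),
                     replicate(50, dhaFrame(3.5, 120), simplify = FALSE)))
  occ <- hbondOccupancy(mixed, spec)
  expect_equal(occ$count, 50L)
  expect_equal(occ$occupancy, 50.0)
  expect_equal(occ$frames, 100L)
})

test_that("the hydrogen of an H-bond spec must be a hydrogen", {
  spec <- hbondSpec("bad", "A:1:NE2", "A:2:O4", "A:1:2HE")
  tr <- dhaTraj(list(dhaFrame(2.9, 165)))
  expect_error(hbondOccupancy(tr, spec), "expected H")
})

test_that("salt-bridge occupancy applies the inclusive 5 A cutoff", {
  top <- makeTopology(chain = c("A", "B"), resid = c(117, 96),
                      name = c("NZ", "CD"), element = c("N", "C"))
  at <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  spec <- saltBridgeSpec("K117A-E96B", "A:117:NZ", "B:96:CD")

  expect_equal(saltBridgeOccupancy(makeTraj(top, list(at(4.9))),
                                   spec)$occupancy, 100)
  expect_equal(saltBridgeOccupancy(makeTraj(top, list(at(5.1))),
                                   spec)$occupancy, 0)

  mixed <- makeTraj(top, c(replicate(30, at(4.5), simplify = FALSE),
                           replicate(70, at(5.5), simplify = FALSE)))
  occ <- saltBridgeOccupancy(mixed, spec)
  expect_equal(occ$count, 30L)
  expect_equal(occ$occupancy, 30.0)
})

test_that("relaxing criteria never decreases occupancy", {
  top <- buildDimerTopology(c(A = 8L, B = 8L),
    decorations = list(list(chain = "A", resid = 4, type = "gln"),
                       list(chain = "B", resid = 4, type = "lys")))
  hb <- hbondSpec("probe", "A:4:NE2", "A:4:2HE", "B:4:NZ")
  g <- generateTrajectory(top, motionSpec(nFrames = 80, noiseSigma = 0.25,
    hbondSchedule = list(list(spec = hb, fraction = 0.5)), seed = 17))
  tr <- g$trajectory
  base <- hbondOccupancy(tr, hb)$occupancy
  looser <- list(
    geometricCriteria(maxDonorAcceptorDistance = 3.6),
    geometricCriteria(angleRange = c(110, 180)),
    geometricCriteria(maxDonorAcceptorDistance = 4.0,
                      angleRange = c(100, 180)))
  for (cr in looser)
    expect_gte(hbondOccupancy(tr, hb, cr)$occupancy, base)
})

test_that("occupancy of concatenated runs is the frame-weighted mean", {
  top <- makeTopology(chain = c("A", "B"), resid = c(1, 1),
                      name = c("NZ", "CD"), element = c("N", "C"))
  at <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  spec <- saltBridgeSpec("sb", "A:1:NZ", "B:1:CD")
  f1 <- c(replicate(8, at(4), simplify = FALSE),
          replicate(2, at(6), simplify = FALSE))   # 80 %
  f2 <- c(replicate(5, at(4), simplify = FALSE),
          replicate(15, at(6), simplify = FALSE))  # 25 %
  o1 <- saltBridgeOccupancy(makeTraj(top, f1), spec)
  o2 <- saltBridgeOccupancy(makeTraj(top, f2), spec)
  oc <- saltBridgeOccupancy(makeTraj(top, c(f1, f2)), spec)
  # exact identity on the underlying counts ...
  expect_equal(oc$count, o1$count + o2$count)
  expect_equal(100 * oc$count / oc$frames,
               (o1$frames * (100 * o1$count / o1$frames) +
                  o2$frames * (100 * o2$count / o2$frames)) /
                 (o1$frames + o2$frames))
  # ... and on the reported percentages up to the 0.1 reporting precision
  expect_lt(abs(oc$occupancy -
                  (10 * o1$occupancy + 20 * o2$occupancy) / 30), 0.05)
})

test_that("skipFrames excludes leading frames from the statistics", {
  top <- makeTopology(chain = c("A", "B"), resid = c(1, 1),
                      name = c("NZ", "CD"), element = c("N", "C"))
  at <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  spec <- saltBridgeSpec("sb", "A:1:NZ", "B:1:CD")
  frames <- c(replicate(5, at(4), simplify = FALSE),
              replicate(5, at(6), simplify = FALSE))
  tr <- makeTraj(top, frames)
  expect_equal(saltBridgeOccupancy(tr, spec, skipFrames = 5)$occupancy, 0)
  expect_equal(saltBridgeOccupancy(tr, spec)$occupancy, 50)
  expect_error(saltBridgeOccupancy(tr, spec, skipFrames = 10), "skipFrames")
})
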