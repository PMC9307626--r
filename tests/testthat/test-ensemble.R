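noAtoms <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))

test_that("grid volume of an unoccluded seeded sphere is analytic", {
  spec <- volumeGridSpec(matrix(0, 1, 3))
  expect_warning(v <- tunnelVolume(noAtoms, spec), "empty atom set")
  expect_equal(v, 4 / 3 * pi * 20^3, tolerance = 0.03)
  # grid refinement: halving the spacing moves the estimate < 1%
  specFine <- volumeGridSpec(matrix(0, 1, 3), gridSpacing = 1.0)
  expect_warning(vf <- tunnelVolume(noAtoms, specFine), "empty")
  expect_lt(abs(vf - v) / vf, 0.01)
})

test_that("volume responds to occlusion monotonically", {
  spec <- volumeGridSpec(matrix(0, 1, 3), sphereRadius = 8,
                         gridSpacing = 2.0)
  # dense atom fill kills the whole region
  g <- expand.grid(x = seq(-9, 9, 2), y = seq(-9, 9, 2), z = seq(-9, 9, 2))
  g$element <- "C"
  expect_equal(tunnelVolume(g, spec), 0)
  # removing any subset of atoms never decreases the volume
  set.seed(5)
  for (i in 1:5) {
    keep <- sample(nrow(g), nrow(g) %/% 2)
    expect_gte(tunnelVolume(g[keep, ], spec), tunnelVolume(g, spec))
    expect_gte(tunnelVolume(g[-keep, ][1:20, ], spec),
               tunnelVolume(g[-keep, ], spec))
  }
})

test_that("volume differences on a shared grid match a brute-force recount", {
  set.seed(8)
  wt <- data.frame(x = rnorm(60, sd = 6), y = rnorm(60, sd = 6),
                   z = rnorm(60, sd = 6), element = "C")
  mutant <- wt[1:45, ]  # a deleted loop: fewer occluding atoms
  spec <- volumeGridSpec(matrix(0, 1, 3), sphereRadius = 10,
                         gridSpacing = 2.0)
  dv <- volumeDifference(mutant, wt, spec)
  expect_gte(dv, 0)

  # independent grid enumeration oracle
  ax <- seq(-20, 20, by = 2)
  grid <- as.matrix(expand.grid(ax, ax, ax))
  inSphere <- sqrt(rowSums(grid^2)) < 10
  countAlive <- function(at) {
    alive <- inSphere
    for (i in seq_len(nrow(at))) {
      d <- sqrt((grid[, 1] - at$x[i])^2 + (grid[, 2] - at$y[i])^2 +
                  (grid[, 3] - at$z[i])^2)
      alive <- alive & d >= (1.7 + 1.09)
    }
    sum(alive) * 8
  }
  expect_equal(dv, countAlive(mutant) - countAlive(wt))
})

test_that("contact frequencies match the all-pairs oracle on a random fixture", {
  ens <- simulateEnsemble(ensembleSpec(nFrames = 20, ncLength = 8,
                                       mobility = rep(0.7, 8), seed = 13))
  for (cutoff in c(4.5, 6)) {
    cm <- contactFrequencies(ens, cutoff = cutoff)
    oracle <- bruteForceContacts(ens, cutoff)
    m <- merge(cm, oracle, by = c("nc_residue", "component"))
    expect_equal(m$frequency.x, m$frequency.y, tolerance = 1e-12)
  }
  # a vanishing cutoff removes every contact
  expect_true(all(contactFrequencies(ens, cutoff = 1e-9)$frequency == 0))
})

test_that("contact bookkeeping respects frames and roles", {
  # hand-built: NC within cutoff of the wall in 3 of 10 frames
  u <- matrix(rep(c(1, 0, 0), 10), ncol = 3, byrow = TRUE)
  ens <- handEnsemble(u)
  ens@coords[4, , ] <- ens@coords[4, , ]  # wall far away
  ens@coords[4, , 1:3] <- c(2, 0, 0)      # close in frames 1-3
  cm <- contactFrequencies(ens, cutoff = 4.5)
  expect_equal(cm$frequency[cm$component == "rRNA:wall"], 30)

  noNc <- ens
  noNc@atoms$role <- "rRNA:wall"
  expect_error(contactFrequencies(noNc), "no nascent-chain")
})

test_that("order parameters evaluate the second-moment tensor", {
  # identical frames: rigid limit
  ensR <- handEnsemble(matrix(rep(c(0.3, -0.5, 0.9), 8), ncol = 3,
                              byrow = TRUE))
  expect_equal(orderParameters(ensR)$s2, 1, tolerance = 1e-9)

  # two orthogonal orientations, equal weight
  ensO <- handEnsemble(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(orderParameters(ensO)$s2, 0.25, tolerance = 1e-12)

  # isotropic orientations approach zero
  set.seed(77)
  u <- matrix(rnorm(3 * 10000), ncol = 3)
  ensI <- handEnsemble(u)
  expect_lt(orderParameters(ensI)$s2, 0.05)
  expect_true(all(orderParameters(ensI)$s2 >= 0))
})

test_that("ensemble statistics are invariant under global rigid motions", {
  ens <- simulateEnsemble(ensembleSpec(nFrames = 8, ncLength = 6,
                                       mobility = rep(0.5, 6), seed = 21))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(11.5, -3.2, 7.7)
  moved <- ens
  for (f in seq_len(nFrames(ens)))
    moved@coords[, , f] <- frameCoords(ens, f) %*% t(R) +
      rep(shift, each = nrow(atomTable(ens)))

  # S2 uses internal vectors: exact invariance
  expect_equal(orderParameters(moved)$s2, orderParameters(ens)$s2,
               tolerance = 1e-9)
  # contacts use pair distances: exact invariance
  expect_equal(contactFrequencies(moved, 6)$frequency,
               contactFrequencies(ens, 6)$frequency)

  # grid volume moves with the frame: exact under translation (the grid is
  # anchored to the seeds), approximate under rotation (axis-aligned grid)
  at <- atomFrame(ens, 1)
  wall <- at[at$role != "NC", ]
  seeds <- frameCoords(ens, 1)[atomTable(ens)$role == "NC" &
                                 atomTable(ens)$name == "CA", ]
  v0 <- tunnelVolume(wall, volumeGridSpec(seeds, sphereRadius = 12))
  wallT <- wall
  wallT[, c("x", "y", "z")] <- wall[, c("x", "y", "z")] +
    rep(shift, each = nrow(wall))
  vT <- tunnelVolume(wallT, volumeGridSpec(seeds + rep(shift, each =
                                                         nrow(seeds)),
                                           sphereRadius = 12))
  expect_equal(vT, v0)
  wallR <- wall
  wallR[, c("x", "y", "z")] <- as.matrix(wall[, c("x", "y", "z")]) %*% t(R)
  vR <- tunnelVolume(wallR, volumeGridSpec(seeds %*% t(R),
                                           sphereRadius = 12))
  expect_equal(vR, v0, tolerance = 0.03)
})

test_that("center-distance mode and vdW tables are honoured", {
  spec <- volumeGridSpec(matrix(0, 1, 3), sphereRadius = 6,
                         gridSpacing = 2, distanceCutoff = 2.5,
                         mode = "center")
  one <- data.frame(x = 0, y = 0, z = 0, element = "C")
  vC <- tunnelVolume(one, spec)
  specV <- volumeGridSpec(matrix(0, 1, 3), sphereRadius = 6,
                          gridSpacing = 2, distanceCutoff = 2.5)
  vV <- tunnelVolume(one, specV)
  # vdW mode excludes a larger ball (radius 1.7 + 2.5 vs plain 2.5)
  expect_lt(vV, vC)
  expect_warning(.rad <- rncfold:::.vdwRadius(c("C", "Xx")), "unknown")
  expect_equal(.rad, c(1.7, 1.7))
})
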