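test_that("Dpw and Dnn match hand enumeration on the toy tree", {
  D <- toyD()
  expect_equal(dpw(c("A", "B"), "C", D), 4)
  expect_equal(dpw(c("A", "B"), c("A", "B"), D), 1)  # self pairs included
  expect_equal(dpw(c("A", "B"), c("A", "B"), D, exclude_shared = TRUE), 2)
  expect_equal(dnn(c("A", "B"), c("A", "B"), D), 0)
  expect_equal(dnn("A", "C", D), 4)
  expect_equal(dnn(c("A", "B"), "C", D), 4)
  # disjoint clades: mean of values >= m is >= m
  expect_gte(dpw(c("A", "B"), "C", D), min(D["A", "C"], D["B", "C"]))
})

test_that("Dpw/Dnn equal enumeration oracles and are symmetric", {
  set.seed(23)
  for (i in 1:200) {
    tr <- ape::rtree(10)
    D <- patristicDistances(tr)
    s1 <- randomAssemblage(tr, kmin = 1, kmax = 6)
    s2 <- randomAssemblage(tr, kmin = 1, kmax = 6)
    expect_equal(dpw(s1, s2, D), oracleDpw(s1, s2, D), tolerance = 1e-12)
    expect_equal(dnn(s1, s2, D), oracleDnn(s1, s2, D), tolerance = 1e-12)
    expect_equal(dpw(s1, s2, D), dpw(s2, s1, D), tolerance = 1e-12)
    expect_equal(dnn(s1, s2, D), dnn(s2, s1, D), tolerance = 1e-12)
  }
})

test_that("Dpw/Dnn agree with picante's comdist and comdistnt", {
  skip_if_not_installed("picante")
  set.seed(29)
  tr <- ape::rtree(20)
  D <- patristicDistances(tr)
  comm <- matrix(rbinom(6 * 20, 1, 0.4), 6, 20,
                 dimnames = list(paste0("P", 1:6), tr$tip.label))
  comm[rowSums(comm) == 0, 1] <- 1
  cd <- as.matrix(picante::comdist(comm, D))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(dpw(comm[i, ], comm[j, ], D), cd[i, j], tolerance = 1e-10)
  }
  # picante pools all nearest-taxon distances into one mean, which coincides
  # with the average of the two directional means when richness is equal
  commEq <- t(vapply(1:6, function(i) {
    out <- numeric(20); out[sample(20, 8)] <- 1; out
  }, numeric(20)))
  dimnames(commEq) <- dimnames(comm)
  cdnt <- as.matrix(picante::comdistnt(commEq, D))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(dnn(commEq[i, ], commEq[j, ], D), cdnt[i, j],
                 tolerance = 1e-10)
  }
})

test_that("beta SES has the documented sign convention and is reproducible", {
  set.seed(37)
  tr <- ape::rtree(20)
  D <- patristicDistances(tr)
  comm <- matrix(rbinom(8 * 20, 1, 0.35) * rpois(160, 2), 8, 20,
                 dimnames = list(paste0("P", 1:8), tr$tip.label))
  comm[rowSums(comm > 0) < 1, 1] <- 1
  b1 <- sesBeta(comm, D, n_null = 99, seed = 6)
  b2 <- sesBeta(comm, D, n_null = 99, seed = 6)
  expect_identical(b1, b2)
  expect_identical(b1$dpw, t(b1$dpw))
  expect_true(all(b1$dpw >= 0) && all(b1$dnn >= 0))
  expect_true(all(diag(b1$dnn) == 0))
  # SES positive exactly when observed exceeds the null mean
  up <- upper.tri(b1$dpw)
  expect_equal(sign(b1$ses_dpw[up]),
               sign(b1$dpw[up] - b1$null_mean$dpw[up]))
  expect_equal(sign(b1$ses_dnn[up]),
               sign(b1$dnn[up] - b1$null_mean$dnn[up]))
})

test_that("neutral beta SES is centred near zero across replicate datasets", {
  # the SES entries of one dataset are strongly correlated (shared tree and
  # plots), so calibration is judged on the mean over replicate datasets
  ms <- vapply(1:5, function(sd) {
    cfg <- scenarioConfig(n_species = 60, n_plots = 30, process = "neutral",
                          mean_richness = 10, seed = sd)
    sc <- simulateScenario(cfg)
    D <- patristicDistances(sc$tree)
    b <- sesBeta(communityMatrix(sc$data), D, n_null = 199,
                 seed = childSeed(sd, "beta"))
    c(mean(b$ses_dpw[upper.tri(b$ses_dpw)], na.rm = TRUE),
      mean(b$ses_dnn[upper.tri(b$ses_dnn)], na.rm = TRUE))
  }, numeric(2))
  expect_lt(abs(mean(ms[1, ])), 0.2)
  expect_lt(abs(mean(ms[2, ])), 0.2)
})

test_that("spatial distances use the 6371 km great circle and elevation differences", {
  env <- data.frame(plot = c("P1", "P2", "P3"),
                    elevation = c(1200, 2200, 1200),
                    latitude = c(36, 37, 36),
                    longitude = c(59, 59, 59))
  sp <- spatialDistances(env)
  expect_equal(sp$geographic["P1", "P3"], 0)
  expect_equal(sp$geographic["P1", "P2"], 111.19, tolerance = 0.005)
  expect_equal(sp$elevation["P1", "P2"], 1000)
  # latitude-only fallback: meridian arc
  sp2 <- spatialDistances(env[, c("plot", "elevation", "latitude")])
  expect_equal(sp2$geographic["P1", "P2"], sp$geographic["P1", "P2"])
  expect_error(spatialDistances(transform(env, latitude = c(36, NA, 36))),
               "P2")
})

test_that("Mantel statistic and permutation test behave on known inputs", {
  set.seed(41)
  X <- as.matrix(dist(matrix(rnorm(40), 20)))
  m <- mantelTest(X, X, n_perm = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_lte(m$p_value, 0.01)

  # hand example: upper triangles (1..6) and their doubling
  Y4 <- X4 <- matrix(0, 4, 4)
  X4[upper.tri(X4)] <- 1:6; X4 <- X4 + t(X4)
  Y4[upper.tri(Y4)] <- 2 * (1:6); Y4 <- Y4 + t(Y4)
  expect_equal(mantelTest(X4, Y4, n_perm = 99, seed = 2)$r, 1)

  # invariant under positive affine transforms of either matrix
  Y <- as.matrix(dist(matrix(rnorm(40), 20)))
  r0 <- mantelTest(X, Y, n_perm = 99, seed = 3)$r
  expect_equal(mantelTest(X, 3 * Y + 7 * (1 - diag(20)), n_perm = 99,
                          seed = 3)$r, r0, tolerance = 1e-12)
  expect_identical(mantelTest(X, Y, n_perm = 199, seed = 9)$p_value,
                   mantelTest(X, Y, n_perm = 199, seed = 9)$p_value)
  expect_error(mantelTest(X, matrix(1, 20, 20) - diag(20) * 0, 99, 1),
               "zero variance")
})

test_that("Mantel r and partial r agree with vegan", {
  skip_if_not_installed("vegan")
  set.seed(43)
  X <- as.matrix(dist(matrix(rnorm(60), 30)))
  Y <- as.matrix(dist(matrix(rnorm(60), 30) + 0.5 * matrix(rnorm(60), 30)))
  Z <- as.matrix(dist(matrix(rnorm(60), 30)))
  expect_equal(mantelTest(X, Y, n_perm = 99, seed = 1)$r,
               unname(vegan::mantel(X, Y, permutations = 5)$statistic),
               tolerance = 1e-10)
  expect_equal(partialMantelTest(X, Y, Z, n_perm = 99, seed = 1)$r,
               unname(vegan::mantel.partial(X, Y, Z, permutations = 5)$statistic),
               tolerance = 1e-10)
})

test_that("partial Mantel collapses to simple r when conditioning is orthogonal", {
  set.seed(47)
  n <- 15
  X <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  Y <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  ut <- upper.tri(X)
  # build a symmetric Z whose unfolded entries are orthogonal to X's and Y's
  z <- residuals(lm(rnorm(sum(ut)) ~ X[ut] + Y[ut]))
  Z <- matrix(0, n, n); Z[ut] <- z; Z <- Z + t(Z)
  rSimple <- mantelTest(X, Y, n_perm = 99, seed = 4)$r
  rPartial <- partialMantelTest(X, Y, Z, n_perm = 99, seed = 4)$r
  expect_equal(rPartial, rSimple, tolerance = 1e-10)

  # association running entirely through the conditioning matrix shrinks
  # towards zero once the conditioning matrix is held constant
  mkSym <- function(v) { M <- matrix(0, n, n); M[ut] <- v; M + t(M) }
  zc <- rnorm(sum(ut))
  Xc <- mkSym(zc + rnorm(sum(ut)))
  Yc <- mkSym(zc + rnorm(sum(ut)))
  Zc <- mkSym(zc)
  rp <- partialMantelTest(Xc, Yc, Zc, n_perm = 99, seed = 5)$r
  expect_lt(abs(rp), 0.25)
  expect_lt(abs(rp), abs(mantelTest(Xc, Yc, n_perm = 99, seed = 5)$r))

  # identical conditioning matrix is rejected as undefined
  expect_error(partialMantelTest(X, Y, Y, n_perm = 99, seed = 1),
               "undefined")
  expect_identical(partialMantelTest(X, Y, Z, 199, seed = 8)$p_value,
                   partialMantelTest(X, Y, Z, 199, seed = 8)$p_value)
})
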