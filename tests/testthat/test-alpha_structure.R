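test_that("MPD and MNTD match hand-enumerated values on the toy tree", {
  D <- toyD()
  expect_equal(mpd(c("A", "B", "C"), D), 10 / 3)
  expect_equal(mpd(c("A", "B"), D), 2)
  expect_equal(mntd(c("A", "B", "C"), D), 8 / 3)
  expect_equal(mntd(c("A", "B"), D), 2)
  expect_true(is.na(mpd("A", D)))
  expect_true(is.na(mntd("A", D)))
  # equal abundances: weighted equals unweighted
  ab <- stats::setNames(c(2, 2, 2), c("A", "B", "C"))
  expect_equal(mpd(ab, D, weighted = TRUE), mpd(ab, D))
  expect_equal(mntd(ab, D, weighted = TRUE), mntd(ab, D))
})

test_that("MPD/MNTD equal pair-enumeration oracles on random communities", {
  set.seed(77)
  for (i in 1:200) {
    tr <- ape::rtree(10)
    D <- patristicDistances(tr)
    sp <- randomAssemblage(tr)
    ab <- stats::setNames(sample(1:5, length(sp), replace = TRUE), sp)
    expect_equal(mpd(sp, D), oracleMPD(sp, D), tolerance = 1e-12)
    expect_equal(mntd(sp, D), oracleMNTD(sp, D), tolerance = 1e-12)
    expect_equal(mpd(ab, D, weighted = TRUE), oracleMPD(sp, D, ab),
                 tolerance = 1e-12)
    expect_equal(mntd(ab, D, weighted = TRUE), oracleMNTD(sp, D, ab),
                 tolerance = 1e-12)
    expect_lte(mntd(sp, D), mpd(sp, D) + 1e-12)  # min <= mean, averaged
  }
})

test_that("MPD/MNTD agree with picante on a random landscape", {
  skip_if_not_installed("picante")
  set.seed(19)
  tr <- ape::rtree(25)
  D <- patristicDistances(tr)
  comm <- matrix(rbinom(10 * 25, 1, 0.4) * rpois(250, 2), 10, 25,
                 dimnames = list(paste0("P", 1:10), tr$tip.label))
  mine <- apply(comm, 1, function(r) mpd(r, D))
  theirs <- picante::mpd(comm, D)
  expect_equal(unname(mine), theirs, tolerance = 1e-10)
  mineN <- apply(comm, 1, function(r) mntd(r, D))
  theirsN <- picante::mntd(comm, D)
  expect_equal(unname(mineN), theirsN, tolerance = 1e-10)
})

test_that("null communities preserve richness and the abundance multiset", {
  set.seed(2)
  comm <- matrix(rbinom(5 * 8, 1, 0.5) * rpois(40, 3), 5, 8,
                 dimnames = list(paste0("P", 1:5), paste0("s", 1:8)))
  comm[1, ] <- c(4, 1, 0, 0, 0, 0, 0, 0)
  pool <- paste0("s", 1:20)
  nulls <- nullCommunities(comm, pool, n_null = 50, seed = 3)
  for (nc in nulls[1:10]) {
    expect_equal(unname(rowSums(nc > 0)), unname(rowSums(comm > 0)))
    for (p in 1:5) {
      expect_equal(sort(nc[p, nc[p, ] > 0]), sort(comm[p, comm[p, ] > 0]),
                   ignore_attr = TRUE)
    }
  }
  expect_identical(nullCommunities(comm, pool, 5, seed = 9),
                   nullCommunities(comm, pool, 5, seed = 9))

  # richness equal to pool size forces the full pool
  commF <- matrix(c(1, 2, 3), 1, 3, dimnames = list("P1", c("a", "b", "c")))
  nf <- nullCommunities(commF, c("a", "b", "c"), n_null = 20, seed = 1)
  for (nc in nf) expect_equal(unname(nc["P1", ] > 0), rep(TRUE, 3))
  expect_error(nullCommunities(commF, c("a", "b"), 5, 1), "pool")
})

test_that("null identity draws are uniform over the pool", {
  comm <- matrix(1, 1, 5, dimnames = list("P1", paste0("s", 1:5)))
  pool <- paste0("s", 1:20)
  nulls <- nullCommunities(comm, pool, n_null = 1000, seed = 4)
  freq <- rowMeans(vapply(nulls, function(nc) nc["P1", ] > 0, logical(20)))
  p <- 5 / 20
  ci <- 3.3 * sqrt(p * (1 - p) / 1000)  # ~99.9% binomial band
  expect_true(all(abs(freq - p) < ci))
})

test_that("SES is zero-centred by construction and invariant to branch rescaling", {
  set.seed(31)
  tr <- ape::rtree(15)
  D <- patristicDistances(tr)
  comm <- matrix(rbinom(6 * 15, 1, 0.4), 6, 15,
                 dimnames = list(paste0("P", 1:6), tr$tip.label))
  comm[rowSums(comm) < 2, 1:2] <- 1
  s1 <- sesAlpha(comm, D, n_null = 199, seed = 5)
  s2 <- sesAlpha(comm, 10 * D, n_null = 199, seed = 5)
  expect_equal(s1$ses, s2$ses, tolerance = 1e-10)
  expect_equal(s1$rank_p, s2$rank_p)

  # observed equal to the null mean gives SES 0 by definition
  fake <- s1[1, ]
  expect_equal((fake$null_mean - fake$null_mean) / fake$null_sd, 0)

  # degenerate null: richness equals pool size, so every draw is identical
  commAll <- matrix(1, 3, 4, dimnames = list(paste0("P", 1:3), tr$tip.label[1:4]))
  sAll <- sesAlpha(commAll, D[1:4, 1:4], n_null = 99, seed = 2)
  expect_true(all(is.na(sAll$ses)))
  expect_true(all(sAll$null_sd == 0))
})

test_that("habitat assemblages add member plots and conserve abundance", {
  comm <- rbind(P1 = c(1, 0), P2 = c(0, 2), P3 = c(5, 5))
  colnames(comm) <- c("a", "b")
  hab <- stats::setNames(c("H1", "H1", "H2"), rownames(comm))
  pooled <- habitatAssemblage(comm, hab)
  expect_equal(pooled["H1", ], c(a = 1, b = 2))
  expect_equal(pooled["H2", ], c(a = 5, b = 5))
  expect_equal(colSums(pooled), colSums(comm))
  # one plot per habitat: identity
  hab1 <- stats::setNames(paste0("H", 1:3), rownames(comm))
  expect_equal(unname(habitatAssemblage(comm, hab1)), unname(comm))
})

test_that("SES gradient regression recovers exact and null relationships", {
  env <- data.frame(plot = paste0("P", 1:10), elevation = 1:10 * 100 + 1200,
                    latitude = rep(36.5, 10))
  ses <- data.frame(unit = env$plot, metric = "mpd",
                    ses = 2 * env$elevation + 1)
  fit <- suppressWarnings(regressSES(ses, env, "elevation"))  # exact fit
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  expect_error(regressSES(ses, env, "latitude"), "zero predictor variance")

  set.seed(9)
  ps <- vapply(1:200, function(i) {
    ses$ses <- rnorm(10)
    regressSES(ses, env, "elevation")$p_value
  }, numeric(1))
  expect_gt(mean(ps <= 0.05), 0.005)
  expect_lt(mean(ps <= 0.05), 0.12)  # roughly uniform p under the null
})
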