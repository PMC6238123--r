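test_that("node impurity is the multivariate within-node sum of squares", {
  expect_equal(nodeImpurity(matrix(c(5, 3), 1)), 0)
  expect_equal(nodeImpurity(rbind(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(nodeImpurity(rbind(c(0, 2), c(2, 0))), 4)
  expect_error(nodeImpurity(matrix(numeric(), 0, 2)), "empty node")

  set.seed(8)
  for (i in 1:200) {
    Y <- matrix(rpois(5 * 20, 2), ncol = 5)
    expect_equal(nodeImpurity(Y), oracleImpurity(Y), tolerance = 1e-12)
  }
})

test_that("best split finds the midpoint of a compositional step change", {
  env <- data.frame(elevation = c(1700, 1750, 1850, 1900))
  Y <- rbind(c(5, 0), c(5, 0), c(0, 5), c(0, 5))
  sp <- bestSplit(Y, env, "elevation", min_leaf = 1)
  expect_equal(sp$var, "elevation")
  expect_equal(sp$threshold, 1800)
  expect_equal(sp$gain, nodeImpurity(Y))  # children are pure

  # constant composition: nothing to explain
  expect_null(bestSplit(matrix(1, 4, 3), env, "elevation", min_leaf = 1))
  # all predictor values tied: no admissible cut
  expect_null(bestSplit(Y, data.frame(elevation = rep(1, 4)), "elevation",
                        min_leaf = 1))
})

test_that("best split equals exhaustive enumeration on random nodes", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(6:20, 1)
    Y <- matrix(rpois(n * 4, 2), n)
    X <- data.frame(elevation = sample(1200:2200, n, replace = TRUE),
                    latitude = round(runif(n, 36, 37), 3))
    got <- bestSplit(Y, X, c("elevation", "latitude"), min_leaf = 2)
    want <- oracleBestSplit(Y, X, c("elevation", "latitude"), min_leaf = 2)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$gain, want$gain, tolerance = 1e-9)
      # gain equals parent impurity minus child impurities at the returned cut
      left <- X[[got$var]] < got$threshold
      expect_equal(got$gain,
                   nodeImpurity(Y) - nodeImpurity(Y[left, , drop = FALSE]) -
                     nodeImpurity(Y[!left, , drop = FALSE]),
                   tolerance = 1e-9)
      expect_gte(got$gain, 0)
    }
  }
})

test_that("univariate special case agrees with rpart's root split", {
  skip_if_not_installed("rpart")
  set.seed(5)
  for (i in 1:10) {
    n <- 40
    x <- runif(n, 1200, 2200)
    y <- ifelse(x < 1600, 2, 6) + rnorm(n)
    sp <- bestSplit(matrix(y, ncol = 1), data.frame(elevation = x),
                    "elevation", min_leaf = 5)
    fit <- rpart::rpart(y ~ x, method = "anova", maxdepth = 1,
                        minbucket = 5, minsplit = 10, cp = 0, xval = 0)
    expect_equal(sp$threshold, unname(fit$splits[1, "index"]))
  }
})

test_that("resubstitution relative error is non-increasing along the pruning path", {
  cfg <- scenarioConfig(n_species = 30, n_plots = 80, process = "filtering",
                        process_strength = 6, habitat_structure = TRUE,
                        mean_richness = 8, seed = 6)
  sc <- simulateScenario(cfg)
  m <- mrtFit(communityMatrix(sc$data), plotEnvironment(sc$data),
              min_leaf = 5, cv_folds = 5, n_cv_reps = 2, seed = 2)
  tab <- m@cvTable[order(m@cvTable$size), ]
  expect_true(all(diff(tab$relerr) <= 1e-9))  # larger size, smaller error
  expect_true(all(diff(tab$alpha) <= 1e-9))   # complexity penalty shrinks with size
  expect_gte(m@rSquared, 0)
  expect_lte(m@rSquared, 1)
  expect_equal(sort(unique(names(habitatAssignments(m)))),
               sort(rownames(communityMatrix(sc$data))))
})

test_that("MRT fits are deterministic given the seed and reject tiny inputs", {
  cfg <- scenarioConfig(n_species = 20, n_plots = 40, process = "filtering",
                        process_strength = 5, habitat_structure = TRUE,
                        mean_richness = 6, seed = 13)
  sc <- simulateScenario(cfg)
  m1 <- mrtFit(communityMatrix(sc$data), plotEnvironment(sc$data),
               cv_folds = 5, n_cv_reps = 2, seed = 31)
  m2 <- mrtFit(communityMatrix(sc$data), plotEnvironment(sc$data),
               cv_folds = 5, n_cv_reps = 2, seed = 31)
  expect_identical(m1@cvTable, m2@cvTable)
  expect_identical(m1@assignments, m2@assignments)

  expect_error(mrtFit(communityMatrix(sc$data)[1:6, ],
                      plotEnvironment(sc$data)[1:6, ], min_leaf = 5),
               "fewer plots")
})

test_that("a structured scenario is recovered and habitats are labelled by elevation", {
  cfg <- scenarioConfig(n_species = 60, n_plots = 160, process = "filtering",
                        process_strength = 8, habitat_structure = TRUE,
                        mean_richness = 10, seed = 1)
  sc <- simulateScenario(cfg)
  m <- mrtFit(communityMatrix(sc$data), plotEnvironment(sc$data),
              min_leaf = 5, cv_folds = 10, n_cv_reps = 3, seed = 1)
  expect_equal(sum(m@frame$leaf), 4L)
  expect_equal(m@frame$var[1], "elevation")  # dominant gradient splits first
  ri <- randIndex(habitatAssignments(m)[names(sc$habitats)], sc$habitats)
  expect_gt(ri, 0.9)
  # predictHabitat reproduces the training assignment
  expect_identical(predictHabitat(m, plotEnvironment(sc$data)),
                   habitatAssignments(m))
  # H1..Hk ordered by leaf-mean elevation
  agg <- tapply(plotEnvironment(sc$data)$elevation,
                habitatAssignments(m)[plotEnvironment(sc$data)$plot], mean)
  expect_lt(unname(agg["H1"]), unname(agg["H3"]))
})
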