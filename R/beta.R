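## Between-assemblage phylogenetic beta diversity (Dpw, Dnn) with SES under
## the same pool-randomization null, spatial distance matrices, and Mantel /
## partial Mantel tests.

#' Mean pairwise phylogenetic distance between two assemblages (Dpw)
#'
#' Mean of the patristic distance over all ordered cross pairs (one species
#' from each assemblage).  Species shared by both assemblages contribute
#' zero self-distances by default (the comdist convention);
#' \code{exclude_shared} drops those pairs.  The weighted variant weights
#' pairs by the product of relative abundances.
#'
#' @param c1,c2 named abundance vectors or character vectors of species.
#' @param D patristic distance matrix.
#' @param weighted logical, relative-abundance-product weighting.
#' @param exclude_shared logical, drop same-species (zero) pairs.
#' @return numeric; \code{NA} if either assemblage is empty.
#' @export
dpw <- function(c1, c2, D, weighted = FALSE, exclude_shared = FALSE) {
  a1 <- asAbundance(c1, D); a2 <- asAbundance(c2, D)
  s1 <- names(a1)[a1 > 0]; s2 <- names(a2)[a2 > 0]
  if (!length(s1) || !length(s2)) return(NA_real_)
  d <- D[s1, s2, drop = FALSE]
  w <- if (weighted) outer(a1[s1] / sum(a1[s1]), a2[s2] / sum(a2[s2])) else
    matrix(1, length(s1), length(s2))
  if (exclude_shared) {
    shared <- outer(s1, s2, "==")
    w[shared] <- 0
    if (sum(w) == 0) return(NA_real_)
  }
  sum(w * d) / sum(w)
}

#' Mean nearest neighbour phylogenetic distance between two assemblages (Dnn)
#'
#' For every species of one assemblage, the minimum distance into the other;
#' the two directional means are averaged (a symmetric statistic).  The
#' weighted variant weights each species' nearest-neighbour distance by its
#' relative abundance within its own assemblage.
#'
#' @inheritParams dpw
#' @return numeric; \code{NA} if either assemblage is empty.
#' @export
dnn <- function(c1, c2, D, weighted = FALSE) {
  a1 <- asAbundance(c1, D); a2 <- asAbundance(c2, D)
  s1 <- names(a1)[a1 > 0]; s2 <- names(a2)[a2 > 0]
  if (!length(s1) || !length(s2)) return(NA_real_)
  d <- D[s1, s2, drop = FALSE]
  m1 <- apply(d, 1L, min)
  m2 <- apply(d, 2L, min)
  if (!weighted) {
    (mean(m1) + mean(m2)) / 2
  } else {
    w1 <- a1[s1] / sum(a1[s1]); w2 <- a2[s2] / sum(a2[s2])
    (sum(m1 * w1) + sum(m2 * w2)) / 2
  }
}

#' Phylogenetic beta diversity matrices with standardized effect sizes
#'
#' Computes the pairwise Dpw and Dnn matrices over all units (plots or
#' habitats) and their standardized effect sizes under the same
#' richness-preserving pool-randomization null as [sesAlpha()], applied
#' jointly to all units per randomization; the same draws serve both
#' metrics.  Positive SES means the observed dissimilarity exceeds the null
#' expectation.
#'
#' @param comm units x species abundance matrix.
#' @param D patristic distance matrix over the pool (rows of \code{D} define
#'   the pool).
#' @param metric one or both of \code{"dpw"}, \code{"dnn"}.
#' @param n_null number of null randomizations.
#' @param seed integer seed.
#' @param weighted logical, abundance weighting.
#' @return list of class \code{BetaMatrices} with elements \code{units},
#'   \code{dpw}, \code{dnn}, \code{ses_dpw}, \code{ses_dnn} (symmetric
#'   matrices; absent metrics NULL), \code{null_mean} / \code{null_sd}
#'   (per-metric matrices of null moments) and \code{n_null}.  Pairs with a
#'   degenerate null sd get \code{NA} SES.
#' @export
sesBeta <- function(comm, D, metric = c("dpw", "dnn"), n_null = 999L,
                    seed = 1L, weighted = FALSE) {
  metric <- match.arg(metric, several.ok = TRUE)
  stopIfNot2(n_null >= 99, "n_null must be >= 99")
  pool <- rownames(D)
  stopIfNot2(all(colnames(comm) %in% pool), "comm species missing from D")
  n <- nrow(comm)
  units <- rownames(comm)
  colIdx <- match(colnames(comm), pool)
  idsList <- lapply(seq_len(n), function(p) colIdx[comm[p, ] > 0])
  abList <- lapply(seq_len(n), function(p) comm[p, comm[p, ] > 0])
  kVec <- lengths(idsList)
  stopIfNot2(all(kVec >= 1L), "every unit must contain at least one species")
  poolN <- length(pool)

  pairStat <- function(ids, abs_) {
    dpwM <- dnnM <- matrix(0, n, n, dimnames = list(units, units))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- D[ids[[i]], ids[[j]], drop = FALSE]
      if ("dpw" %in% metric) {
        if (!weighted) {
          v <- mean(d)
        } else {
          w <- outer(abs_[[i]] / sum(abs_[[i]]), abs_[[j]] / sum(abs_[[j]]))
          v <- sum(w * d)
        }
        dpwM[i, j] <- dpwM[j, i] <- v
      }
      if ("dnn" %in% metric) {
        m1 <- if (nrow(d) == 1L) min(d) else apply(d, 1L, min)
        m2 <- if (ncol(d) == 1L) min(d) else apply(d, 2L, min)
        v <- if (!weighted) (mean(m1) + mean(m2)) / 2 else
          (sum(m1 * abs_[[i]] / sum(abs_[[i]])) +
           sum(m2 * abs_[[j]] / sum(abs_[[j]]))) / 2
        dnnM[i, j] <- dnnM[j, i] <- v
      }
    }
    list(dpw = dpwM, dnn = dnnM)
  }

  obs <- pairStat(idsList, abList)
  acc <- list(dpw = list(s = 0, s2 = 0), dnn = list(s = 0, s2 = 0))
  withSeed(seed, {
    for (it in seq_len(n_null)) {
      nullIds <- lapply(kVec, function(k) sample.int(poolN, k))
      nullAb <- if (weighted) lapply(abList, sample) else abList
      st <- pairStat(nullIds, nullAb)
      for (m in metric) {
        acc[[m]]$s <- acc[[m]]$s + st[[m]]
        acc[[m]]$s2 <- acc[[m]]$s2 + st[[m]]^2
      }
    }
  })
  out <- list(units = units, dpw = NULL, dnn = NULL,
              ses_dpw = NULL, ses_dnn = NULL,
              null_mean = list(), null_sd = list(), n_null = n_null)
  for (m in metric) {
    mu <- acc[[m]]$s / n_null
    sdv <- sqrt(pmax(acc[[m]]$s2 / n_null - mu^2, 0) * n_null / (n_null - 1))
    ses <- (obs[[m]] - mu) / sdv
    ses[sdv == 0] <- NA_real_
    diag(ses) <- 0
    out[[m]] <- obs[[m]]
    out[[paste0("ses_", m)]] <- ses
    out$null_mean[[m]] <- mu
    out$null_sd[[m]] <- sdv
  }
  class(out) <- "BetaMatrices"
  out
}

#' @export
print.BetaMatrices <- function(x, ...) {
  cat("BetaMatrices:", length(x$units), "units, n_null =", x$n_null, "\n")
  for (m in c("dpw", "dnn")) if (!is.null(x[[m]])) {
    cat(" ", m, ": mean off-diagonal", signif(mean(upperTriangle(x[[m]])), 4),
        "; mean SES", signif(mean(upperTriangle(x[[paste0("ses_", m)]]),
                                  na.rm = TRUE), 4), "\n")
  }
  invisible(x)
}

#' Geographic and elevation distance matrices between plots
#'
#' Geographic distances are great-circle (haversine, Earth radius 6,371 km)
#' from latitude/longitude in decimal degrees; when longitude is absent the
#' meridian arc from latitude alone is used.  Elevation distance is the
#' absolute difference in metres.
#'
#' @param env plot environment data.frame (\code{plot}, \code{elevation},
#'   \code{latitude}, optional \code{longitude}).
#' @return list with \code{geographic} (km) and \code{elevation} (m)
#'   symmetric matrices labelled by plot.
#' @export
spatialDistances <- function(env) {
  stopIfNot2(all(c("plot", "elevation", "latitude") %in% names(env)),
             "environment table needs plot, elevation, latitude")
  bad <- !is.finite(env$latitude) | !is.finite(env$elevation)
  if (!is.null(env$longitude)) bad <- bad | !is.finite(env$longitude)
  if (any(bad)) stop("missing coordinates for plot(s): ",
                     paste(env$plot[bad], collapse = ", "), call. = FALSE)
  lon <- if (!is.null(env$longitude)) env$longitude else rep(0, nrow(env))
  geo <- geosphere::distm(cbind(lon, env$latitude),
                          fun = function(a, b)
                            geosphere::distHaversine(a, b, r = 6371000)) / 1000
  elev <- abs(outer(env$elevation, env$elevation, "-"))
  dimnames(geo) <- dimnames(elev) <- list(env$plot, env$plot)
  list(geographic = geo, elevation = elev)
}

checkSquare <- function(m, n = NULL) {
  stopIfNot2(is.matrix(m) && nrow(m) == ncol(m), "matrices must be square")
  if (!is.null(n)) stopIfNot2(nrow(m) == n, "matrices must be conformable")
  nrow(m)
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation of the upper-triangle entries of two distance
#' matrices, with significance from simultaneously permuting the rows and
#' columns of \code{Y}.  One-sided ("greater") by default, matching
#' distance-decay hypotheses; \code{p = (1 + #\{r_perm >= r_obs\}) /
#' (n_perm + 1)}.
#'
#' @param X,Y square symmetric matrices over the same units in the same
#'   order.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @return list of class \code{MantelResult}: \code{kind}, \code{r},
#'   \code{p_value}, \code{n_perm}, \code{n_units}, \code{alternative}.
#' @export
mantelTest <- function(X, Y, n_perm = 999L, seed = 1L,
                       alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- checkSquare(X); checkSquare(Y, n)
  stopIfNot2(n >= 4L, "need >= 4 units")
  ut <- upper.tri(X)
  x <- X[ut]
  stopIfNot2(stats::var(x) > 0 && stats::var(Y[ut]) > 0,
             "zero variance in a distance matrix")
  r <- stats::cor(x, Y[ut])
  rPerm <- withSeed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(x, Y[p, p][ut])
  }, numeric(1)))
  p <- switch(alternative,
    greater = permPvalGreater(r, rPerm),
    less = permPvalGreater(-r, -rPerm),
    two.sided = min(1, 2 * min(permPvalGreater(r, rPerm),
                               permPvalGreater(-r, -rPerm))))
  structure(list(kind = "simple", r = r, p_value = p, n_perm = n_perm,
                 n_units = n, alternative = alternative),
            class = "MantelResult")
}

#' Partial Mantel test
#'
#' First-order partial correlation of \code{X} and \code{Y} given \code{Z}
#' on the unfolded upper triangles,
#' \code{r_XY.Z = (r_XY - r_XZ r_YZ) / sqrt((1 - r_XZ^2)(1 - r_YZ^2))},
#' with significance from permuting the rows and columns of \code{X} and
#' recomputing the partial statistic.
#'
#' @inheritParams mantelTest
#' @param Z conditioning matrix.
#' @return a \code{MantelResult} (kind \code{"partial"}).
#' @export
partialMantelTest <- function(X, Y, Z, n_perm = 999L, seed = 1L,
                              alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- checkSquare(X); checkSquare(Y, n); checkSquare(Z, n)
  stopIfNot2(n >= 4L, "need >= 4 units")
  ut <- upper.tri(X)
  x <- X[ut]; y <- Y[ut]; z <- Z[ut]
  rXY <- stats::cor(x, y); rXZ <- stats::cor(x, z); rYZ <- stats::cor(y, z)
  if (abs(rXZ) >= 1 - 1e-12 || abs(rYZ) >= 1 - 1e-12) {
    stop("partial correlation undefined: conditioning correlation is +/- 1",
         call. = FALSE)
  }
  partial <- function(rxy, rxz, ryz) {
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  r <- partial(rXY, rXZ, rYZ)
  rPerm <- withSeed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    xp <- X[p, p][ut]
    partial(stats::cor(xp, y), stats::cor(xp, z), rYZ)
  }, numeric(1)))
  p <- switch(alternative,
    greater = permPvalGreater(r, rPerm),
    less = permPvalGreater(-r, -rPerm),
    two.sided = min(1, 2 * min(permPvalGreater(r, rPerm),
                               permPvalGreater(-r, -rPerm))))
  structure(list(kind = "partial", r = r, p_value = p, n_perm = n_perm,
                 n_units = n, alternative = alternative),
            class = "MantelResult")
}

#' @export
print.MantelResult <- function(x, ...) {
  cat(sprintf("%s Mantel test: r = %.4f, p = %.4g (%s, %d permutations, %d units)\n",
              x$kind, x$r, x$p_value, x$alternative, x$n_perm, x$n_units))
  invisible(x)
}
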