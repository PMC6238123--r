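## Within-assemblage phylogenetic structure: MPD, MNTD, the pool-randomization
## null model, standardized effect sizes, and SES ~ gradient regressions.

#' Mean pairwise phylogenetic distance of one assemblage
#'
#' Mean of the patristic distance over all unordered pairs of distinct species
#' present in the assemblage ("basal" phylogenetic structure).  The weighted
#' variant weights each pair by the product of the two species' abundances.
#'
#' @param x named abundance (or presence) vector, or a character vector of
#'   species names.
#' @param D patristic distance matrix with species labels.
#' @param weighted logical, abundance weighting.
#' @return numeric; \code{NA} for assemblages with fewer than two species.
#' @export
mpd <- function(x, D, weighted = FALSE) {
  ab <- asAbundance(x, D)
  sp <- names(ab)[ab > 0]
  if (length(sp) < 2L) return(NA_real_)
  d <- D[sp, sp, drop = FALSE]
  if (!weighted) {
    mean(d[upper.tri(d)])
  } else {
    w <- ab[sp]
    wm <- outer(w, w)
    sum(wm[upper.tri(wm)] * d[upper.tri(d)]) / sum(wm[upper.tri(wm)])
  }
}

#' Mean nearest taxon phylogenetic distance of one assemblage
#'
#' Mean over the species present of the distance to their nearest co-occurring
#' relative ("terminal" phylogenetic structure); abundance-weighted mean when
#' \code{weighted}.
#'
#' @inheritParams mpd
#' @return numeric; \code{NA} for assemblages with fewer than two species.
#' @export
mntd <- function(x, D, weighted = FALSE) {
  ab <- asAbundance(x, D)
  sp <- names(ab)[ab > 0]
  if (length(sp) < 2L) return(NA_real_)
  d <- D[sp, sp, drop = FALSE]
  diag(d) <- Inf
  nt <- apply(d, 1L, min)
  if (!weighted) mean(nt) else sum(nt * ab[sp]) / sum(ab[sp])
}

asAbundance <- function(x, D) {
  if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
  stopIfNot2(!is.null(names(x)), "assemblage must be named or a character vector")
  stopIfNot2(all(names(x)[x > 0] %in% rownames(D)),
             "assemblage contains species missing from the distance matrix")
  x
}

#' Richness-preserving pool-randomization null communities
#'
#' Random communities are generated by maintaining each plot's species
#' richness and its multiset of abundance values, while the species
#' identities are drawn uniformly without replacement from the whole species
#' pool; plots are randomized independently.
#'
#' @param comm plots x species abundance matrix (columns are the observed
#'   species; the pool may be wider).
#' @param pool character vector of pool species (superset of the occupied
#'   columns of \code{comm}).
#' @param n_null number of randomizations (>= 1).
#' @param seed integer seed.
#' @return list of \code{n_null} plots x pool abundance matrices.
#' @export
nullCommunities <- function(comm, pool = colnames(comm), n_null = 99L, seed = 1L) {
  occupied <- colnames(comm)[colSums(comm > 0) > 0]
  stopIfNot2(all(occupied %in% pool), "pool must contain every observed species")
  rich <- rowSums(comm > 0)
  stopIfNot2(max(rich) <= length(pool), "plot richness exceeds pool size")
  withSeed(seed, lapply(seq_len(n_null), function(i) {
    m <- matrix(0, nrow(comm), length(pool),
                dimnames = list(rownames(comm), pool))
    for (p in seq_len(nrow(comm))) {
      ab <- comm[p, comm[p, ] > 0]
      m[p, sample(length(pool), length(ab))] <- sample(ab)
    }
    m
  }))
}

#' Standardized effect sizes of MPD / MNTD per plot
#'
#' Compares each plot's observed MPD and/or MNTD with the null distribution
#' under the richness-preserving pool-randomization null
#' ([nullCommunities()]; the identical draws serve both metrics).
#' \code{ses = (observed - null mean) / null sd}; positive values indicate
#' phylogenetic overdispersion, negative values clustering.  \code{rank_p} is
#' the two-sided permutation quantile with the add-one correction.
#'
#' @param comm plots x species abundance matrix.
#' @param D patristic distance matrix over the pool.
#' @param metric one or both of \code{"mpd"}, \code{"mntd"}.
#' @param n_null number of null randomizations (default 999).
#' @param seed integer seed.
#' @param weighted logical, abundance-weighted metrics.
#' @param null_model \code{"pool"} (default: identities re-drawn from the
#'   pool) or \code{"labels"} (shuffle the species labels of \code{D}).
#' @return data.frame with columns \code{unit}, \code{metric},
#'   \code{observed}, \code{null_mean}, \code{null_sd}, \code{ses},
#'   \code{rank_p}, \code{n_null}.  Plots with fewer than two species, or a
#'   degenerate null (sd = 0), get \code{NA} ses.
#' @export
sesAlpha <- function(comm, D, metric = c("mpd", "mntd"), n_null = 999L,
                     seed = 1L, weighted = FALSE, null_model = c("pool", "labels")) {
  metric <- match.arg(metric, several.ok = TRUE)
  null_model <- match.arg(null_model)
  stopIfNot2(n_null >= 99, "n_null must be >= 99")
  pool <- rownames(D)
  stopIfNot2(all(colnames(comm) %in% pool), "comm species missing from D")
  nP <- nrow(comm)
  poolN <- length(pool)
  Didx <- D  # numeric indexing is much faster than name lookup
  colIdx <- match(colnames(comm), pool)

  metricFun <- function(ids, ab) {
    d <- Didx[ids, ids, drop = FALSE]
    out <- c(mpd = NA_real_, mntd = NA_real_)
    if ("mpd" %in% metric) {
      ut <- d[upper.tri(d)]
      if (!weighted) out["mpd"] <- mean(ut) else {
        wm <- outer(ab, ab)[upper.tri(d)]
        out["mpd"] <- sum(wm * ut) / sum(wm)
      }
    }
    if ("mntd" %in% metric) {
      diag(d) <- Inf
      nt <- apply(d, 1L, min)
      out["mntd"] <- if (!weighted) mean(nt) else sum(nt * ab) / sum(ab)
    }
    out
  }

  res <- vector("list", nP)
  withSeed(seed, {
    for (p in seq_len(nP)) {
      pres <- comm[p, ] > 0
      ab <- comm[p, pres]
      ids <- colIdx[pres]
      k <- length(ids)
      if (k < 2L) {
        res[[p]] <- lapply(metric, function(m)
          data.frame(unit = rownames(comm)[p], metric = m, observed = NA_real_,
                     null_mean = NA_real_, null_sd = NA_real_, ses = NA_real_,
                     rank_p = NA_real_, n_null = n_null))
        next
      }
      obs <- metricFun(ids, ab)
      nulls <- matrix(NA_real_, n_null, 2L,
                      dimnames = list(NULL, c("mpd", "mntd")))
      for (i in seq_len(n_null)) {
        nullIds <- if (null_model == "pool") sample.int(poolN, k) else
          sample.int(poolN)[ids]  # shuffle tip labels across the pool
        nullAb <- if (weighted) sample(ab) else ab
        nulls[i, ] <- metricFun(nullIds, nullAb)
      }
      res[[p]] <- lapply(metric, function(m) {
        nm <- mean(nulls[, m]); nsd <- stats::sd(nulls[, m])
        data.frame(unit = rownames(comm)[p], metric = m, observed = obs[[m]],
                   null_mean = nm, null_sd = nsd,
                   ses = if (nsd > 0) (obs[[m]] - nm) / nsd else NA_real_,
                   rank_p = permPvalTwoSided(obs[[m]], nulls[, m]),
                   n_null = n_null)
      })
    }
  })
  out <- do.call(rbind, unlist(res, recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' Pool plot rows into habitat-level assemblages
#'
#' Habitat row = element-wise sum of the abundance rows of its member plots;
#' total abundance is conserved.
#'
#' @param comm plots x species abundance matrix.
#' @param habitats named character vector (or factor), plot -> habitat label.
#' @return habitats x species abundance matrix.
#' @export
habitatAssemblage <- function(comm, habitats) {
  stopIfNot2(all(rownames(comm) %in% names(habitats)),
             "every plot needs a habitat label")
  g <- as.character(habitats[rownames(comm)])
  rowsum(comm, group = g, reorder = TRUE)
}

#' Ordinary least squares of SES on an environmental gradient
#'
#' @param ses data.frame as returned by [sesAlpha()] (one metric).
#' @param env plot environment table.
#' @param predictor name of the environment column (e.g. \code{"elevation"}).
#' @return data.frame row with \code{response}, \code{predictor},
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{p_value},
#'   \code{n}.
#' @export
regressSES <- function(ses, env, predictor) {
  stopIfNot2(predictor %in% names(env), "predictor not in environment table")
  stopIfNot2(length(unique(ses$metric)) == 1L, "one metric at a time")
  x <- env[[predictor]][match(ses$unit, env$plot)]
  keep <- is.finite(ses$ses) & is.finite(x)
  stopIfNot2(sum(keep) >= 3L, "need >= 3 non-missing points")
  x <- x[keep]; y <- ses$ses[keep]
  stopIfNot2(stats::var(x) > 0, "zero predictor variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(
    response = paste0("ses_", ses$metric[1L]), predictor = predictor,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2L, 4L],
    n = sum(keep)
  )
}
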