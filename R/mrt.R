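## Multivariate regression tree on community composition (CART with the
## sums-of-squares-about-the-multivariate-mean impurity), cost-complexity
## pruning, and minimum-CVRE model selection by repeated k-fold
## cross-validation.

#' Multivariate node impurity
#'
#' Sum over the plots of a node of the squared deviations of every species'
#' abundance from the node mean of that species — the CART extension's
#' within-node sum of squares about the multivariate mean.
#'
#' @param comm_rows abundance sub-matrix (plots of one node x species).
#' @return non-negative numeric.
#' @export
nodeImpurity <- function(comm_rows) {
  comm_rows <- as.matrix(comm_rows)
  stopIfNot2(nrow(comm_rows) >= 1L, "empty node")
  sum(sweep(comm_rows, 2L, colMeans(comm_rows))^2)
}

#' Best single-variable threshold split of a node
#'
#' Exhaustive search over the predictors and all candidate thresholds (the
#' midpoints between consecutive sorted unique predictor values), maximizing
#' the impurity reduction under a minimum-leaf-size constraint.  Ties are
#' broken by predictor order as supplied, then by the smaller threshold.
#'
#' @param comm_rows abundance sub-matrix of the node.
#' @param env_rows matching environment rows (data.frame).
#' @param predictors character, numeric predictor columns.
#' @param min_leaf minimum plots per child.
#' @return list with \code{var}, \code{threshold} and \code{gain}, or
#'   \code{NULL} when no admissible split exists (e.g. all predictor values
#'   tied or no impurity to explain).
#' @export
bestSplit <- function(comm_rows, env_rows, predictors, min_leaf = 5L) {
  Y <- as.matrix(comm_rows)
  n <- nrow(Y)
  stopIfNot2(n >= 2L * min_leaf, "node smaller than 2 * min_leaf")
  stopIfNot2(all(predictors %in% names(env_rows)), "unknown predictor")
  best <- NULL
  tol <- 1e-12
  for (v in predictors) {
    x <- env_rows[[v]]
    ord <- order(x)
    xs <- x[ord]
    Yo <- Y[ord, , drop = FALSE]
    cumY <- apply(Yo, 2L, cumsum)
    if (is.null(dim(cumY))) cumY <- matrix(cumY, nrow = n)
    cumY2 <- cumsum(rowSums(Yo^2))
    totY <- cumY[n, ]
    totY2 <- cumY2[n]
    parentSS <- totY2 - sum(totY^2) / n
    ks <- which(diff(xs) > 0)
    ks <- ks[ks >= min_leaf & (n - ks) >= min_leaf]
    if (!length(ks)) next
    rsL <- rowSums(cumY^2)[ks]
    rsR <- rowSums(sweep(-cumY[ks, , drop = FALSE], 2L, totY, "+")^2)
    ssL <- cumY2[ks] - rsL / ks
    ssR <- (totY2 - cumY2[ks]) - rsR / (n - ks)
    gain <- parentSS - ssL - ssR
    kBest <- which.max(gain)  # ascending thresholds: first strict max wins
    if (gain[kBest] > tol && (is.null(best) || gain[kBest] > best$gain + tol)) {
      k <- ks[kBest]
      best <- list(var = v, threshold = (xs[k] + xs[k + 1L]) / 2,
                   gain = gain[kBest])
    }
  }
  best
}

## --- internal tree machinery ------------------------------------------------

# Grow a maximal tree.  Returns a data.frame with one row per node:
# node, parent, left, right, var, threshold, n, ss, and a list of row indices.
growTree <- function(Y, X, predictors, min_leaf) {
  nodes <- new.env(parent = emptyenv())
  nodes$frame <- list()
  nodes$rows <- list()
  nodes$counter <- 0L
  grow <- function(rows, parent) {
    nodes$counter <- nodes$counter + 1L
    id <- nodes$counter
    ss <- nodeImpurity(Y[rows, , drop = FALSE])
    rec <- list(node = id, parent = parent, left = NA_integer_,
                right = NA_integer_, var = NA_character_,
                threshold = NA_real_, n = length(rows), ss = ss)
    nodes$frame[[id]] <- rec
    nodes$rows[[id]] <- rows
    if (length(rows) >= 2L * min_leaf && ss > 1e-12) {
      sp <- bestSplit(Y[rows, , drop = FALSE],
                      X[rows, , drop = FALSE], predictors, min_leaf)
      if (!is.null(sp)) {
        goLeft <- X[rows, sp$var] < sp$threshold
        lid <- grow(rows[goLeft], id)
        rid <- grow(rows[!goLeft], id)
        rec$left <- lid; rec$right <- rid
        rec$var <- sp$var; rec$threshold <- sp$threshold
        nodes$frame[[id]] <- rec
      }
    }
    id
  }
  grow(seq_len(nrow(Y)), NA_integer_)
  frame <- do.call(rbind, lapply(nodes$frame, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  list(frame = frame, rows = nodes$rows)
}

# Leaf statistics of a (possibly pruned) tree.  `pruned` is an integer set of
# internal nodes treated as leaves.  Returns per node: R (sum of leaf ss in
# the subtree) and nLeaves, honouring the pruning.
subtreeStats <- function(frame, pruned) {
  nN <- nrow(frame)
  left <- frame$left; right <- frame$right; ss <- frame$ss
  prunedMask <- logical(nN); prunedMask[pruned] <- TRUE
  R <- numeric(nN); L <- integer(nN)
  # nodes were created in preorder, so children always have larger ids
  for (id in rev(seq_len(nN))) {
    if (is.na(left[id]) || prunedMask[id]) {
      R[id] <- ss[id]; L[id] <- 1L
    } else {
      R[id] <- R[left[id]] + R[right[id]]
      L[id] <- L[left[id]] + L[right[id]]
    }
  }
  list(R = R, nLeaves = L)
}

# Internal nodes that are still split given the pruned set (i.e. not pruned,
# not below a pruned node).
activeInternal <- function(frame, pruned) {
  nN <- nrow(frame)
  parent <- frame$parent; left <- frame$left
  prunedMask <- logical(nN); prunedMask[pruned] <- TRUE
  active <- logical(nN)
  for (id in seq_len(nN)) {
    active[id] <- if (is.na(parent[id])) TRUE else
      active[parent[id]] && !prunedMask[parent[id]]
  }
  which(active & !is.na(left) & !prunedMask)
}

# Weakest-link cost-complexity pruning sequence.
# Returns data.frame (size, alpha, R) plus the pruned set per step.
pruneSequence <- function(frame) {
  pruned <- integer()
  steps <- list()
  st <- subtreeStats(frame, pruned)
  steps[[1L]] <- list(alpha = 0, pruned = pruned,
                      size = st$nLeaves[1L], R = st$R[1L])
  tol <- 1e-12
  repeat {
    internal <- activeInternal(frame, pruned)
    if (!length(internal)) break
    st <- subtreeStats(frame, pruned)
    g <- (frame$ss[internal] - st$R[internal]) / (st$nLeaves[internal] - 1L)
    m <- min(g)
    pruned <- c(pruned, internal[g <= m + tol])
    st2 <- subtreeStats(frame, pruned)
    steps[[length(steps) + 1L]] <- list(alpha = m, pruned = pruned,
                                        size = st2$nLeaves[1L], R = st2$R[1L])
  }
  steps
}

# Smallest cost-complexity-optimal pruned set at penalty alpha; `start` lets
# callers walking an increasing alpha grid reuse the previous pruned set.
pruneAtAlpha <- function(frame, alpha, start = integer()) {
  pruned <- start
  tol <- 1e-12
  repeat {
    internal <- activeInternal(frame, pruned)
    if (!length(internal)) break
    st <- subtreeStats(frame, pruned)
    g <- (frame$ss[internal] - st$R[internal]) / (st$nLeaves[internal] - 1L)
    m <- min(g)
    if (m <= alpha + tol) pruned <- c(pruned, internal[g <= m + tol]) else break
  }
  pruned
}

# Route rows of X down the pruned tree; returns the leaf node id per row.
routeRows <- function(frame, pruned, X) {
  nN <- nrow(frame)
  left <- frame$left; right <- frame$right
  var <- frame$var; thr <- frame$threshold
  prunedMask <- logical(nN); prunedMask[pruned] <- TRUE
  xcols <- lapply(unique(var[!is.na(var)]), function(v) X[[v]])
  names(xcols) <- unique(var[!is.na(var)])
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    id <- 1L
    while (!is.na(left[id]) && !prunedMask[id]) {
      id <- if (xcols[[var[id]]][i] < thr[id]) left[id] else right[id]
    }
    out[i] <- id
  }
  out
}

leafIds <- function(frame, pruned) {
  ids <- integer()
  walk <- function(id) {
    row <- frame[id, ]
    if (is.na(row$left) || id %in% pruned) ids[[length(ids) + 1L]] <<- id
    else { walk(row$left); walk(row$right) }
  }
  walk(1L)
  ids
}

#' Fit a multivariate regression tree with minimum-CVRE selection
#'
#' Grows a maximal tree on the (by default untransformed) plot-by-species
#' abundance matrix with single-variable threshold splits on the environment
#' predictors, derives the nested cost-complexity pruning sequence, estimates
#' the cross-validated relative error CVRE(size) = (cross-validated
#' prediction sum of squares) / (total sum of squares about the grand
#' multivariate mean) by \code{n_cv_reps} repeats of \code{cv_folds}-fold
#' cross-validation, and returns the pruned tree whose size minimizes the
#' mean CVRE (ties towards the smaller tree).  Leaves become habitat labels
#' \code{H1..Hk}, ordered by leaf-mean elevation then latitude.
#'
#' @param comm plots x species abundance matrix.
#' @param env plot environment data.frame (\code{plot} plus the predictors).
#' @param predictors numeric predictor columns (default elevation, latitude).
#' @param min_leaf minimum plots per leaf (default 5).
#' @param cv_folds folds per cross-validation (default 10).
#' @param n_cv_reps cross-validation repeats (default 50).
#' @param seed integer seed for the fold assignments.
#' @param hellinger logical; apply the Hellinger transform (square root of
#'   relative abundance) to the response first.  Default FALSE (raw
#'   abundances).
#' @return an [MRTModel-class].
#' @export
mrtFit <- function(comm, env, predictors = c("elevation", "latitude"),
                   min_leaf = 5L, cv_folds = 10L, n_cv_reps = 50L,
                   seed = 1L, hellinger = FALSE) {
  Y <- as.matrix(comm)
  stopIfNot2(!is.null(rownames(Y)), "comm needs plot row names")
  stopIfNot2(all(rownames(Y) %in% env$plot), "plots missing from env")
  X <- env[match(rownames(Y), env$plot), , drop = FALSE]
  stopIfNot2(all(predictors %in% names(X)), "predictors missing from env")
  n <- nrow(Y)
  stopIfNot2(n >= 2L * min_leaf, "fewer plots than 2 * min_leaf")
  if (hellinger) {
    rs <- rowSums(Y)
    rs[rs == 0] <- 1
    Y <- sqrt(Y / rs)
  }

  full <- growTree(Y, X, predictors, min_leaf)
  steps <- pruneSequence(full$frame)
  sizes <- vapply(steps, `[[`, numeric(1), "size")
  alphas <- vapply(steps, `[[`, numeric(1), "alpha")
  Rs <- vapply(steps, `[[`, numeric(1), "R")
  R0 <- full$frame$ss[1L]
  relerr <- if (R0 > 0) Rs / R0 else rep(1, length(Rs))

  m <- length(steps)
  alphaPrime <- if (m == 1L) 0 else {
    c(0, sqrt(alphas[-1] * c(alphas[-c(1L, 2L)], 2 * alphas[m]))[seq_len(m - 1L)])
  }

  ## repeated k-fold CV of the prediction SS per pruning-sequence size
  TSS <- nodeImpurity(Y)
  cvreMat <- matrix(NA_real_, n_cv_reps, m)
  for (rep in seq_len(n_cv_reps)) {
    folds <- withSeed(childSeed(seed, paste0("cv", rep)),
                      sample(rep_len(seq_len(cv_folds), n)))
    cvss <- numeric(m)
    for (f in seq_len(cv_folds)) {
      test <- which(folds == f)
      train <- which(folds != f)
      ft <- growTree(Y[train, , drop = FALSE], X[train, , drop = FALSE],
                     predictors, min_leaf)
      pruned <- integer()
      for (si in seq_len(m)) {
        pruned <- pruneAtAlpha(ft$frame, alphaPrime[si], start = pruned)
        leafOfTest <- routeRows(ft$frame, pruned, X[test, , drop = FALSE])
        for (lf in unique(leafOfTest)) {
          mu <- colMeans(Y[train[ft$rows[[lf]]], , drop = FALSE])
          rows <- test[leafOfTest == lf]
          cvss[si] <- cvss[si] +
            sum(sweep(Y[rows, , drop = FALSE], 2L, mu)^2)
        }
      }
    }
    cvreMat[rep, ] <- cvss / TSS
  }
  cvre <- colMeans(cvreMat)
  cvse <- if (n_cv_reps > 1L) apply(cvreMat, 2L, stats::sd) else
    rep(NA_real_, m)

  winners <- which(cvre <= min(cvre) + 1e-12)
  sel <- winners[which.min(sizes[winners])]

  pruned <- steps[[sel]]$pruned
  leaves <- leafIds(full$frame, pruned)
  leafOfPlot <- routeRows(full$frame, pruned, X)
  ord <- order(
    vapply(leaves, function(id) mean(X$elevation[full$rows[[id]]]), numeric(1)),
    vapply(leaves, function(id) mean(X$latitude[full$rows[[id]]]), numeric(1)))
  labels <- stats::setNames(paste0("H", seq_along(leaves)), leaves[ord])
  assignments <- stats::setNames(unname(labels[as.character(leafOfPlot)]),
                                 rownames(Y))

  keep <- sort(unique(c(1L, unlist(lapply(leaves, function(id) {
    path <- id
    while (!is.na(frameParent <- full$frame$parent[path[1L]])) {
      path <- c(frameParent, path)
    }
    path
  })))))
  fr <- full$frame[keep, , drop = FALSE]
  isLeaf <- fr$node %in% leaves
  fr$var[isLeaf] <- NA_character_
  fr$threshold[isLeaf] <- NA_real_
  frame <- data.frame(node = fr$node, parent = fr$parent, var = fr$var,
                      threshold = fr$threshold, n = fr$n, ss = fr$ss,
                      leaf = isLeaf,
                      label = ifelse(isLeaf, labels[as.character(fr$node)], NA),
                      stringsAsFactors = FALSE)

  methods::new("MRTModel",
    frame = frame, assignments = assignments,
    cvre = cvre[sel],
    rSquared = 1 - relerr[sel],
    cvTable = data.frame(size = sizes, alpha = alphas, relerr = relerr,
                         cvre = cvre, cvse = cvse),
    predictors = predictors)
}

#' @describeIn mrtFit the plot -> habitat assignment of the fitted model.
#' @param model an \code{MRTModel}.
#' @export
habitatAssignments <- function(model) model@assignments

#' Assign new plots to the habitats of a fitted MRT
#'
#' @param model an [MRTModel-class].
#' @param env environment data.frame containing the model's predictors.
#' @return named character vector of habitat labels.
#' @export
predictHabitat <- function(model, env) {
  fr <- model@frame
  out <- character(nrow(env))
  for (i in seq_len(nrow(env))) {
    id <- fr$node[1L]
    repeat {
      row <- fr[fr$node == id, ]
      if (row$leaf) break
      id <- if (env[i, row$var] < row$threshold) {
        kids <- fr$node[!is.na(fr$parent) & fr$parent == id]
        min(kids)
      } else {
        kids <- fr$node[!is.na(fr$parent) & fr$parent == id]
        max(kids)
      }
    }
    out[i] <- fr$label[fr$node == id]
  }
  if (!is.null(env$plot)) names(out) <- env$plot
  out
}
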