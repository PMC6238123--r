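#' @import methods
NULL

setOldClass("phylo")

#' CommunityData: plots x species abundances with environment and phylogeny
#'
#' The central container of the package, holding a plot-by-species abundance
#' matrix of non-negative integers, a plot environment table (elevation in
#' metres, latitude/longitude in decimal degrees) and a rooted phylogeny with
#' branch lengths covering the species pool.  Validity enforces the
#' cross-references between the three components; use [communityData()] to
#' construct one (it harmonizes names first).
#'
#' @slot comm numeric matrix, plots in rows, species in columns.
#' @slot env data.frame with one row per plot; columns \code{plot},
#'   \code{elevation}, \code{latitude} and optionally \code{longitude}.
#' @slot tree an \code{ape::phylo} tree whose tip labels cover the species.
#' @aliases CommunityData-class
#' @export
setClass("CommunityData",
  representation(comm = "matrix", env = "data.frame", tree = "phylo")
)

setValidity("CommunityData", function(object) {
  comm <- object@comm
  env <- object@env
  tree <- object@tree
  msgs <- character()
  if (is.null(rownames(comm)) || is.null(colnames(comm))) {
    msgs <- c(msgs, "abundance matrix must have plot row names and species column names")
  } else {
    if (anyDuplicated(rownames(comm))) msgs <- c(msgs, "duplicate plot ids")
    if (anyDuplicated(colnames(comm))) msgs <- c(msgs, "duplicate species ids")
    if (!setequal(rownames(comm), env$plot)) {
      msgs <- c(msgs, "plots in abundance matrix and environment table differ")
    }
    if (!all(colnames(comm) %in% tree$tip.label)) {
      msgs <- c(msgs, "species present in the matrix but absent from the tree")
    }
  }
  if (any(comm < 0)) msgs <- c(msgs, "negative abundances")
  if (!all(c("plot", "elevation", "latitude") %in% names(env))) {
    msgs <- c(msgs, "environment table needs columns plot, elevation, latitude")
  } else {
    if (any(!is.finite(env$elevation))) msgs <- c(msgs, "non-finite elevation")
    if (any(abs(env$latitude) > 90)) msgs <- c(msgs, "latitude outside [-90, 90]")
  }
  if (length(msgs)) msgs else TRUE
})

#' MRTModel: a fitted multivariate regression tree
#'
#' Binary tree of single-variable threshold splits on environment/geography
#' predictors, with the whole community-composition matrix as the response.
#' The returned tree is the member of the cost-complexity pruning sequence
#' minimizing the cross-validated relative error (CVRE).  Leaves are habitat
#' labels \code{H1..Hk}, ordered by leaf-mean elevation then latitude.
#'
#' @slot frame data.frame describing the pruned tree: one row per node with
#'   columns \code{node}, \code{parent}, \code{var}, \code{threshold},
#'   \code{n}, \code{ss}, \code{leaf} (logical), \code{label}.
#' @slot assignments named character vector, plot id -> habitat label.
#' @slot cvre numeric, CVRE of the selected tree size.
#' @slot rSquared numeric, 1 - resubstitution relative error.
#' @slot cvTable data.frame with the pruning path: \code{size}, \code{alpha},
#'   \code{relerr} (resubstitution relative error) and \code{cvre}.
#' @slot predictors character, predictor columns used.
#' @aliases MRTModel-class
#' @export
setClass("MRTModel",
  representation(
    frame = "data.frame", assignments = "character", cvre = "numeric",
    rSquared = "numeric", cvTable = "data.frame", predictors = "character"
  )
)

setValidity("MRTModel", function(object) {
  msgs <- character()
  if (length(object@rSquared) && (object@rSquared < -1e-8 || object@rSquared > 1 + 1e-8)) {
    msgs <- c(msgs, "rSquared outside [0, 1]")
  }
  if (length(object@cvre) && object@cvre < 0) msgs <- c(msgs, "negative cvre")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CommunityData", function(object) {
  cat("CommunityData:", nrow(object@comm), "plots x", ncol(object@comm), "species\n")
  cat("  phylogeny:", length(object@tree$tip.label), "tips;",
      "elevation", paste(round(range(object@env$elevation)), collapse = "-"), "m\n")
  occ <- rowSums(object@comm > 0)
  cat("  plot richness:", min(occ), "-", max(occ),
      "(median", stats::median(occ), ")\n")
  invisible(object)
})

setMethod("show", "MRTModel", function(object) {
  k <- sum(object@frame$leaf)
  cat("Multivariate regression tree:", k, "habitat(s), CVRE =",
      signif(object@cvre, 3), ", R^2 =", signif(object@rSquared, 3), "\n")
  if (k > 1L) {
    printNode <- function(id, indent) {
      row <- object@frame[which(object@frame$node == id), ]
      pad <- strrep("  ", indent)
      if (row$leaf) {
        cat(pad, row$label, " (n=", row$n, ")\n", sep = "")
      } else {
        cat(pad, row$var, " < ", signif(row$threshold, 6), "\n", sep = "")
        kids <- object@frame$node[which(object@frame$parent == id)]
        for (ch in kids) printNode(ch, indent + 1L)
      }
    }
    printNode(object@frame$node[1L], 0L)
  }
  invisible(object)
})
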