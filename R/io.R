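#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation downstream analyses rely on:
#' unique tip labels, at least two tips, a rooted topology and non-negative
#' branch lengths (zero-length branches are allowed).
#'
#' @param path path to a Newick file.
#' @return an \code{ape::phylo} object.
#' @export
readPhylogeny <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse failure: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("Newick parse failure: no tree in file", call. = FALSE)
  validatePhylogeny(tree)
}

#' @rdname readPhylogeny
#' @param tree an \code{ape::phylo} object to validate in place.
#' @export
validatePhylogeny <- function(tree) {
  stopIfNot2(inherits(tree, "phylo"), "not a phylo object")
  tree$tip.label <- normalizeNames(tree$tip.label)
  stopIfNot2(length(tree$tip.label) >= 2L, "phylogeny must have >= 2 tips")
  stopIfNot2(!anyDuplicated(tree$tip.label), "duplicate tip labels in phylogeny")
  stopIfNot2(!is.null(tree$edge.length), "phylogeny must carry branch lengths")
  stopIfNot2(all(tree$edge.length >= 0), "negative branch lengths in phylogeny")
  stopIfNot2(ape::is.rooted(tree), "phylogeny must be rooted")
  tree
}

#' Read a plot-by-species abundance matrix
#'
#' Expects delimiter-separated text with a header row of species names and
#' plot ids in the first column.  Abundances must be non-negative counts.
#'
#' @param path file path.
#' @param sep field delimiter (default tab).
#' @return numeric matrix, plots in rows.
#' @export
readCommunityMatrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- normalizeNames(rownames(m))
  colnames(m) <- normalizeNames(colnames(m))
  stopIfNot2(all(is.finite(m)), "non-numeric abundances")
  stopIfNot2(all(m >= 0), "negative abundances")
  m
}

#' Read a plot environment table
#'
#' @param path file path to a delimited table with columns \code{plot},
#'   \code{elevation} (m), \code{latitude} (decimal degrees) and optionally
#'   \code{longitude}.
#' @param sep field delimiter (default tab).
#' @return a data.frame with one row per plot.
#' @export
readPlotEnvironment <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopIfNot2(all(c("plot", "elevation", "latitude") %in% names(df)),
             "environment table needs columns plot, elevation, latitude")
  df$plot <- normalizeNames(as.character(df$plot))
  stopIfNot2(!anyDuplicated(df$plot), "duplicate plot ids in environment table")
  stopIfNot2(all(is.finite(df$elevation)), "non-finite elevation")
  stopIfNot2(all(abs(df$latitude) <= 90), "latitude outside [-90, 90]")
  df
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips; the
#' pairwise phylogenetic distance underlying MPD, MNTD, Dpw and Dnn.
#'
#' @param tree an \code{ape::phylo}.
#' @return symmetric matrix with zero diagonal, labelled by tip.
#' @export
patristicDistances <- function(tree) {
  tree <- validatePhylogeny(tree)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Harmonize tree, community matrix and environment table
#'
#' Prunes the phylogeny to the species present in the matrix, drops matrix
#' columns without a matching tip and restricts plots to those present in
#' both the matrix and the environment table.  Name matching is exact string
#' matching after trimming whitespace and replacing spaces with underscores.
#' Dropped names are reported via \code{message()}.  The operation is
#' idempotent.
#'
#' @param tree \code{ape::phylo}.
#' @param comm plots x species abundance matrix.
#' @param env plot environment data.frame.
#' @return list with elements \code{tree}, \code{comm}, \code{env}.
#' @export
harmonizeData <- function(tree, comm, env) {
  tree <- validatePhylogeny(tree)
  rownames(comm) <- normalizeNames(rownames(comm))
  colnames(comm) <- normalizeNames(colnames(comm))
  env$plot <- normalizeNames(as.character(env$plot))

  spp <- intersect(colnames(comm), tree$tip.label)
  if (length(spp) == 0L) stop("no species shared between tree and matrix", call. = FALSE)
  plots <- intersect(rownames(comm), env$plot)
  if (length(plots) == 0L) stop("no plots shared between matrix and environment table",
                                call. = FALSE)

  droppedTips <- setdiff(tree$tip.label, spp)
  droppedCols <- setdiff(colnames(comm), spp)
  droppedPlots <- union(setdiff(rownames(comm), plots), setdiff(env$plot, plots))
  if (length(droppedTips)) message("harmonize: dropped ", length(droppedTips),
                                   " tree tip(s) absent from the matrix")
  if (length(droppedCols)) message("harmonize: dropped ", length(droppedCols),
                                   " matrix species absent from the tree")
  if (length(droppedPlots)) message("harmonize: dropped ", length(droppedPlots),
                                    " plot(s) not shared by matrix and environment")

  if (length(droppedTips)) tree <- ape::keep.tip(tree, spp)
  comm <- comm[plots, spp, drop = FALSE]
  env <- env[match(plots, env$plot), , drop = FALSE]
  rownames(env) <- NULL
  list(tree = tree, comm = comm, env = env)
}

#' Construct a CommunityData object
#'
#' Harmonizes the three inputs (see [harmonizeData()]) and returns a validated
#' [CommunityData-class] container.
#'
#' @inheritParams harmonizeData
#' @return a \code{CommunityData} object.
#' @export
communityData <- function(comm, env, tree) {
  h <- harmonizeData(tree, comm, env)
  methods::new("CommunityData", comm = h$comm, env = h$env, tree = h$tree)
}

#' @describeIn communityData the plots x species abundance matrix.
#' @param x a \code{CommunityData}.
#' @export
communityMatrix <- function(x) x@comm

#' @describeIn communityData the plot environment table.
#' @export
plotEnvironment <- function(x) x@env

#' @describeIn communityData the phylogeny.
#' @export
phylogeny <- function(x) x@tree

#' Ultrametricity report for a phylogeny
#'
#' The null-model metrics are well defined on non-ultrametric trees, but a
#' dated tree should be close to ultrametric; this reports the spread of
#' root-to-tip depths so deviations are visible rather than silently ignored.
#'
#' @param tree \code{ape::phylo}.
#' @return list with \code{min_depth}, \code{max_depth}, \code{spread} and
#'   logical \code{ultrametric} (spread below 1e-6 of max depth).
#' @export
ultrametricityReport <- function(tree) {
  tree <- validatePhylogeny(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  spread <- max(depths) - min(depths)
  list(min_depth = min(depths), max_depth = max(depths), spread = spread,
       ultrametric = spread <= 1e-6 * max(depths, 1e-300))
}

#' Write a numeric matrix as delimited text with an id header column
#' @param m matrix with dimnames.
#' @param path output path.
#' @param sep delimiter.
#' @export
writeMatrix <- function(m, path, sep = "\t") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
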