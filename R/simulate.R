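#' Scenario configuration for the synthetic-community generator
#'
#' Describes a simulated plot survey: a species pool with a Brownian trait on
#' a Yule phylogeny, plots stratified into elevation zones along a latitudinal
#' gradient, latent habitat types, and one or more assembly processes
#' (\code{neutral}, \code{filtering}, \code{limiting_similarity},
#' \code{dispersal_limitation}) whose strength is tunable.  Defaults emulate a
#' mountainous-rangeland survey design: 236 plots of 1 m2 in four elevation
#' zones (1,200-1,500, 1,500-1,800, 1,800-2,000 and 2,000-2,200 m) of 59
#' plots each, 168 species, a ~24 km latitudinal extent, and four latent
#' habitat types formed by elevation zones and a latitudinal break (a river
#' barrier): the two lowest zones are habitats of their own and the two upper
#' zones are split at the latitude midline.
#'
#' @param n_species species-pool size (>= 4).
#' @param n_plots number of plots (>= 8).
#' @param elevation_range numeric length 2, metres.
#' @param latitude_range numeric length 2, decimal degrees.
#' @param longitude_range numeric length 2, decimal degrees.
#' @param n_habitats number of latent habitat types.
#' @param process character, any subset of \code{"neutral"},
#'   \code{"filtering"}, \code{"limiting_similarity"},
#'   \code{"dispersal_limitation"}; several combine multiplicatively.
#' @param process_strength non-negative real; 0 is equivalent to neutral.
#' @param trait_model Brownian rate (variance per unit branch length) of the
#'   simulated tolerance trait.
#' @param mean_richness Poisson mean of per-plot species richness (truncated
#'   below at 2); identical across processes for a given seed.
#' @param abundance_mean mean of the shifted-geometric abundance of an
#'   occurrence (>= 1).
#' @param habitat_structure logical; when TRUE, the filtering optimum is the
#'   latent habitat's characteristic trait optimum (a step function of the
#'   elevation band and latitude side — habitat specialization) rather than a
#'   smooth linear map of plot elevation.
#' @param filter_gradient real in [0, 1); fraction by which the effective
#'   filtering strength declines from the lowest to the highest plot,
#'   letting filtering relax along the elevation gradient.
#' @param seed integer master seed; all stage seeds are derived from it.
#' @return a validated list of class \code{ScenarioConfig}.
#' @export
scenarioConfig <- function(n_species = 168L, n_plots = 236L,
                           elevation_range = c(1200, 2200),
                           latitude_range = c(36.667, 36.883),
                           longitude_range = c(59.283, 59.517),
                           n_habitats = 4L,
                           process = "neutral",
                           process_strength = 0,
                           trait_model = 1,
                           mean_richness = 15,
                           abundance_mean = 3,
                           habitat_structure = FALSE,
                           filter_gradient = 0,
                           seed = 1L) {
  process <- match.arg(process,
    c("neutral", "filtering", "limiting_similarity", "dispersal_limitation"),
    several.ok = TRUE)
  stopIfNot2(n_species >= 4, "n_species must be >= 4")
  stopIfNot2(n_plots >= 8, "n_plots must be >= 8")
  stopIfNot2(process_strength >= 0, "process_strength must be >= 0")
  stopIfNot2(trait_model >= 0, "trait_model (Brownian rate) must be >= 0")
  stopIfNot2(abundance_mean >= 1, "abundance_mean must be >= 1")
  stopIfNot2(filter_gradient >= 0 && filter_gradient < 1,
             "filter_gradient must be in [0, 1)")
  stopIfNot2(diff(elevation_range) > 0, "elevation_range must be increasing")
  cfg <- list(
    n_species = as.integer(n_species), n_plots = as.integer(n_plots),
    elevation_range = as.numeric(elevation_range),
    latitude_range = as.numeric(latitude_range),
    longitude_range = as.numeric(longitude_range),
    n_habitats = as.integer(n_habitats), process = process,
    process_strength = as.numeric(process_strength),
    trait_model = as.numeric(trait_model),
    mean_richness = as.numeric(mean_richness),
    abundance_mean = as.numeric(abundance_mean),
    habitat_structure = isTRUE(habitat_structure),
    filter_gradient = as.numeric(filter_gradient),
    seed = as.integer(seed)
  )
  class(cfg) <- "ScenarioConfig"
  cfg
}

#' @export
print.ScenarioConfig <- function(x, ...) {
  cat("ScenarioConfig:", x$n_plots, "plots,", x$n_species, "species,",
      x$n_habitats, "habitats\n  process:",
      paste(x$process, collapse = " x "), "(strength", x$process_strength,
      ")  seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Constant-rate pure-birth tree conditioned on the number of tips, rescaled
#' so the root-to-tip depth is exactly 1; deterministic given the seed.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed.
#' @return an ultrametric \code{ape::phylo} with tips \code{S001, S002, ...}.
#' @export
simulatePhylogeny <- function(n_species, seed = 1L) {
  stopIfNot2(n_species >= 2, "n_species must be >= 2")
  tree <- withSeed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("S%03d", seq_len(n_species))
  tree
}

#' Simulate a Brownian trait on a phylogeny
#'
#' Brownian motion from a root value of 0 with variance \code{rate} per unit
#' branch length, giving the species' environmental tolerance a concrete,
#' phylogenetically conserved mechanism.
#'
#' @param tree \code{ape::phylo}.
#' @param rate Brownian rate (>= 0).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulateTrait <- function(tree, rate = 1, seed = 1L) {
  stopIfNot2(rate >= 0, "rate must be >= 0")
  if (rate == 0) {
    return(stats::setNames(numeric(length(tree$tip.label)), tree$tip.label))
  }
  withSeed(seed, ape::rTraitCont(tree, model = "BM", sigma = sqrt(rate),
                                 root.value = 0))
}

# Elevation band boundaries for the latent zones.  For the default four-zone
# 1,200-2,200 m design the bands are the survey's zone boundaries
# (1,500 / 1,800 / 2,000 m); otherwise equal-width bands.
elevationBands <- function(cfg) {
  er <- cfg$elevation_range
  if (cfg$n_habitats == 4L && isTRUE(all.equal(er, c(1200, 2200)))) {
    return(c(1200, 1500, 1800, 2000, 2200))
  }
  seq(er[1], er[2], length.out = max(cfg$n_habitats, 1L) + 1L)
}

# Latent habitat of each plot: elevation band x latitude side, truncated to
# n_habitats labels.  The lowest n_habitats - 2 bands are habitats on their
# own; the top two bands are split at the latitude midline.
latentHabitat <- function(cfg, elevation, latitude) {
  k <- cfg$n_habitats
  if (k <= 1L) return(rep("H1", length(elevation)))
  bands <- elevationBands(cfg)
  zone <- findInterval(elevation, bands, rightmost.closed = TRUE,
                       all.inside = TRUE)
  north <- latitude >= mean(cfg$latitude_range)
  if (k == 2L) {
    lab <- ifelse(north, 2L, 1L)
  } else {
    lab <- zone
    hi <- zone >= k - 1L
    lab[hi] <- ifelse(north[hi], k, k - 1L)
  }
  paste0("H", lab)
}

#' Simulate plot communities under a known assembly process
#'
#' Plots receive elevations stratified into the configured elevation zones
#' (equal plot counts per zone) and uniform latitudes/longitudes; the latent
#' habitat of each plot is its elevation band crossed with the latitude side
#' (see [scenarioConfig()]).  Per-plot richness is drawn once (Poisson,
#' identical across processes for a seed) and species identities are drawn
#' according to the configured process:
#' \describe{
#'   \item{neutral}{uniform over the pool.}
#'   \item{filtering}{Gaussian kernel on the trait about a plot optimum; the
#'     kernel width shrinks as \code{process_strength} grows.}
#'   \item{limiting_similarity}{sequential admission rejecting candidates
#'     whose patristic distance to any resident falls below a pool-distance
#'     quantile rising with \code{process_strength}; if no candidate
#'     complies, the most distant one is admitted and a warning summarizes
#'     the fallbacks.}
#'   \item{dispersal_limitation}{each species has a 2-D Gaussian range kernel
#'     about a random range centre; occurrence probability decays with
#'     geographic distance from the centre, faster for larger
#'     \code{process_strength}.}
#' }
#' Processes named together combine multiplicatively.  Abundances are i.i.d.
#' shifted-geometric per occurrence.
#'
#' @param cfg a [scenarioConfig()].
#' @param tree phylogeny for the pool (defaults to a simulated Yule tree).
#' @param traits named trait vector (defaults to a simulated Brownian trait).
#' @return list with \code{comm} (plots x species integer matrix), \code{env}
#'   (plot environment data.frame), \code{habitats} (named character vector of
#'   true latent habitats) and \code{traits}.
#' @export
simulateCommunities <- function(cfg, tree = NULL, traits = NULL) {
  stopIfNot2(inherits(cfg, "ScenarioConfig"), "cfg must be a ScenarioConfig")
  if (is.null(tree)) tree <- simulatePhylogeny(cfg$n_species, childSeed(cfg$seed, "tree"))
  if (is.null(traits)) traits <- simulateTrait(tree, cfg$trait_model,
                                               childSeed(cfg$seed, "trait"))
  S <- length(tree$tip.label)
  stopIfNot2(S == cfg$n_species, "tree size does not match cfg$n_species")
  stopIfNot2(all(tree$tip.label %in% names(traits)), "traits must cover all tips")
  traits <- traits[tree$tip.label]
  n <- cfg$n_plots

  ## environment: zones with equal plot counts, uniform within band
  bands <- elevationBands(cfg)
  nz <- length(bands) - 1L
  perZone <- rep(n %/% nz, nz)
  if (n %% nz) perZone[seq_len(n %% nz)] <- perZone[seq_len(n %% nz)] + 1L
  env <- withSeed(childSeed(cfg$seed, "environment"), {
    elev <- unlist(lapply(seq_len(nz), function(z) {
      stats::runif(perZone[z], bands[z], bands[z + 1L])
    }))
    data.frame(
      plot = sprintf("P%03d", seq_len(n)),
      elevation = elev,
      latitude = stats::runif(n, cfg$latitude_range[1], cfg$latitude_range[2]),
      longitude = stats::runif(n, cfg$longitude_range[1], cfg$longitude_range[2])
    )
  })
  habitats <- stats::setNames(latentHabitat(cfg, env$elevation, env$latitude),
                              env$plot)

  ## richness: shared across processes for a given seed
  richness <- withSeed(childSeed(cfg$seed, "richness"), {
    pmin(pmax(stats::rpois(n, cfg$mean_richness), 2L), S)
  })

  ## process weight matrix (n x S)
  W <- matrix(1, n, S)
  strength <- cfg$process_strength
  if ("filtering" %in% cfg$process && strength > 0) {
    tr <- as.numeric(traits)
    relElev <- (env$elevation - cfg$elevation_range[1]) / diff(cfg$elevation_range)
    if (cfg$habitat_structure) {
      hIdx <- as.integer(sub("^H", "", habitats))
      opt <- stats::quantile(tr, (hIdx - 0.5) / cfg$n_habitats, names = FALSE)
    } else {
      opt <- min(tr) + relElev * (max(tr) - min(tr))
    }
    effStrength <- strength * (1 - cfg$filter_gradient * relElev)
    sigma <- stats::sd(tr) / (1 + effStrength)
    W <- W * exp(-(outer(opt, tr, "-"))^2 / (2 * sigma^2))
  }
  if ("dispersal_limitation" %in% cfg$process && strength > 0) {
    centres <- withSeed(childSeed(cfg$seed, "ranges"), {
      cbind(lon = stats::runif(S, cfg$longitude_range[1], cfg$longitude_range[2]),
            lat = stats::runif(S, cfg$latitude_range[1], cfg$latitude_range[2]))
    })
    plotXY <- cbind(env$longitude, env$latitude)
    dKm <- geosphere::distm(plotXY, centres,
                            fun = geosphere::distHaversine) / 1000
    extent <- geosphere::distHaversine(
      c(cfg$longitude_range[1], cfg$latitude_range[1]),
      c(cfg$longitude_range[2], cfg$latitude_range[2])) / 1000
    rho <- extent / (2 * (1 + strength))
    W <- W * exp(-dKm^2 / (2 * rho^2))
  }
  W <- W + 1e-12  # keep every species drawable when richness forces it

  limiting <- "limiting_similarity" %in% cfg$process && strength > 0
  if (limiting) {
    D <- patristicDistances(tree)
    tau <- stats::quantile(D[upper.tri(D)], 0.8 * strength / (1 + strength),
                           names = FALSE)
  }

  ## identities + abundances
  comm <- matrix(0L, n, S, dimnames = list(env$plot, tree$tip.label))
  nFallback <- 0L
  withSeed(childSeed(cfg$seed, "occurrence"), {
    for (p in seq_len(n)) {
      k <- richness[p]
      w <- W[p, ]
      if (!limiting) {
        ids <- sample.int(S, k, prob = w)
      } else {
        ids <- sample.int(S, 1L, prob = w)
        while (length(ids) < k) {
          cand <- setdiff(seq_len(S), ids)
          minD <- apply(D[cand, ids, drop = FALSE], 1L, min)
          ok <- cand[minD >= tau]
          if (length(ok)) {
            ids <- c(ids, if (length(ok) == 1L) ok else
                            sample(ok, 1L, prob = w[ok]))
          } else {
            ids <- c(ids, cand[which.max(minD)])
            nFallback <- nFallback + 1L
          }
        }
      }
      comm[p, ids] <- 1L
    }
  })
  if (nFallback > 0L) {
    warning("limiting-similarity admission infeasible ", nFallback,
            " time(s); admitted the most distant candidate instead",
            call. = FALSE)
  }
  occ <- which(comm > 0)
  comm[occ] <- withSeed(childSeed(cfg$seed, "abundance"), {
    1L + stats::rgeom(length(occ), prob = 1 / cfg$abundance_mean)
  })

  list(comm = comm, env = env, habitats = habitats, traits = traits)
}

#' Simulate a full scenario as a CommunityData object
#'
#' Convenience wrapper chaining [simulatePhylogeny()], [simulateTrait()] and
#' [simulateCommunities()], returning the harmonized container plus the truth.
#'
#' @param cfg a [scenarioConfig()].
#' @return list with \code{data} (a [CommunityData-class]), \code{tree},
#'   \code{traits}, \code{habitats}.
#' @export
simulateScenario <- function(cfg) {
  tree <- simulatePhylogeny(cfg$n_species, childSeed(cfg$seed, "tree"))
  traits <- simulateTrait(tree, cfg$trait_model, childSeed(cfg$seed, "trait"))
  sim <- simulateCommunities(cfg, tree, traits)
  dat <- suppressMessages(communityData(sim$comm, sim$env, tree))
  list(data = dat, tree = tree, traits = sim$traits, habitats = sim$habitats)
}
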