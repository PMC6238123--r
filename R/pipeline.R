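## End-to-end orchestration: simulate (or read) -> harmonize -> MRT habitats
## -> indicator species -> alpha SES + gradient regressions -> beta SES +
## Mantel / partial Mantel, written to a run directory with a manifest, a log
## and the verbatim configuration.

#' Default pipeline configuration
#'
#' @param output_dir run directory to create.
#' @param seed master seed; each stage derives its own via [childSeed()].
#' @return nested configuration list; amend and pass to [runPipeline()].
#' @export
pipelineConfig <- function(output_dir = tempfile("phylocomm_run_"), seed = 1L) {
  list(
    output_dir = output_dir,
    seed = as.integer(seed),
    # either `scenario` (passed to scenarioConfig) or `inputs` with paths
    # tree / comm / env must be present
    scenario = list(),
    inputs = NULL,
    predictors = c("elevation", "latitude"),
    mrt = list(min_leaf = 5L, cv_folds = 10L, n_cv_reps = 10L),
    indval = list(n_perm = 999L),
    alpha = list(n_null = 999L, weighted = FALSE),
    beta = list(n_null = 199L, weighted = FALSE),
    mantel = list(n_perm = 999L)
  )
}

writeTable <- function(df, path) {
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full community-phylogenetics pipeline
#'
#' Executes every stage on either a simulated scenario or files named in the
#' configuration, writing all result tables, a timestamped log, the verbatim
#' configuration and a manifest with an md5 content hash per output.  Any
#' stage failure aborts with the stage name and the offending input recorded
#' in the log.  Identical configurations produce byte-identical result
#' tables.
#'
#' @param config configuration list (see [pipelineConfig()]) or the path to a
#'   YAML file with the same structure.
#' @return the run directory, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipelineConfig(output_dir = config$output_dir %||% tempfile("phylocomm_run_"),
                             seed = config$seed %||% 1L)
  config <- utils::modifyList(defaults, config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  logLines <- character()
  logIt <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    logLines <<- c(logLines, line)
    writeLines(logLines, out("log.txt"))
  }
  stage <- function(name, expr) {
    logIt("stage ", name, ": start")
    tryCatch(expr, error = function(e) {
      logIt("stage ", name, ": FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  yaml::write_yaml(config, out("config.yaml"))
  seed <- config$seed

  ## ---- inputs ----
  dat <- stage("input", {
    if (!is.null(config$inputs)) {
      tree <- readPhylogeny(config$inputs$tree)
      comm <- readCommunityMatrix(config$inputs$comm)
      env <- readPlotEnvironment(config$inputs$env)
      truth <- NULL
      cd <- communityData(comm, env, tree)
      list(data = cd, habitats_true = truth)
    } else {
      cfg <- do.call(scenarioConfig,
                     utils::modifyList(list(seed = childSeed(seed, "scenario")),
                                       as.list(config$scenario)))
      sc <- simulateScenario(cfg)
      list(data = sc$data, habitats_true = sc$habitats)
    }
  })
  cd <- dat$data
  comm <- communityMatrix(cd)
  env <- plotEnvironment(cd)
  tree <- phylogeny(cd)
  ape::write.tree(tree, out("tree.nwk"))
  writeMatrix(comm, out("community.tsv"))
  writeTable(env, out("environment.tsv"))
  if (!is.null(dat$habitats_true)) {
    writeTable(data.frame(plot = names(dat$habitats_true),
                          habitat_true = unname(dat$habitats_true)),
               out("habitats_true.tsv"))
  }
  D <- patristicDistances(tree)
  um <- ultrametricityReport(tree)
  logIt("tree depth spread ", signif(um$spread, 4),
        if (um$ultrametric) " (ultrametric)" else " (not ultrametric)")

  ## ---- MRT habitats ----
  model <- stage("mrt", do.call(mrtFit, c(
    list(comm = comm, env = env, predictors = config$predictors,
         seed = childSeed(seed, "mrt")), config$mrt)))
  habitats <- habitatAssignments(model)
  writeTable(model@frame, out("mrt_nodes.tsv"))
  writeTable(model@cvTable, out("mrt_cv.tsv"))
  writeTable(data.frame(plot = names(habitats), habitat = unname(habitats)),
             out("habitat_assignments.tsv"))
  logIt("mrt: ", sum(model@frame$leaf), " habitat(s), CVRE ",
        signif(model@cvre, 4), ", R2 ", signif(model@rSquared, 4))

  ## ---- indicator species ----
  nHab <- length(unique(habitats))
  if (nHab >= 2L) {
    ivt <- stage("indval", indvalTest(comm, habitats,
                                      n_perm = config$indval$n_perm,
                                      seed = childSeed(seed, "indval")))
    ivLong <- data.frame(
      species = rep(rownames(ivt$indval), ncol(ivt$indval)),
      habitat = rep(colnames(ivt$indval), each = nrow(ivt$indval)),
      A = as.vector(ivt$A), B = as.vector(ivt$B),
      indval = as.vector(ivt$indval))
    writeTable(ivLong, out("indval_matrix.tsv"))
    writeTable(ivt$species, out("indval_species.tsv"))
    logIt("indval: ", sum(ivt$species$p_value <= 0.05, na.rm = TRUE),
          " indicator species at alpha = 0.05")
  } else {
    logIt("indval: skipped, a single habitat was selected")
  }

  ## ---- alpha structure ----
  sesPlot <- stage("alpha", sesAlpha(comm, D, n_null = config$alpha$n_null,
                                     seed = childSeed(seed, "alpha"),
                                     weighted = config$alpha$weighted))
  writeTable(sesPlot, out("ses_plots.tsv"))
  habComm <- habitatAssemblage(comm, habitats)
  sesHab <- stage("alpha_habitat",
                  sesAlpha(habComm, D, n_null = config$alpha$n_null,
                           seed = childSeed(seed, "alpha_habitat"),
                           weighted = config$alpha$weighted))
  writeTable(sesHab, out("ses_habitats.tsv"))
  regs <- stage("regressions", do.call(rbind, lapply(
    intersect(c("elevation", "latitude"), names(env)), function(pv) {
      do.call(rbind, lapply(c("mpd", "mntd"), function(m) {
        regressSES(sesPlot[sesPlot$metric == m, ], env, pv)
      }))
    })))
  writeTable(regs, out("ses_regressions.tsv"))

  ## ---- beta structure + Mantel ----
  sp <- stage("spatial", spatialDistances(env))
  beta <- stage("beta", sesBeta(comm, D, n_null = config$beta$n_null,
                                seed = childSeed(seed, "beta"),
                                weighted = config$beta$weighted))
  for (nm in c("dpw", "dnn", "ses_dpw", "ses_dnn")) {
    writeMatrix(beta[[nm]], out(paste0("beta_", nm, ".tsv")))
  }
  mantelRows <- stage("mantel", {
    rows <- list()
    for (m in c("ses_dpw", "ses_dnn")) {
      B <- beta[[m]]
      for (d in c("elevation", "geographic")) {
        r <- mantelTest(B, sp[[d]], n_perm = config$mantel$n_perm,
                        seed = childSeed(seed, paste0("mantel_", m, "_", d)))
        rows[[length(rows) + 1L]] <- data.frame(
          scale = "plot", kind = "simple", beta = m, predictor = d,
          conditioned_on = NA, r = r$r, p_value = r$p_value,
          n_perm = r$n_perm)
      }
      pr1 <- partialMantelTest(B, sp$geographic, sp$elevation,
                               n_perm = config$mantel$n_perm,
                               seed = childSeed(seed, paste0("pmantel_g_", m)))
      pr2 <- partialMantelTest(B, sp$elevation, sp$geographic,
                               n_perm = config$mantel$n_perm,
                               seed = childSeed(seed, paste0("pmantel_e_", m)))
      rows[[length(rows) + 1L]] <- data.frame(
        scale = "plot", kind = "partial", beta = m, predictor = "geographic",
        conditioned_on = "elevation", r = pr1$r, p_value = pr1$p_value,
        n_perm = pr1$n_perm)
      rows[[length(rows) + 1L]] <- data.frame(
        scale = "plot", kind = "partial", beta = m, predictor = "elevation",
        conditioned_on = "geographic", r = pr2$r, p_value = pr2$p_value,
        n_perm = pr2$n_perm)
    }
    do.call(rbind, rows)
  })

  ## habitat-level beta (centroid coordinates), when >= 4 habitats
  if (nHab >= 4L) {
    habEnv <- stage("habitat_env", {
      agg <- stats::aggregate(env[c("elevation", "latitude",
                                    intersect("longitude", names(env)))],
                              by = list(plot = habitats[env$plot]), FUN = mean)
      agg
    })
    spH <- spatialDistances(habEnv)
    betaH <- stage("beta_habitat",
                   sesBeta(habComm, D, n_null = config$beta$n_null,
                           seed = childSeed(seed, "beta_habitat"),
                           weighted = config$beta$weighted))
    for (nm in c("dpw", "dnn", "ses_dpw", "ses_dnn")) {
      writeMatrix(betaH[[nm]], out(paste0("beta_habitat_", nm, ".tsv")))
    }
    habRows <- lapply(c("ses_dpw", "ses_dnn"), function(m) {
      B <- betaH[[m]][habEnv$plot, habEnv$plot]
      do.call(rbind, lapply(c("elevation", "geographic"), function(d) {
        r <- mantelTest(B, spH[[d]], n_perm = config$mantel$n_perm,
                        seed = childSeed(seed, paste0("hmantel_", m, "_", d)))
        data.frame(scale = "habitat", kind = "simple", beta = m,
                   predictor = d, conditioned_on = NA, r = r$r,
                   p_value = r$p_value, n_perm = r$n_perm)
      }))
    })
    mantelRows <- rbind(mantelRows, do.call(rbind, habRows))
  }
  writeTable(mantelRows, out("mantel_results.tsv"))

  ## ---- manifest ----
  files <- setdiff(list.files(config$output_dir), c("manifest.tsv", "log.txt"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$output_dir, files))))
  writeTable(manifest, out("manifest.tsv"))
  logIt("done: ", length(files), " output file(s)")
  invisible(config$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
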