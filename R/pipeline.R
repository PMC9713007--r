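## Formats, run configuration and the orchestrating pipeline:
## simulate (optional) -> connectome -> metrics -> nbs -> stats -> classify.
## All artifacts are plain text (TSV/CSV/JSON); a manifest records inputs,
## parameters and seeds so identical configurations reproduce identical
## files byte for byte.

#' Read a directory of per-subject ROI time-series TSVs
#'
#' Every file must carry the same ROI header (order may differ; columns are
#' realigned by label against the first subject). Subjects are sorted by
#' file name; any non-numeric or missing cell is an error, not an
#' imputation.
#'
#' @param path Directory of `<subject>.tsv` files.
#' @return Named list of timepoints-by-nodes matrices.
#' @export
readTimeseriesDir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv files in ", path, call. = FALSE)
  ids <- sub("\\.tsv$", "", basename(files))
  ref <- NULL
  out <- vector("list", length(files))
  names(out) <- ids
  for (k in seq_along(files)) {
    df <- read.delim(files[k], check.names = FALSE)
    if (is.null(ref)) ref <- colnames(df)
    if (!setequal(colnames(df), ref)) {
      stop(sprintf("ROI header of %s does not match %s", ids[k], ids[1]),
           call. = FALSE)
    }
    df <- df[, ref, drop = FALSE]     # realign columns by label
    m <- as.matrix(df)
    if (!is.numeric(m) || anyNA(m)) {
      bad <- which(is.na(suppressWarnings(apply(df, 2, as.numeric))), arr.ind = TRUE)
      stop(sprintf("non-numeric or missing value in %s (row %s, column %s)",
                   ids[k], bad[1, 1], ref[bad[1, 2]]), call. = FALSE)
    }
    out[[k]] <- m
  }
  out
}

#' Default pipeline run configuration
#'
#' Nested list of stage settings; any element can be overridden via
#' `modifyList`-style `...` arguments or loaded from a YAML file with
#' [readRunConfig()]. Defaults follow the conventional whole-brain
#' analysis settings (sparsity grid 0.05-0.40 step 0.01, NBS primary
#' p 0.001 with 5000 permutations, 10000/5000 max-statistic permutations,
#' LASSO + linear SVM with C = 1 and 100 x 5-fold CV) with a desk-scale
#' simulated cohort.
#'
#' @param ... Named overrides of the top-level sections (`simulate`,
#'   `connectome`, `metrics`, `nbs`, `stats`, `classify`, `seed`, `paths`).
#' @return List of class `RunConfig`.
#' @export
runConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    paths = list(input = NULL, output = "rsconnectome-run"),
    simulate = list(enabled = TRUE, nPerGroup = 20L, nNodes = 60L,
                    nTimepoints = 196L, baseDensity = 0.1, arCoeff = 0.3,
                    plantedEdges = NULL),
    connectome = list(alpha = 0.1),
    metrics = list(gridLo = 0.05, gridHi = 0.40, gridStep = 0.01,
                   nRef = 20L, louvainRestarts = 10L, smallWorld = TRUE,
                   includeELoc = FALSE),
    nbs = list(pPrimary = 0.001, nPerm = 5000L,
               directions = c("positive", "negative"),
               covariates = character(0)),
    stats = list(nPermGlobal = 10000L, nPermLocal = 5000L,
                 clinicalVars = c("hama", "bprs"),
                 controlVars = c("age", "education", "ftnd")),
    classify = list(C = 1, nFolds = 5L, nRepeats = 100L, lassoRepeats = 10L,
                    lassoFolds = 5L, lambdaRule = "min",
                    selectionMode = "nested", nPerm = 5000L),
    paperConvention = FALSE)
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      modifyList(cfg[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file with any subset of the [runConfig()] sections.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> connectome -> metrics -> nbs -> stats ->
#' classify, writing each stage's artifacts under the output directory plus
#' a `manifest.json` (parameters, seeds, package version, input hashes,
#' stage status). A failure in any stage aborts with the stage name after
#' persisting the partial manifest. Reruns with identical configuration and
#' seed reproduce identical files.
#'
#' @param config A [runConfig()].
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$paths$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "rsConnectome",
                   version = as.character(utils::packageVersion("rsConnectome")),
                   seed = config$seed,
                   ## paths are machine-specific; everything else is recorded
                   parameters = unclass(config)[setdiff(names(config), "paths")],
                   stages = list())
  persist <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  runStage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      persist()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(res)),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  ## -- simulate / ingest -------------------------------------------------
  env <- new.env()
  runStage("simulate", function() {
    if (isTRUE(config$simulate$enabled)) {
      sim <- config$simulate
      cc <- cohortConfig(nPerGroup = sim$nPerGroup, nNodes = sim$nNodes,
                         nTimepoints = sim$nTimepoints,
                         baseDensity = sim$baseDensity,
                         plantedEdges = sim$plantedEdges,
                         arCoeff = sim$arCoeff,
                         seed = childSeed(config$seed, "simulate"))
      cohort <- simulateCohort(cc)
      writeCohort(cohort, file.path(out, "cohort"))
      env$series <- timeSeries(cohort)
      env$pheno <- phenotypes(cohort)
    } else {
      env$series <- readTimeseriesDir(file.path(config$paths$input, "timeseries"))
      env$pheno <- utils::read.csv(file.path(config$paths$input, "phenotypes.csv"))
      env$pheno$group <- factor(env$pheno$group, levels = c("control", "patient"))
      env$series <- env$series[env$pheno$subject_id]
    }
    phenoFile <- if (isTRUE(config$simulate$enabled)) {
      file.path(out, "cohort", "phenotypes.csv")
    } else {
      file.path(config$paths$input, "phenotypes.csv")
    }
    env$hash <- unname(tools::md5sum(phenoFile))
    NULL
  })
  manifest$inputs <- list(phenotype_md5 = env$hash,
                          n_subjects = length(env$series),
                          n_nodes = ncol(env$series[[1]]),
                          n_timepoints = nrow(env$series[[1]]))

  ## -- connectome --------------------------------------------------------
  runStage("connectome", function() {
    alpha <- config$connectome$alpha
    cmDir <- file.path(out, "connectome")
    dir.create(cmDir, showWarnings = FALSE)
    env$stack <- lapply(names(env$series), function(id) {
      cm <- connectivityMatrix(env$series[[id]], alpha = alpha, subjectID = id)
      write.table(format(zValues(cm), digits = 10, trim = TRUE),
                  file.path(cmDir, paste0(id, ".tsv")),
                  sep = "\t", quote = FALSE)
      jsonlite::write_json(list(subject_id = id, alpha = alpha),
                           file.path(cmDir, paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA)
      cm
    })
    names(env$stack) <- names(env$series)
    NULL
  })

  ## -- metrics -----------------------------------------------------------
  runStage("metrics", function() {
    mt <- config$metrics
    grid <- sparsityGrid(mt$gridLo, mt$gridHi, mt$gridStep)
    curves <- do.call(rbind, lapply(env$stack, function(cm) {
      metricCurves(cm, grid, nRef = mt$nRef,
                   seed = childSeed(config$seed, "metrics"),
                   louvainRestarts = mt$louvainRestarts,
                   smallWorld = mt$smallWorld)
    }))
    rownames(curves) <- NULL
    write.table(curves, file.path(out, "metric_curves.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    env$features <- assembleAucFeatures(curves, env$pheno,
                                        includeELoc = mt$includeELoc)
    auc <- assay(env$features, "auc")
    write.table(data.frame(feature = rownames(auc),
                           format(auc, digits = 10, trim = TRUE),
                           check.names = FALSE),
                file.path(out, "auc_features.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    NULL
  })

  ## -- nbs ---------------------------------------------------------------
  runStage("nbs", function() {
    des <- designMatrix(env$pheno, config$nbs$covariates)
    nbsOut <- lapply(config$nbs$directions, function(dir) {
      res <- nbsTest(env$stack, des, pPrimary = config$nbs$pPrimary,
                     nPerm = config$nbs$nPerm, direction = dir,
                     seed = childSeed(config$seed, "nbs"),
                     paperConvention = config$paperConvention)
      comps <- lapply(res@components, function(co) {
        list(n_edges = co$nEdges, nodes = co$nodes, p_perm = co$pPerm)
      })
      for (k in seq_along(res@components)) {
        if (res@components[[k]]$pPerm < 0.05) {
          write.table(res@components[[k]]$edges,
                      file.path(out, sprintf("nbs_%s_component%d.tsv", dir, k)),
                      sep = "\t", quote = FALSE, row.names = FALSE,
                      col.names = c("node_i", "node_j"))
        }
      }
      list(direction = dir, t_critical = res@tCritical,
           n_perm = res@nPerm, components = comps)
    })
    jsonlite::write_json(nbsOut, file.path(out, "nbs.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    NULL
  })

  ## -- stats -------------------------------------------------------------
  runStage("stats", function() {
    des <- designMatrix(env$pheno, config$nbs$covariates)
    fam <- setNames(rowData(env$features)$attribute, rownames(env$features))
    isGlobal <- is.na(rowData(env$features)$roi)
    auc <- assay(env$features, "auc")
    resG <- maxstatPermGLM(auc[isGlobal, , drop = FALSE], des,
                           family = fam[isGlobal],
                           nPerm = config$stats$nPermGlobal,
                           seed = childSeed(config$seed, "stats-global"))
    resL <- maxstatPermGLM(auc[!isGlobal, , drop = FALSE], des,
                           family = fam[!isGlobal],
                           nPerm = config$stats$nPermLocal,
                           seed = childSeed(config$seed, "stats-local"))
    tab <- data.frame(
      feature = c(names(resG@tObserved), names(resL@tObserved)),
      level = rep(c("global", "nodal"), c(length(resG@tObserved),
                                          length(resL@tObserved))),
      t = c(resG@tObserved, resL@tObserved),
      p_perm = c(resG@pPerm, resL@pPerm))
    write.table(tab, file.path(out, "maxstat_glm.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    sig <- tab$feature[tab$level == "global" & tab$p_perm < 0.05]
    clin <- intersect(config$stats$clinicalVars, names(env$pheno))
    ctrl <- intersect(config$stats$controlVars, names(env$pheno))
    if (length(sig) && length(clin)) {
      patients <- env$pheno$subject_id[env$pheno$group == "patient"]
      cc <- clinicalCorrelations(env$features, sig, clin, ctrl,
                                 subjects = patients)
      write.table(cc, file.path(out, "clinical_correlations.csv"), sep = ",",
                  quote = FALSE, row.names = FALSE)
    }
    NULL
  })

  ## -- classify ----------------------------------------------------------
  runStage("classify", function() {
    cl <- config$classify
    cfg <- classifierConfig(C = cl$C, nFolds = cl$nFolds,
                            nRepeats = cl$nRepeats,
                            lassoRepeats = cl$lassoRepeats,
                            lassoFolds = cl$lassoFolds,
                            lambdaRule = cl$lambdaRule,
                            selectionMode = cl$selectionMode,
                            nPerm = cl$nPerm,
                            seed = childSeed(config$seed, "classify"),
                            paperConvention = config$paperConvention)
    report <- crossValidateSvm(env$features, env$pheno$group, cfg)
    perm <- permutationTestAccuracy(env$features, env$pheno$group, cfg,
                                    report = report)
    write.table(report@foldMetrics, file.path(out, "classifier_folds.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(selected = report@selected,
           summary = report@summary,
           p_perm = perm$pPerm),
      file.path(out, "classifier.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    NULL
  })

  persist()
  invisible(manifest)
}
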