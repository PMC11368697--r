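# End-to-end workflow: simulate -> fit -> impute -> uncertainty -> select
# -> evaluate, with a YAML config, per-stage artifacts and a JSON run
# manifest.  The Rscript front end in inst/scripts/spotimpute.R is a thin
# wrapper over runPipeline().

.defaultConfig <- function() {
  list(
    seed = 1L,
    outDir = ".",
    normalization = "none",
    inputs = list(),
    simulate = list(nCells = 200L, nSpots = 100L, nGenes = 100L,
                    nClusters = 5L, grid = c(10L, 10L), noiseSd = 0,
                    dropoutRate = 0.3, fracSpatialGenes = 0.5,
                    smoothSigma = 1.5),
    graph = list(k = 6L, scheme = "inverse_distance"),
    fit = list(mode = "lowrank", K = 256L, lambdaSpa = 0, vClip = NULL,
               epochs = 2000L, learningRate = 0.01, weightDecay = 0.01),
    impute = list(genes = NULL),
    uncertainty = list(nSim = 20L),
    select = list(method = "knee"),
    evaluate = list(nClusters = NULL, shvgMethod = "permutation",
                    nPerm = 999L, fdr = 0.01)
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list), filling unspecified fields with
#' package defaults.
#'
#' @param config path to a YAML config file, or a named list, or `NULL`
#'   for pure defaults.
#' @return Complete configuration list.
#' @export
loadRunConfig <- function(config = NULL) {
  base <- .defaultConfig()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  .mergeConfig(base, config)
}

.pipePath <- function(cfg, ...) file.path(cfg$outDir, paste0(...))

.loadRef <- function(cfg) {
  p <- cfg$inputs$ref %||% .pipePath(cfg, "ref_")
  x <- if (grepl("\\.(csv|tsv)$", p)) readExpressionDelim(p, "cells")
       else readExpressionMtx(p, "cells")
  normalizeExpression(x, cfg$normalization)
}

.loadSt <- function(cfg) {
  p <- cfg$inputs$st %||% .pipePath(cfg, "st_")
  x <- if (grepl("\\.(csv|tsv)$", p)) readExpressionDelim(p, "spots")
       else readExpressionMtx(p, "spots")
  normalizeExpression(x, cfg$normalization)
}

.loadLabels <- function(cfg) {
  p <- cfg$inputs$labels %||% .pipePath(cfg, "labels.csv")
  if (!file.exists(p)) return(NULL)
  df <- read.delim(p, sep = ",")
  setNames(as.character(df[[2]]), df[[1]])
}

.loadCoords <- function(cfg) {
  readCoordsCsv(cfg$inputs$coords %||% .pipePath(cfg, "coords.csv"))
}

.stageSimulate <- function(cfg) {
  s <- cfg$simulate
  sim <- simulateSpatialData(
    nCells = s$nCells, nSpots = s$nSpots, nGenes = s$nGenes,
    nClusters = s$nClusters, grid = unlist(s$grid), noiseSd = s$noiseSd,
    dropoutRate = s$dropoutRate, fracSpatialGenes = s$fracSpatialGenes,
    smoothSigma = s$smoothSigma, seed = cfg$seed)
  writeExpressionMtx(sim$ref, .pipePath(cfg, "ref_"))
  writeExpressionMtx(sim$refCounts, .pipePath(cfg, "ref_counts_"))
  writeExpressionMtx(sim$st, .pipePath(cfg, "st_"))
  writeCoordsCsv(sim$coords, .pipePath(cfg, "coords.csv"))
  write.table(
    data.frame(cell = names(sim$truth$clusterLabels),
               cluster = as.character(sim$truth$clusterLabels)),
    .pipePath(cfg, "labels.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(sim$truth$WTrue, sparse = TRUE),
                  .pipePath(cfg, "w_true.mtx"))
  c("ref_matrix.mtx", "st_matrix.mtx", "coords.csv", "labels.csv",
    "w_true.mtx")
}

.stageFit <- function(cfg) {
  ref <- .loadRef(cfg)
  st <- .loadSt(cfg)
  labels <- .loadLabels(cfg)
  f <- cfg$fit
  graph <- NULL
  if (f$lambdaSpa > 0)
    graph <- buildSpatialGraph(.loadCoords(cfg), k = cfg$graph$k,
                               scheme = cfg$graph$scheme)
  model <- fitTranslation(
    ref, st, mode = f$mode, labels = labels, graph = graph, K = f$K,
    lambdaSpa = f$lambdaSpa, vClip = f$vClip, epochs = f$epochs,
    learningRate = f$learningRate, weightDecay = f$weightDecay,
    seed = cfg$seed)
  saveMappingModel(model, .pipePath(cfg, "model.rds"))
  write.table(lossTrace(model), .pipePath(cfg, "loss_trace.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  c("model.rds", "loss_trace.tsv")
}

.stageImpute <- function(cfg) {
  model <- loadMappingModel(.pipePath(cfg, "model.rds"))
  ref <- .loadRef(cfg)
  labels <- .loadLabels(cfg)
  genes <- cfg$impute$genes
  if (is.character(genes) && length(genes) == 1L && file.exists(genes))
    genes <- readLines(genes)
  if (is.null(genes)) genes <- geneIds(ref)
  imp <- imputeGenes(model, ref, genes, labels = labels)
  writeExpressionDelim(imp, .pipePath(cfg, "imputed.csv"))
  "imputed.csv"
}

.stageUncertainty <- function(cfg) {
  model <- loadMappingModel(.pipePath(cfg, "model.rds"))
  ref <- .loadRef(cfg)
  st <- .loadSt(cfg)
  labels <- .loadLabels(cfg)
  if (is.null(labels)) stop("uncertainty stage requires cluster labels")
  countsPrefix <- .pipePath(cfg, "ref_counts_")
  counts <- if (file.exists(paste0(countsPrefix, "matrix.mtx")))
    readExpressionMtx(countsPrefix, "cells") else ref
  vars <- scoreVariance(model, ref, st, labels,
                        nSim = cfg$uncertainty$nSim, seed = cfg$seed + 1L)
  al <- alignGenes(ref, st)
  input <- if (model@clusterMode)
    aggregateByCluster(ref[, al$refIndex], labels) else ref[, al$refIndex]
  pred <- translateExpression(model, input)
  feats <- uncertaintyFeatures(counts, pred)
  um <- fitUncertainty(feats, vars)
  unc <- predictUncertainty(um, feats)
  out <- merge(feats, unc, by = "gene", sort = FALSE)
  out$bootVariance <- as.numeric(vars[out$gene])
  write.table(out, .pipePath(cfg, "uncertainty.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  "uncertainty.tsv"
}

.stageSelect <- function(cfg) {
  unc <- read.delim(.pipePath(cfg, "uncertainty.tsv"))
  model <- loadMappingModel(.pipePath(cfg, "model.rds"))
  ref <- .loadRef(cfg)
  st <- .loadSt(cfg)
  labels <- .loadLabels(cfg)
  al <- alignGenes(ref, st)
  input <- if (model@clusterMode)
    aggregateByCluster(ref[, al$refIndex], labels) else ref[, al$refIndex]
  pred <- translateExpression(model, input)
  css <- cssPerGene(pred, st[, al$stIndex])
  sel <- selectGenesByKnee(css, unc, method = cfg$select$method,
                           seed = cfg$seed)
  writeGeneList(sel$selected, .pipePath(cfg, "selected_genes.txt"))
  write.table(sel$curve, .pipePath(cfg, "curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  c("selected_genes.txt", "curve.tsv")
}

.stageEvaluate <- function(cfg) {
  model <- loadMappingModel(.pipePath(cfg, "model.rds"))
  ref <- .loadRef(cfg)
  st <- .loadSt(cfg)
  labels <- .loadLabels(cfg)
  coords <- .loadCoords(cfg)
  graph <- buildSpatialGraph(coords, k = cfg$graph$k,
                             scheme = cfg$graph$scheme)
  al <- alignGenes(ref, st)
  input <- if (model@clusterMode)
    aggregateByCluster(ref[, al$refIndex], labels) else ref[, al$refIndex]
  pred <- translateExpression(model, input)
  obs <- st[, al$stIndex]
  gene <- cssSummary(pred, obs, "gene")
  cell <- cssSummary(pred, obs, "cell")
  write.table(data.frame(gene = names(gene$scores), css = gene$scores),
              .pipePath(cfg, "css.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(spot = names(cell$scores), css = cell$scores),
              .pipePath(cfg, "css_cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  uncPath <- .pipePath(cfg, "uncertainty.tsv")
  if (file.exists(uncPath)) {
    unc <- read.delim(uncPath)
    curve <- cssByUncertaintyQuantile(gene$scores, unc)
    write.table(curve, .pipePath(cfg, "curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  nClusters <- cfg$evaluate$nClusters %||%
    max(2L, length(unique(labels %||% c("a", "b"))))
  labObs <- spatialAgglomerativeClustering(obs, graph, nClusters)
  labImp <- spatialAgglomerativeClustering(pred, graph, nClusters)
  conc <- clusteringConcordance(labImp, labObs)
  jsonlite::write_json(conc, .pipePath(cfg, "clustering.json"),
                       auto_unbox = TRUE, digits = NA)
  truthTest <- moransITest(obs, graph, method = cfg$evaluate$shvgMethod,
                           nPerm = cfg$evaluate$nPerm, seed = cfg$seed)
  impTest <- moransITest(pred, graph, method = cfg$evaluate$shvgMethod,
                         nPerm = cfg$evaluate$nPerm, seed = cfg$seed)
  truthSig <- truthTest$q < cfg$evaluate$fdr
  if (any(truthSig) && !all(truthSig)) {
    prc <- shvgPrc(truthSig, impTest$z)
    out <- prc$curve
    out$auprc <- prc$auprc
    write.table(out, .pipePath(cfg, "shvg_prc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  writeShvgResults(truthTest, .pipePath(cfg, "shvg_observed.tsv"),
                   fdr = cfg$evaluate$fdr)
  c("css.tsv", "css_cells.tsv", "clustering.json", "shvg_observed.tsv")
}

#' Run the imputation workflow
#'
#' Executes one stage or the whole chain
#' (`simulate -> fit -> impute -> uncertainty -> select -> evaluate`),
#' writing per-stage artifacts plus a JSON run manifest (config echo,
#' seed, package version, stage timings and artifact checksums) into
#' `config$outDir`.  Stages never modify their inputs; identical configs
#' and seeds reproduce identical artifacts.
#'
#' @param config YAML path or config list (see [loadRunConfig()]).
#' @param command one of `"simulate"`, `"fit"`, `"impute"`,
#'   `"uncertainty"`, `"select"`, `"evaluate"`, `"all"`.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = NULL,
                        command = c("all", "simulate", "fit", "impute",
                                    "uncertainty", "select", "evaluate")) {
  command <- match.arg(command)
  cfg <- loadRunConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (command == "all")
    c("simulate", "fit", "impute", "uncertainty", "select", "evaluate")
  else command
  runners <- list(simulate = .stageSimulate, fit = .stageFit,
                  impute = .stageImpute, uncertainty = .stageUncertainty,
                  select = .stageSelect, evaluate = .stageEvaluate)
  manifest <- list(
    config = cfg,
    packageVersion = as.character(utils::packageVersion("spotimpute")),
    stages = list())
  for (stg in stages) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(runners[[stg]](cfg), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stg, conditionMessage(e)),
           call. = FALSE))
    paths <- file.path(cfg$outDir, files)
    manifest$stages[[stg]] <- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      artifacts = as.list(setNames(unname(tools::md5sum(paths)), files)))
  }
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
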