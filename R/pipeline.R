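# End-to-end orchestration: simulate -> segment/quantify -> DE/TE/classify ->
# enrichment -> melt-curve Tm, from one config, with a reproducibility
# manifest. Stage seeds are fanned out from the global seed by a stage-name
# hash (stageSeed), so any stage can be rerun independently yet reproducibly.

writeTSV <- function(df, path, rownameCol = NULL) {
  if (!is.null(rownameCol)) {
    df <- cbind(stats::setNames(data.frame(rownames(df)), rownameCol), df)
    rownames(df) <- NULL
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a synthetic field as a multi-page 16-bit TIFF
#'
#' Page 1 is the nuclear channel, page 2 the reporter channel, both scaled by
#' 1/65535 into the 16-bit range.
#'
#' @param field a [SyntheticField-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeFieldTIFF <- function(field, path) {
  chans <- lapply(list(nuclearChannel(field), reporterChannel(field)),
                  function(m) round(pmin(pmax(m, 0), 65535)) / 65535)
  tiff::writeTIFF(chans, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel field TIFF written by [writeFieldTIFF()]
#'
#' @param path TIFF path.
#' @return list with \code{nuclear} and \code{reporter} matrices in photon
#'   units.
#' @export
readFieldTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopIfNot(length(pages) >= 2, "expected a two-page TIFF")
  list(nuclear = pages[[1]] * 65535, reporter = pages[[2]] * 65535)
}

#' Default pipeline configuration
#'
#' Demo-scale settings with the analysis thresholds at their defaults
#' (eccentricity 0.875, baseMean 20, padj 0.01/0.05/0.05, TPM > 1); the
#' simulation sizes are kept small so a full run finishes in minutes.
#'
#' @return nested list of stage parameters; see the vignette for the schema.
#' @export
defaultPipelineConfig <- function() {
  list(
    stages = c("simulate-images", "quantify", "simulate-counts", "classify",
               "gsea", "go", "melt"),
    images = list(
      nFieldsPerCondition = 2L,
      conditions = list(WT = list(fociPerCell = 3),
                        V11A = list(fociPerCell = 0.8)),
      fieldSpec = list(imageSize = c(256L, 256L), nCells = 8L,
                       cellRadius = c(28, 2), nucleusRadius = c(10, 1))),
    quantify = list(reference = "WT", maxEccentricity = 0.875,
                    speckleRadius = 6, fociMinArea = 5, rescaleFactor = 1,
                    regularization = 0.05, thresholdMode = "otsu",
                    nucleusMinArea = 50, minCells = 100L),
    counts = list(nGenes = 500L,
                  classes = c(TE_UP = 30L, TE_DOWN = 30L, BUFFERING_UP = 30L,
                              BUFFERING_DOWN = 30L, RNA_ABUNDANCE_UP = 30L,
                              RNA_ABUNDANCE_DOWN = 30L),
                  effectLfc = 2, baselineMean = 200, dispersion = 0.02),
    classify = list(baseMeanMin = 20, padjBuffering = 0.01, padjSig = 0.05),
    gsea = list(nPerm = 1000L, weightP = 1),
    go = list(tpmThreshold = 1, padjCutoff = 0.05),
    melt = list(trueTm = 55, steepness = 2, noiseSd = 20, smoothWindow = 5L)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

logThreshold <- function(log, what, value) {
  msg <- sprintf("threshold %s = %s", what, paste(value, collapse = ", "))
  message(msg)
  c(log, msg)
}

#' Run the analysis pipeline end to end
#'
#' Executes the selected stages in dependency order from a single config and
#' seed, writing every output as TSV/TIFF plus a JSON manifest recording the
#' package version, seed, parameters, per-output row counts and MD5 content
#' hashes. Reruns with the same config and seed are byte-identical. A failing
#' stage halts the run with a stage-named error and leaves a FAILED marker
#' next to the partial outputs.
#'
#' @param config a nested list overriding [defaultPipelineConfig()], or the
#'   path of a YAML file with the same structure.
#' @param outDir output directory (created if needed).
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @return The manifest, invisibly; also written to
#'   \code{file.path(outDir, "manifest.json")}.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("sgribo_run_"),
                        seed = 1L) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  stages <- cfg$stages
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  log <- character()
  state <- new.env(parent = emptyenv())

  addOutput <- function(path, rows) {
    outputs[[basename(path)]] <<- list(path = basename(path), rows = rows)
  }
  runStage <- function(name, fun) {
    if (!name %in% stages) return(invisible())
    ok <- tryCatch({ fun(stageSeed(seed, name)); TRUE },
                   error = function(e) {
                     writeLines(sprintf("stage %s failed: %s", name,
                                        conditionMessage(e)),
                                file.path(outDir, "FAILED"))
                     stop(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)), call. = FALSE)
                   })
    invisible(ok)
  }

  runStage("simulate-images", function(sd) {
    fields <- list()
    meta <- list()
    i <- 0L
    for (cond in names(cfg$images$conditions)) {
      over <- cfg$images$conditions[[cond]]
      specArgs <- mergeConfig(cfg$images$fieldSpec, over)
      specArgs <- lapply(specArgs, unlist)  # YAML sequences arrive as lists
      spec <- do.call(fieldSpec, specArgs)
      for (rep in seq_len(cfg$images$nFieldsPerCondition)) {
        i <- i + 1L
        f <- generateField(spec, stageSeed(sd, paste0(cond, rep)))
        tag <- sprintf("field_%s_r%d", cond, rep)
        writeFieldTIFF(f, file.path(outDir, paste0(tag, ".tif")))
        fields[[tag]] <- f
        meta[[tag]] <- data.frame(field = tag, condition = cond,
                                  replicate = rep)
        tc <- truthCells(f); tc$field <- tag
        addOutput(writeTSV(tc, file.path(outDir, paste0(tag, "_truth_cells.tsv"))),
                  nrow(tc))
      }
    }
    state$fields <- fields
    state$fieldMeta <- do.call(rbind, meta)
    addOutput(writeTSV(state$fieldMeta, file.path(outDir, "fields.tsv")),
              nrow(state$fieldMeta))
  })

  runStage("quantify", function(sd) {
    stopIfNot(!is.null(state$fields), "quantify requires simulate-images")
    q <- cfg$quantify
    log <<- logThreshold(log, "max_eccentricity", q$maxEccentricity)
    cells <- list()
    for (tag in names(state$fields)) {
      f <- state$fields[[tag]]
      res <- quantifyField(nuclearChannel(f), reporterChannel(f),
                           rescaleFactor = q$rescaleFactor,
                           nucleusMinArea = q$nucleusMinArea,
                           regularization = q$regularization,
                           speckleRadius = q$speckleRadius,
                           thresholdMode = q$thresholdMode,
                           fociMinArea = q$fociMinArea,
                           maxEccentricity = q$maxEccentricity)
      ct <- res$cellTable
      m <- state$fieldMeta[state$fieldMeta$field == tag, ]
      ct$condition <- m$condition
      ct$replicate <- m$replicate
      ct$field <- tag
      cells[[tag]] <- ct
      addOutput(writeTSV(res$fociTable,
                         file.path(outDir, paste0(tag, "_foci.tsv"))),
                nrow(res$fociTable))
    }
    allCells <- do.call(rbind, cells)
    rownames(allCells) <- NULL
    addOutput(writeTSV(allCells, file.path(outDir, "cells.tsv")),
              nrow(allCells))
    summ <- summarizeCondition(allCells, minCells = q$minCells)
    addOutput(writeTSV(summ, file.path(outDir, "condition_summary.tsv")),
              nrow(summ))
    if (q$reference %in% allCells$condition &&
        length(unique(allCells$condition)) > 1) {
      cmp <- compareConditions(allCells$total_foci_area, allCells$condition,
                               q$reference)
      addOutput(writeTSV(cmp, file.path(outDir, "condition_tests.tsv")),
                nrow(cmp))
      dev <- checkExpressionDeviation(allCells$reporter_mean,
                                      allCells$condition, q$reference)
      addOutput(writeTSV(dev, file.path(outDir, "expression_deviation.tsv")),
                nrow(dev))
    }
    state$cells <- allCells
  })

  runStage("simulate-counts", function(sd) {
    cc <- cfg$counts
    design <- countDesign(nGenes = cc$nGenes, classes = unlist(cc$classes),
                          effectLfc = cc$effectLfc,
                          baselineMean = cc$baselineMean,
                          dispersion = cc$dispersion, seed = sd)
    se <- generateCounts(design)
    state$se <- se
    counts <- SummarizedExperiment::assay(se, "counts")
    addOutput(writeTSV(as.data.frame(counts),
                       file.path(outDir, "counts.tsv"), "gene"),
              nrow(counts))
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    addOutput(writeTSV(cd, file.path(outDir, "metadata.tsv")), nrow(cd))
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    addOutput(writeTSV(rd, file.path(outDir, "truth_genes.tsv"), "gene"),
              nrow(rd))
  })

  runStage("classify", function(sd) {
    stopIfNot(!is.null(state$se), "classify requires simulate-counts")
    se <- state$se
    counts <- SummarizedExperiment::assay(se, "counts")
    cd <- SummarizedExperiment::colData(se)
    cl <- cfg$classify
    log <<- logThreshold(log, "basemean_min", cl$baseMeanMin)
    log <<- logThreshold(log, "padj_rna_buffering", cl$padjBuffering)
    log <<- logThreshold(log, "padj_sig", cl$padjSig)
    rnaIdx <- cd$assay == "RNA"
    riboIdx <- cd$assay == "RIBO"
    rna <- shrinkLFC(nbWaldTest(counts[, rnaIdx], cd$condition[rnaIdx]))
    ribo <- shrinkLFC(nbWaldTest(counts[, riboIdx], cd$condition[riboIdx]))
    te <- teInteractionTest(counts[, rnaIdx], counts[, riboIdx],
                            cd$condition[rnaIdx], cd$condition[riboIdx])
    cls <- classifyGenes(rna, ribo, te, baseMeanMin = cl$baseMeanMin,
                         padjBuffering = cl$padjBuffering,
                         padjSig = cl$padjSig)
    state$rna <- rna; state$ribo <- ribo; state$te <- te; state$cls <- cls
    addOutput(writeTSV(rna, file.path(outDir, "de_rna.tsv"), "gene"), nrow(rna))
    addOutput(writeTSV(ribo, file.path(outDir, "de_ribo.tsv"), "gene"), nrow(ribo))
    addOutput(writeTSV(te, file.path(outDir, "te.tsv"), "gene"), nrow(te))
    addOutput(writeTSV(cls, file.path(outDir, "classification.tsv"), "gene"),
              nrow(cls))
    reg <- deltaTeRnaRegression(te$te_log2FC, rna$log2FC)
    addOutput(writeTSV(as.data.frame(reg),
                       file.path(outDir, "te_rna_regression.tsv")), 1L)
  })

  runStage("gsea", function(sd) {
    stopIfNot(!is.null(state$rna), "gsea requires classify")
    truth <- SummarizedExperiment::rowData(state$se)
    genes <- rownames(state$rna)
    sets <- list(planted_rna_up = genes[truth$rna_lfc > 0],
                 planted_rna_down = genes[truth$rna_lfc < 0])
    sets <- Filter(length, sets)
    writeGMT(sets, file.path(outDir, "gene_sets.gmt"))
    outputs[["gene_sets.gmt"]] <<- list(path = "gene_sets.gmt",
                                        rows = length(sets))
    ranked <- rankGenes(stats::setNames(state$rna$log2FC, genes))
    addOutput(writeTSV(data.frame(gene = names(ranked), score = ranked),
                       file.path(outDir, "ranking.tsv")), length(ranked))
    res <- prerankedGSEA(ranked, sets, weightP = cfg$gsea$weightP,
                         nPerm = cfg$gsea$nPerm, seed = sd)
    addOutput(writeTSV(res, file.path(outDir, "gsea.tsv")), nrow(res))
    state$gsea <- res
  })

  runStage("go", function(sd) {
    stopIfNot(!is.null(state$cls), "go requires classify")
    counts <- SummarizedExperiment::assay(state$se, "counts")
    rnaIdx <- SummarizedExperiment::colData(state$se)$assay == "RNA"
    lens <- withSeed(stageSeed(sd, "lengths"),
                     exp(rnorm(nrow(counts), log(1500), 0.5)))
    tpm <- computeTPM(counts[, rnaIdx], lens)
    log <<- logThreshold(log, "tpm_background", cfg$go$tpmThreshold)
    bg <- buildBackground(tpm, cfg$go$tpmThreshold)
    truth <- SummarizedExperiment::rowData(state$se)
    annotation <- split(rownames(counts), truth$class)
    study <- intersect(rownames(state$cls)[state$cls$label != "NS"], bg)
    res <- goOverrepresentation(study, bg, annotation,
                                padjCutoff = cfg$go$padjCutoff)
    addOutput(writeTSV(res, file.path(outDir, "go.tsv")), nrow(res))
    state$go <- res
  })

  runStage("melt", function(sd) {
    mc <- cfg$melt
    curve <- generateMeltCurve(mc$trueTm, steepness = mc$steepness,
                               noiseSd = mc$noiseSd, seed = sd)
    addOutput(writeTSV(curve, file.path(outDir, "melt_curve.tsv")),
              nrow(curve))
    est <- meltCurveTm(curve, smoothWindow = mc$smoothWindow)
    addOutput(writeTSV(data.frame(tm = est$tm, true_tm = mc$trueTm,
                                  smooth_window = est$smoothWindow),
                       file.path(outDir, "tm.tsv")), 1L)
    state$tm <- est
  })

  files <- vapply(outputs, `[[`, character(1), "path")
  md5 <- tools::md5sum(file.path(outDir, files))
  manifest <- list(
    package = "sgribo",
    version = as.character(utils::packageVersion("sgribo")),
    seed = seed,
    stages = as.list(stages),
    parameters = cfg[setdiff(names(cfg), "stages")],
    log = as.list(log),
    outputs = lapply(names(outputs), function(nm)
      list(file = outputs[[nm]]$path, rows = outputs[[nm]]$rows,
           md5 = unname(md5[[file.path(outDir, outputs[[nm]]$path)]])))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
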