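# End-to-end pipeline: simulate (or load) -> community structure ->
# habitat association -> co-occurrence network -> environmental fit,
# with per-stage TSV outputs and one machine-readable JSON report.

#' Default pipeline configuration
#'
#' Every parameter has a default; the configuration round-trips through
#' JSON serialization unchanged.
#'
#' @param seed master seed; deterministic per-stage sub-seeds are derived
#'   from it.
#' @return nested named list understood by [runPipeline()].
#' @export
defaultConfig <- function(seed = 1) {
  list(
    schema = "topomicro-config/1",
    seed = as.integer(seed),
    simulate = list(enabled = TRUE, nRows = 5L, nCols = 6L,
                    quadratSize = 20, nOtus = 300L,
                    specialistFraction = 0.2, effectLogFold = log(8),
                    depth = 10000L, overdispersion = 0.005,
                    spatialRange = 40),
    input = list(otuTable = NULL, metadata = NULL),
    community = list(enabled = TRUE, k = 2L, nStarts = 10L,
                     rarefactionPoints = 5L),
    association = list(enabled = TRUE, alpha = 0.05, minRelAbund = 1e-4,
                       fallbackNPerm = 999L),
    network = list(enabled = TRUE, rThresh = 0.7, pThresh = 0.01,
                   nEst = 20L, nPerm = 100L, perHabitat = FALSE,
                   topOtus = 50L),
    envfit = list(enabled = TRUE, nPerm = 999L, transform = "hellinger"))
}

# merge user overrides into the defaults (shallow per stage)
.mergeConfig <- function(cfg) {
  base <- defaultConfig(if (!is.null(cfg$seed)) cfg$seed else 1)
  for (stage in names(base)) {
    if (is.list(base[[stage]]) && !is.null(cfg[[stage]])) {
      for (k in names(cfg[[stage]])) base[[stage]][[k]] <- cfg[[stage]][[k]]
    } else if (!is.null(cfg[[stage]])) {
      base[[stage]] <- cfg[[stage]]
    }
  }
  base
}

.validateConfig <- function(cfg) {
  bad <- function(msg, cls)
    stop(errorCondition(msg, class = c(cls, "topomicroConfigError",
                                       "error", "condition")))
  a <- cfg$association
  if (a$alpha <= 0 || a$alpha >= 1)
    bad("association alpha must lie in (0, 1)",
        "topomicroInvalidThresholdError")
  n <- cfg$network
  if (n$rThresh < 0 || n$rThresh >= 1 || n$pThresh <= 0 || n$pThresh > 1)
    bad("network thresholds out of range", "topomicroInvalidThresholdError")
  if (!cfg$simulate$enabled &&
      (is.null(cfg$input$otuTable) || is.null(cfg$input$metadata)))
    bad("simulation disabled but no input otuTable/metadata given",
        "topomicroMissingInputError")
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes per-stage TSV
#' outputs and a versioned JSON report into `outputDir`. Identical
#' configuration and seed reproduce the report byte-for-byte.
#'
#' @param config configuration list (see [defaultConfig()]); missing
#'   entries are filled with defaults.
#' @param outputDir directory for outputs (created if needed).
#' @param verbose log stage progress to stderr.
#' @return invisibly, the report list (also written to
#'   `outputDir/report.json`).
#' @export
runPipeline <- function(config = defaultConfig(), outputDir = tempdir(),
                        verbose = FALSE) {
  cfg <- .validateConfig(.mergeConfig(config))
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (verbose) message(sprintf(...))
  seed <- cfg$seed
  report <- list(schema = "topomicro-report/1", seed = seed,
                 config = cfg[setdiff(names(cfg), "schema")])

  # --- inputs -------------------------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    log("stage simulate: %dx%d grid, %d OTUs, seed %d",
        cfg$simulate$nRows, cfg$simulate$nCols, cfg$simulate$nOtus, seed)
    g <- generateLayout(cfg$simulate$nRows, cfg$simulate$nCols,
                        cfg$simulate$quadratSize, seed = seed)
    env <- generateEnvironment(g$layout, g$habitat, seed = seed)
    otu <- generateOtuTable(g$layout, g$habitat,
                            nOtus = cfg$simulate$nOtus,
                            specialistFraction = cfg$simulate$specialistFraction,
                            effectLogFold = cfg$simulate$effectLogFold,
                            depth = cfg$simulate$depth,
                            overdispersion = cfg$simulate$overdispersion,
                            spatialRange = cfg$simulate$spatialRange,
                            seed = seed)
    layout <- g$layout; habitat <- g$habitat
    writeOtuTable(otu, file.path(outputDir, "otu_table.tsv"))
    writeMetadata(layout, habitat, env,
                  file.path(outputDir, "metadata.tsv"))
    writeGroundTruth(otu, file.path(outputDir, "ground_truth.tsv"))
  } else {
    log("stage load: %s", cfg$input$otuTable)
    otu <- readOtuTable(cfg$input$otuTable, metadata = cfg$input$metadata)
    layout <- gridLayout(otu)
    habitat <- HabitatMap(habitats(otu))
    env <- envData(otu)
    env$elevation <- NULL
    env <- cbind(elevation = as.data.frame(colData(otu))$elevation, env)
    rownames(env) <- colnames(otu)
  }
  counts <- .sampleCounts(otu)
  habf <- .habitatFactor(habitat, rownames(counts))

  # --- community structure ------------------------------------------------
  if (isTRUE(cfg$community$enabled)) {
    log("stage community")
    rk <- richnessKruskal(counts, habf)
    utils::write.table(rk$richness, file.path(outputDir, "richness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    venn <- partitionOtus(counts, habf)
    d <- brayCurtis(counts)
    dm <- as.matrix(d)
    utils::write.table(data.frame(sample_id = rownames(dm), dm,
                                  check.names = FALSE),
                       file.path(outputDir, "dissimilarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ord <- nmdsOrdination(d, k = cfg$community$k,
                          nStarts = cfg$community$nStarts,
                          seed = .subSeed(seed, 2L))
    utils::write.table(data.frame(sample_id = rownames(ordinationPoints(ord)),
                                  ordinationPoints(ord)),
                       file.path(outputDir, "ordination.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dmin <- min(rowSums(counts))
    depths <- unique(pmax(1L, round(seq(1, dmin,
                                        length.out = cfg$community$rarefactionPoints))))
    rar <- rarefyExpected(counts, depths)
    utils::write.table(data.frame(sample_id = rownames(rar), rar,
                                  check.names = FALSE),
                       file.path(outputDir, "rarefaction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tern <- ternaryEnrichment(counts, habf)
    utils::write.table(tern, file.path(outputDir, "ternary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$community <- list(
      richness = list(H = rk$H, df = rk$df, p = rk$p,
                      perHabitat = rk$summary),
      venn = list(regions = as.list(vennRegions(venn)),
                  total = venn@total,
                  exclusivityPct = venn@exclusivityPct),
      nmds = list(stress = ordinationStress(ord), k = cfg$community$k))
  }

  # --- habitat association ------------------------------------------------
  if (isTRUE(cfg$association$enabled)) {
    log("stage tt-test")
    assoc <- torusTest(counts, habf, layout,
                       alpha = cfg$association$alpha,
                       minRelAbund = cfg$association$minRelAbund,
                       fallbackNPerm = cfg$association$fallbackNPerm,
                       seed = .subSeed(seed, 3L))
    writeAssociations(assoc, file.path(outputDir, "associations.tsv"))
    smry <- summarizeAssociations(assoc)
    smry$vennPositive <- as.list(smry$vennPositive)
    smry$vennNegative <- as.list(smry$vennNegative)
    report$association <- c(list(nullType = assoc@nullType,
                                 nMaps = assoc@nMaps), smry)
  }

  # --- co-occurrence network ----------------------------------------------
  if (isTRUE(cfg$network$enabled)) {
    log("stage network")
    keep <- order(colSums(counts), decreasing = TRUE)
    keep <- keep[seq_len(min(cfg$network$topOtus, ncol(counts)))]
    sub <- counts[, sort(keep), drop = FALSE]
    netSummary <- function(m, s) {
      net <- suppressWarnings(
        inferNetwork(m, rThresh = cfg$network$rThresh,
                     pThresh = cfg$network$pThresh, nEst = cfg$network$nEst,
                     nPerm = cfg$network$nPerm, seed = s))
      list(net = net, summary = networkSummary(net))
    }
    if (isTRUE(cfg$network$perHabitat)) {
      nets <- lapply(levels(habf), function(h)
        netSummary(sub[habf == h, colSums(sub[habf == h, , drop = FALSE]) > 0,
                       drop = FALSE],
                   .subSeed(seed, 40L + match(h, levels(habf)))))
      names(nets) <- levels(habf)
      for (h in names(nets)) {
        writeEdgeList(nets[[h]]$net,
                      file.path(outputDir, paste0("network_", h, ".tsv")))
        writeGexf(nets[[h]]$net,
                  file.path(outputDir, paste0("network_", h, ".gexf")))
      }
      report$network <- lapply(nets, `[[`, "summary")
    } else {
      ns <- netSummary(sub, .subSeed(seed, 4L))
      writeEdgeList(ns$net, file.path(outputDir, "network_edges.tsv"))
      writeGexf(ns$net, file.path(outputDir, "network.gexf"))
      report$network <- ns$summary
    }
  }

  # --- environmental fit --------------------------------------------------
  if (isTRUE(cfg$envfit$enabled)) {
    log("stage envfit")
    if (!exists("ord", inherits = FALSE))
      ord <- nmdsOrdination(brayCurtis(counts), k = 2,
                            seed = .subSeed(seed, 2L))
    envNum <- env[, vapply(env, is.numeric, logical(1)), drop = FALSE]
    ef <- fitEnvVectors(ord, envNum, nPerm = cfg$envfit$nPerm,
                        seed = .subSeed(seed, 5L))
    utils::write.table(fitTable(ef), file.path(outputDir, "envfit.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rda <- rdaExplained(counts, envNum, transform = cfg$envfit$transform)
    report$envfit <- list(
      vectors = fitTable(ef),
      rda = list(proportion = rda$proportion,
                 explainedPct = round(100 * rda$proportion, 2),
                 nAxes = length(rda$eig)))
  }

  path <- file.path(outputDir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  log("report written to %s", path)
  invisible(report)
}
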