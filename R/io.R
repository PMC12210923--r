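# Plain-text interchange: TSV readers/writers for count tables, quadrat
# metadata and ground truth, plus optional BIOM input.

#' Write an OTU table as TSV
#'
#' First column `sample_id`, remaining columns one per OTU, integer cells.
#'
#' @param otu an [OtuExperiment-class] or samples x OTUs count matrix.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeOtuTable <- function(otu, file) {
  counts <- .sampleCounts(otu)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an OTU table from TSV or BIOM
#'
#' @param file path to a TSV written by [writeOtuTable()] (first column
#'   `sample_id`) or a BIOM file (requires the `biomformat` package).
#' @param metadata optional path to a metadata TSV written by
#'   [writeMetadata()]; when given, layout, habitat and environmental
#'   covariates are attached.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return An [OtuExperiment-class].
#' @export
readOtuTable <- function(file, metadata = NULL, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(file)
    m <- as.matrix(biomformat::biom_data(b))   # OTUs x samples
    counts <- t(m)
  } else {
    df <- utils::read.table(file, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(df[, -1L, drop = FALSE])
    rownames(counts) <- df[[1L]]
  }
  if (is.null(metadata)) return(OtuExperiment(counts))
  md <- readMetadata(metadata)
  ids <- rownames(counts)
  miss <- setdiff(ids, md$meta$quadrat_id)
  if (length(miss))
    stop(errorCondition(
      paste("metadata is missing quadrat(s):", paste(miss, collapse = ", ")),
      class = c("topomicroSampleMismatchError", "error", "condition")))
  OtuExperiment(counts, layout = md$layout, habitat = md$habitat,
                env = md$env)
}

#' Write quadrat metadata (layout + habitat + environment) as one TSV
#'
#' One row per quadrat keyed by `quadrat_id`, with grid position,
#' elevation, habitat label and any environmental covariates.
#'
#' @param layout a [PlotLayout-class].
#' @param hab a [HabitatMap-class].
#' @param env optional environment data.frame (rownames = quadrat ids).
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeMetadata <- function(layout, hab, env = NULL, file) {
  q <- layout@quadrats
  habf <- .habitatFactor(hab, q$quadrat_id)
  df <- data.frame(quadrat_id = q$quadrat_id, row = q$row, col = q$col,
                   elevation = q$elevation, habitat = as.character(habf),
                   stringsAsFactors = FALSE)
  attr(df, "grid") <- c(layout@nRows, layout@nCols)
  if (!is.null(env)) {
    env <- as.data.frame(env)
    df <- cbind(df, env[match(q$quadrat_id, rownames(env)),
                        setdiff(colnames(env), colnames(df)),
                        drop = FALSE])
  }
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid\t%d\t%d\t%g", layout@nRows, layout@nCols,
                     layout@quadratSize), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read quadrat metadata TSV
#'
#' @param file path written by [writeMetadata()].
#' @return list with `layout`, `habitat`, `env` (data.frame of the
#'   remaining covariate columns) and `meta` (the full table).
#' @export
readMetadata <- function(file) {
  first <- readLines(file, n = 1L)
  grid <- NULL
  skip <- 0L
  if (startsWith(first, "# grid")) {
    parts <- strsplit(first, "\t")[[1L]]
    grid <- as.numeric(parts[2:4])
    skip <- 1L
  }
  df <- utils::read.table(file, sep = "\t", header = TRUE, skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  need <- c("quadrat_id", "row", "col", "elevation", "habitat")
  if (!all(need %in% colnames(df)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(df$habitat) || any(df$habitat == ""))
    stop(errorCondition(
      paste("missing habitat label for quadrat(s):",
            paste(df$quadrat_id[is.na(df$habitat) | df$habitat == ""],
                  collapse = ", ")),
      class = c("topomicroMissingHabitatError", "error", "condition")))
  if (is.null(grid)) grid <- c(max(df$row) + 1, max(df$col) + 1, 20)
  layout <- PlotLayout(grid[1L], grid[2L], grid[3L],
                       df[, c("row", "col", "quadrat_id", "elevation")])
  habitat <- HabitatMap(stats::setNames(df$habitat, df$quadrat_id))
  envCols <- setdiff(colnames(df), need)
  env <- df[, envCols, drop = FALSE]
  rownames(env) <- df$quadrat_id
  list(layout = layout, habitat = habitat,
       env = if (ncol(env)) env else NULL, meta = df)
}

#' Write the simulated ground truth as TSV
#' @param otu an [OtuExperiment-class] carrying ground truth, or the
#'   ground-truth data.frame itself.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeGroundTruth <- function(otu, file) {
  gt <- if (is.data.frame(otu)) otu else groundTruth(otu)
  if (is.null(gt)) stop("no ground truth available", call. = FALSE)
  utils::write.table(gt, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write an association table as TSV
#' @param res an [AssociationResult-class].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeAssociations <- function(res, file) {
  utils::write.table(associations(res), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a network edge list as TSV
#'
#' Columns `otu_i`, `otu_j`, `r`, `p`, `sign`, `module_i`, `module_j`.
#'
#' @param net a [CorrelationNetwork-class].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeEdgeList <- function(net, file) {
  e <- networkEdges(net)
  mods <- stats::setNames(networkNodes(net)$module, networkNodes(net)$otu)
  e$module_i <- if (nrow(e)) unname(mods[e$otu_i]) else integer(0)
  e$module_j <- if (nrow(e)) unname(mods[e$otu_j]) else integer(0)
  utils::write.table(e, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
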