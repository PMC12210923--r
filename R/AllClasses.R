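#' @importFrom methods new is validObject setValidity show slot as
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Canonical topographic habitat levels
#'
#' The three terrain habitats used throughout the package, in the fixed
#' reporting order. All habitat factors are built on these levels; ties in
#' argmax-style assignments are broken in this order.
#'
#' @return Character vector `c("valley", "midslope", "ridge")`.
#' @export
habitatLevels <- function() c("valley", "midslope", "ridge")

# ---------------------------------------------------------------------------
# PlotLayout

#' PlotLayout: a rectangular grid of survey quadrats
#'
#' Describes the spatial substrate of the torus null: `nRows` x `nCols`
#' contiguous square quadrats, each with 0-based grid coordinates, an
#' identifier and an elevation (m).
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot quadratSize side length of one quadrat in metres.
#' @slot quadrats data.frame with columns `row`, `col`, `quadrat_id`,
#'   `elevation`; exactly one record per grid cell.
#'
#' @aliases PlotLayout
#' @exportClass PlotLayout
setClass("PlotLayout",
  representation(nRows = "integer", nCols = "integer",
                 quadratSize = "numeric", quadrats = "data.frame"))

setValidity("PlotLayout", function(object) {
  q <- object@quadrats
  need <- c("row", "col", "quadrat_id", "elevation")
  if (!all(need %in% names(q)))
    return(paste("quadrats must have columns", paste(need, collapse = ", ")))
  n <- object@nRows * object@nCols
  if (nrow(q) != n)
    return(sprintf("expected %d quadrats, got %d", n, nrow(q)))
  key <- paste(q$row, q$col)
  full <- paste(rep(seq_len(object@nRows) - 1L, each = object@nCols),
                rep(seq_len(object@nCols) - 1L, times = object@nRows))
  if (anyDuplicated(key) || !setequal(key, full))
    return("(row, col) pairs must be unique and cover the full grid")
  if (anyDuplicated(q$quadrat_id))
    return("quadrat_id values must be unique")
  if (!all(is.finite(q$elevation)))
    return("elevations must be finite")
  if (object@quadratSize <= 0)
    return("quadratSize must be positive")
  TRUE
})

#' Construct a PlotLayout
#'
#' @param nRows,nCols grid dimensions (positive integers).
#' @param quadratSize quadrat side length in metres.
#' @param quadrats data.frame with columns `row`, `col` (0-based),
#'   `quadrat_id`, `elevation`.
#' @return A [PlotLayout-class] object.
#' @export
PlotLayout <- function(nRows, nCols, quadratSize, quadrats) {
  new("PlotLayout", nRows = as.integer(nRows), nCols = as.integer(nCols),
      quadratSize = as.numeric(quadratSize),
      quadrats = as.data.frame(quadrats))
}

setMethod("show", "PlotLayout", function(object) {
  cat(sprintf("PlotLayout: %d x %d grid of %g m quadrats (%d total)\n",
              object@nRows, object@nCols, object@quadratSize,
              nrow(object@quadrats)))
  cat(sprintf("  elevation range: %.1f - %.1f m\n",
              min(object@quadrats$elevation), max(object@quadrats$elevation)))
})

# ---------------------------------------------------------------------------
# HabitatMap

#' HabitatMap: quadrat-to-habitat labelling
#'
#' A named factor assigning each quadrat one of the three terrain habitats.
#' Any torus transformation of the map preserves the label multiset.
#'
#' @slot labels factor with levels from [habitatLevels()], named by
#'   quadrat id.
#' @aliases HabitatMap
#' @exportClass HabitatMap
setClass("HabitatMap", representation(labels = "factor"))

setValidity("HabitatMap", function(object) {
  lab <- object@labels
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    return("labels must be uniquely named by quadrat id")
  if (anyNA(lab)) return("every quadrat must be labelled")
  if (!all(levels(lab) %in% habitatLevels()))
    return(paste("habitat labels must be among",
                 paste(habitatLevels(), collapse = ", ")))
  if (!all(habitatLevels() %in% as.character(lab)))
    return("all three habitat labels must be present")
  TRUE
})

#' Construct a HabitatMap
#'
#' @param labels character or factor of habitat labels, named by quadrat id.
#' @return A [HabitatMap-class] object.
#' @export
HabitatMap <- function(labels) {
  f <- factor(as.character(labels), levels = habitatLevels())
  names(f) <- names(labels)
  new("HabitatMap", labels = f)
}

setMethod("show", "HabitatMap", function(object) {
  cat("HabitatMap:", length(object@labels), "quadrats\n")
  print(table(object@labels))
})

# ---------------------------------------------------------------------------
# OtuExperiment

#' OtuExperiment: a quadrat x OTU count table with plot metadata
#'
#' Extends [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' with a `counts` assay (OTUs in rows, quadrats in columns), quadrat
#' metadata (grid position, elevation, habitat, environmental covariates) in
#' `colData`, and, for simulated tables, the generating [PlotLayout-class]
#' and ground-truth specialist table in `metadata()`.
#'
#' @aliases OtuExperiment-class
#' @exportClass OtuExperiment
setClass("OtuExperiment", contains = "SummarizedExperiment")

setValidity("OtuExperiment", function(object) {
  if (!"counts" %in% assayNames(object))
    return("an OtuExperiment needs a 'counts' assay")
  m <- assay(object, "counts")
  if (!all(is.finite(m))) return("counts must be finite")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) return("counts must be integers")
  if (ncol(m) > 0 && any(colSums(m) <= 0))
    return(paste("every sample must have total count > 0; offending:",
                 paste(colnames(m)[colSums(m) <= 0], collapse = ", ")))
  TRUE
})

#' Construct an OtuExperiment
#'
#' @param counts matrix of non-negative integer counts with samples
#'   (quadrats) in rows and OTUs in columns, as in the TSV interchange
#'   format; it is transposed internally to the features-in-rows layout.
#' @param layout optional [PlotLayout-class]; its `row`, `col`, `elevation`
#'   are joined into `colData` by quadrat id.
#' @param habitat optional [HabitatMap-class] or named character/factor.
#' @param env optional data.frame of environmental covariates, one row per
#'   quadrat (rownames = quadrat ids).
#' @param groundTruth optional data.frame of simulated specialist truth.
#' @param taxonomy optional character vector of taxonomy strings per OTU.
#' @return An [OtuExperiment-class].
#' @export
OtuExperiment <- function(counts, layout = NULL, habitat = NULL, env = NULL,
                          groundTruth = NULL, taxonomy = NULL) {
  m <- t(as.matrix(counts))
  storage.mode(m) <- "double"
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("Q%02d", seq_len(ncol(m)))
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("OTU%04d", seq_len(nrow(m)))
  cd <- DataFrame(row.names = colnames(m))
  if (!is.null(layout)) {
    q <- layout@quadrats
    idx <- match(colnames(m), q$quadrat_id)
    if (anyNA(idx))
      stop("sample ids not found in layout: ",
           paste(colnames(m)[is.na(idx)], collapse = ", "))
    cd$row <- q$row[idx]; cd$col <- q$col[idx]
    cd$elevation <- q$elevation[idx]
  }
  if (!is.null(habitat)) {
    lab <- if (is(habitat, "HabitatMap")) habitat@labels else
      factor(as.character(habitat), levels = habitatLevels())
    if (is.null(names(lab)) && !is(habitat, "HabitatMap"))
      names(lab) <- names(habitat)
    if (!is.null(names(lab))) {
      idx <- match(colnames(m), names(lab))
      if (anyNA(idx))
        stop("missing habitat label for: ",
             paste(colnames(m)[is.na(idx)], collapse = ", "),
             call. = FALSE)
      lab <- lab[idx]
    } else if (length(lab) != ncol(m)) {
      stop("habitat labels must be named or match the sample count")
    }
    cd$habitat <- unname(lab)
  }
  if (!is.null(env)) {
    env <- as.data.frame(env)
    idx <- match(colnames(m), rownames(env))
    if (anyNA(idx)) stop("env rows must be named by quadrat id")
    for (v in colnames(env)) cd[[v]] <- env[idx, v]
  }
  rd <- DataFrame(row.names = rownames(m))
  if (!is.null(taxonomy)) rd$taxonomy <- taxonomy
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m), colData = cd, rowData = rd,
    metadata = list(layout = layout, groundTruth = groundTruth))
  new("OtuExperiment", se)
}

setMethod("show", "OtuExperiment", function(object) {
  m <- assay(object, "counts")
  cat(sprintf("OtuExperiment: %d OTUs x %d quadrats (total reads %s)\n",
              nrow(m), ncol(m), format(sum(m), big.mark = ",")))
  if ("habitat" %in% colnames(colData(object)))
    print(table(colData(object)$habitat))
})

# ---------------------------------------------------------------------------
# Result containers

#' AssociationResult: torus-translation habitat-association classifications
#'
#' One row per (OTU, habitat): the observed statistic (mean per-quadrat
#' relative abundance within the habitat), the two one-sided pseudo
#' p-values over the null map set, and the class.
#'
#' @slot results data.frame with columns `otu`, `habitat`, `S_obs`,
#'   `p_pos`, `p_neg`, `class` (positive/negative/neutral/filtered).
#' @slot alpha two-sided significance level used.
#' @slot minRelAbund rare-taxon filter threshold (overall mean per-quadrat
#'   relative abundance).
#' @slot nMaps number of null habitat maps (observed map included).
#' @slot nullType `"torus"` or `"permutation"`.
#' @aliases AssociationResult
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(results = "data.frame", alpha = "numeric",
                 minRelAbund = "numeric", nMaps = "integer",
                 nullType = "character"))

setValidity("AssociationResult", function(object) {
  r <- object@results
  need <- c("otu", "habitat", "S_obs", "p_pos", "p_neg", "class")
  if (!all(need %in% names(r)))
    return(paste("results must have columns", paste(need, collapse = ", ")))
  tested <- r$class != "filtered"
  p <- c(r$p_pos[tested], r$p_neg[tested])
  if (length(p) && (any(p <= 0) || any(p > 1)))
    return("p-values must lie in (0, 1]")
  if (any(tested) &&
      any(r$p_pos[tested] + r$p_neg[tested] < 1 - 1e-12))
    return("p_pos + p_neg must be >= 1 (observed map is in the null set)")
  TRUE
})

setMethod("show", "AssociationResult", function(object) {
  r <- object@results
  cat(sprintf("AssociationResult (%s null, %d maps, alpha = %g):\n",
              object@nullType, object@nMaps, object@alpha))
  print(table(habitat = r$habitat, class = r$class))
})

#' Extract the per-(OTU, habitat) association table
#' @param x an [AssociationResult-class].
#' @return data.frame.
#' @export
associations <- function(x) {
  stopifnot(is(x, "AssociationResult"))
  x@results
}

#' VennSummary: shared/unique OTU partition across the three habitats
#'
#' @slot regions named integer vector of the seven disjoint Venn region
#'   counts (order: valley, midslope, ridge, valley&midslope,
#'   valley&ridge, midslope&ridge, all three).
#' @slot total number of OTUs with nonzero total abundance.
#' @slot exclusivityPct 100 x (sum of single-habitat counts) / total,
#'   rounded to two decimals.
#' @aliases VennSummary
#' @exportClass VennSummary
setClass("VennSummary",
  representation(regions = "integer", total = "integer",
                 exclusivityPct = "numeric"))

setValidity("VennSummary", function(object) {
  if (length(object@regions) != 7L) return("need seven region counts")
  if (sum(object@regions) != object@total)
    return("region counts must sum to the number of observed OTUs")
  TRUE
})

setMethod("show", "VennSummary", function(object) {
  cat("VennSummary:", object@total, "OTUs observed\n")
  print(object@regions)
  cat(sprintf("  habitat-exclusive: %.2f%%\n", object@exclusivityPct))
})

#' Venn region counts of a VennSummary
#' @param x a [VennSummary-class].
#' @return named integer vector of the seven disjoint region counts.
#' @export
vennRegions <- function(x) {
  stopifnot(is(x, "VennSummary"))
  x@regions
}

#' OrdinationResult: an NMDS configuration
#'
#' @slot points samples x k coordinate matrix of the best configuration.
#' @slot stress Kruskal stress-1 of the best start.
#' @slot converged whether the best start converged within `maxIter`.
#' @slot nStarts number of random starts used.
#' @aliases OrdinationResult
#' @exportClass OrdinationResult
setClass("OrdinationResult",
  representation(points = "matrix", stress = "numeric",
                 converged = "logical", nStarts = "integer"))

setValidity("OrdinationResult", function(object) {
  if (object@stress < 0) return("stress must be non-negative")
  if (!all(is.finite(object@points))) return("coordinates must be finite")
  TRUE
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d samples in %d dimensions, stress = %.4g (%d starts%s)\n",
              nrow(object@points), ncol(object@points), object@stress,
              object@nStarts,
              if (object@converged) "" else ", not converged"))
})

#' Ordination coordinates
#' @param x an [OrdinationResult-class].
#' @return samples x k numeric matrix.
#' @export
ordinationPoints <- function(x) {
  stopifnot(is(x, "OrdinationResult"))
  x@points
}

#' Ordination stress
#' @param x an [OrdinationResult-class].
#' @return Kruskal stress-1 of the reported configuration.
#' @export
ordinationStress <- function(x) {
  stopifnot(is(x, "OrdinationResult"))
  x@stress
}

#' CorrelationNetwork: thresholded SparCC co-occurrence graph
#'
#' @slot nodes data.frame `otu`, `degree`, `module` (NA until
#'   [detectModules()] is run).
#' @slot edges data.frame `otu_i`, `otu_j`, `r`, `p`, `sign`; one row per
#'   unordered pair, no self edges.
#' @slot modularity Newman modularity Q of the detected partition on |r|
#'   weights (NA before detection or for an empty network).
#' @slot rThresh,pThresh thresholds used to admit edges.
#' @aliases CorrelationNetwork
#' @exportClass CorrelationNetwork
setClass("CorrelationNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 modularity = "numeric", rThresh = "numeric",
                 pThresh = "numeric"))

setValidity("CorrelationNetwork", function(object) {
  e <- object@edges
  need <- c("otu_i", "otu_j", "r", "p", "sign")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$otu_i == e$otu_j)) return("self-edges are not allowed")
    key <- apply(cbind(e$otu_i, e$otu_j), 1L,
                 function(z) paste(sort(z), collapse = "\r"))
    if (anyDuplicated(key)) return("each unordered pair may appear once")
    if (any(abs(e$r) <= object@rThresh) || any(e$p >= object@pThresh))
      return("edges must satisfy |r| > rThresh and p < pThresh")
  }
  q <- object@modularity
  if (length(q) == 1L && is.finite(q) && (q < -0.5 - 1e-9 || q > 1 + 1e-9))
    return("modularity must lie in [-0.5, 1]")
  TRUE
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat(sprintf("CorrelationNetwork: %d nodes, %d edges (|r| > %g, p < %g)\n",
              nrow(object@nodes), nrow(object@edges), object@rThresh,
              object@pThresh))
  if (is.finite(object@modularity))
    cat(sprintf("  modularity Q = %.4f over %d modules\n", object@modularity,
                length(unique(stats::na.omit(object@nodes$module)))))
})

#' Network node table
#' @param x a [CorrelationNetwork-class].
#' @return data.frame of nodes with degree and module assignment.
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "CorrelationNetwork"))
  x@nodes
}

#' Network edge table
#' @param x a [CorrelationNetwork-class].
#' @return data.frame of edges (one row per unordered pair).
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "CorrelationNetwork"))
  x@edges
}

#' Modularity of the detected partition
#' @param x a [CorrelationNetwork-class].
#' @return Q, or NA if modules have not been detected / network is empty.
#' @export
modularityScore <- function(x) {
  stopifnot(is(x, "CorrelationNetwork"))
  x@modularity
}

#' FactorFit: permutational fit of environmental vectors to an ordination
#'
#' @slot table data.frame `variable`, `r2`, `p`, `stars`, `constant`.
#' @slot arrows variables x axes matrix of direction cosines.
#' @slot nPerm number of permutations.
#' @slot seed seed used.
#' @aliases FactorFit
#' @exportClass FactorFit
setClass("FactorFit",
  representation(table = "data.frame", arrows = "matrix",
                 nPerm = "integer", seed = "integer"))

setValidity("FactorFit", function(object) {
  t <- object@table
  if (any(t$r2 < -1e-12 | t$r2 > 1 + 1e-12)) return("R2 must lie in [0, 1]")
  lo <- 1 / (object@nPerm + 1)
  if (any(t$p < lo - 1e-12 | t$p > 1 + 1e-12))
    return("p must lie in [1/(nPerm+1), 1]")
  TRUE
})

setMethod("show", "FactorFit", function(object) {
  cat(sprintf("FactorFit: %d variables, %d permutations\n",
              nrow(object@table), object@nPerm))
  print(object@table, row.names = FALSE)
})

#' Vector-fit result table
#' @param x a [FactorFit-class].
#' @return data.frame with per-variable R2, permutation p and stars.
#' @export
fitTable <- function(x) {
  stopifnot(is(x, "FactorFit"))
  x@table
}
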