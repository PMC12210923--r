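# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one master seed drives independent
# sub-streams per stage so stages can be regenerated in isolation.
.subSeed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) * 7919 + as.numeric(offset) * 104729) %%
    2147483629
  as.integer(s)
}

# Canonical samples x OTUs count matrix from an OtuExperiment or a plain
# matrix/data.frame already in samples-in-rows orientation.
.sampleCounts <- function(otu) {
  if (is(otu, "OtuExperiment")) {
    m <- t(assay(otu, "counts"))
  } else {
    m <- as.matrix(otu)
    storage.mode(m) <- "double"
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("Q%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("OTU%04d", seq_len(ncol(m)))
  m
}

# Relative abundance matrix (samples x OTUs); errors on zero-total samples.
.relAbundance <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot <= 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(counts)[tot <= 0], collapse = ", "), call. = FALSE)
  counts / tot
}

# Habitat factor aligned to the given sample ids. Accepts a HabitatMap, a
# named factor/character, or NULL (taken from the OtuExperiment colData).
.habitatFactor <- function(hab, sampleIds, otu = NULL) {
  if (is.null(hab)) {
    if (!is.null(otu) && is(otu, "OtuExperiment") &&
        "habitat" %in% colnames(colData(otu))) {
      lab <- colData(otu)$habitat
      names(lab) <- colnames(otu)
      hab <- lab
    } else {
      stop("no habitat labels supplied and none stored in the object",
           call. = FALSE)
    }
  }
  lab <- if (is(hab, "HabitatMap")) hab@labels else hab
  f <- factor(as.character(lab), levels = habitatLevels())
  names(f) <- names(lab)
  if (!is.null(names(f))) {
    idx <- match(sampleIds, names(f))
    if (anyNA(idx))
      stop("missing habitat label for: ",
           paste(sampleIds[is.na(idx)], collapse = ", "), call. = FALSE)
    f <- f[idx]
  } else if (length(f) != length(sampleIds)) {
    stop("habitat labels must be named by quadrat id or match sample count",
         call. = FALSE)
  }
  if (anyNA(f)) stop("habitat labels contain NA", call. = FALSE)
  droplevels(f)
}

# PlotLayout resolution: explicit argument wins, else the one stored in an
# OtuExperiment's metadata.
.resolveLayout <- function(layout, otu = NULL) {
  if (!is.null(layout)) return(layout)
  if (!is.null(otu) && is(otu, "OtuExperiment")) {
    lay <- metadata(otu)$layout
    if (!is.null(lay)) return(lay)
  }
  NULL
}

#' Ground-truth specialist table of a simulated OtuExperiment
#' @param x an [OtuExperiment-class] produced by [generateOtuTable()].
#' @return data.frame with `otu`, `specialist`, `habitat`, `logFold`, or
#'   NULL for observed data.
#' @export
groundTruth <- function(x) {
  stopifnot(is(x, "OtuExperiment"))
  metadata(x)$groundTruth
}

#' Habitat labels of an OtuExperiment
#' @param x an [OtuExperiment-class] with habitat labels in `colData`.
#' @return factor named by quadrat id.
#' @export
habitats <- function(x) {
  stopifnot(is(x, "OtuExperiment"))
  .habitatFactor(NULL, colnames(x), otu = x)
}

#' OTU count matrix
#' @param x an [OtuExperiment-class].
#' @return numeric matrix, OTUs in rows and quadrats in columns.
#' @export
otuCounts <- function(x) {
  stopifnot(is(x, "OtuExperiment"))
  assay(x, "counts")
}

#' Grid layout stored with an OtuExperiment
#' @param x an [OtuExperiment-class].
#' @return the [PlotLayout-class], or NULL if none is attached.
#' @export
gridLayout <- function(x) {
  stopifnot(is(x, "OtuExperiment"))
  metadata(x)$layout
}

#' Environmental covariates stored with an OtuExperiment
#'
#' Returns the `colData` columns other than the reserved grid/habitat
#' columns (`row`, `col`, `elevation` is kept: it is an environmental
#' variable as well as a grid attribute).
#'
#' @param x an [OtuExperiment-class].
#' @return data.frame, one row per quadrat.
#' @export
envData <- function(x) {
  stopifnot(is(x, "OtuExperiment"))
  cd <- as.data.frame(colData(x))
  drop <- c("row", "col", "habitat")
  cd[, setdiff(colnames(cd), drop), drop = FALSE]
}
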