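# Torus-translation habitat-association test: classify each OTU as
# positively, negatively, or neutrally associated with each terrain
# habitat against a null that moves the whole habitat raster around the
# toroidal grid (plus mirror/rotation variants), preserving the spatial
# autocorrelation of both the species field and the habitat map.

#' Observed habitat statistic per OTU
#'
#' `S[i, h]` is the mean, over quadrats labelled h, of OTU i's per-quadrat
#' relative abundance (count / quadrat total). Using relative abundance
#' respects unequal sequencing depth across quadrats.
#'
#' @param otu an [OtuExperiment-class] or samples x OTUs count matrix.
#' @param hab habitat labels ([HabitatMap-class] or named factor); taken
#'   from the object if omitted. A habitat level with zero quadrats is an
#'   error.
#' @return OTUs x habitats numeric matrix.
#' @export
habitatStat <- function(otu, hab = NULL) {
  counts <- .sampleCounts(otu)
  habf <- .habitatFactor(hab, rownames(counts), otu = otu)
  rel <- .relAbundance(counts)
  .habitatStatRel(rel, habf)
}

# core statistic on a precomputed relative-abundance matrix and integer or
# factor label vector; W is the per-habitat averaging matrix
.habitatStatRel <- function(rel, habf) {
  lev <- levels(habf)
  nh <- table(habf)
  if (any(nh == 0))
    stop("habitat(s) with zero quadrats: ",
         paste(lev[nh == 0], collapse = ", "), call. = FALSE)
  W <- vapply(lev, function(h) (habf == h) / nh[[h]], numeric(length(habf)))
  S <- crossprod(rel, W)           # OTUs x habitats
  dimnames(S) <- list(colnames(rel), lev)
  S
}

#' All torus translations (with reflections) of a habitat map
#'
#' Generates every translation of the habitat raster on the toroidal
#' `R x C` grid, each also in its column-mirrored, 180-degree-rotated and
#' mirrored-rotated form: exactly `4 * R * C` maps, the identity included
#' (first row). Every map preserves the habitat label multiset.
#'
#' @param hab a [HabitatMap-class] or named factor over the layout's
#'   quadrats.
#' @param layout a [PlotLayout-class] describing the rectangular grid.
#' @return character matrix with one map per row and one column per
#'   quadrat (columns named by quadrat id, in layout order).
#' @export
torusMaps <- function(hab, layout) {
  q <- layout@quadrats
  R <- layout@nRows; C <- layout@nCols
  habf <- .habitatFactor(hab, q$quadrat_id)
  # habitat raster indexed [row+1, col+1]
  M <- matrix(NA_integer_, R, C)
  M[cbind(q$row + 1L, q$col + 1L)] <- as.integer(habf)
  variants <- list(M,
                   M[, rev(seq_len(C)), drop = FALSE],
                   M[rev(seq_len(R)), rev(seq_len(C)), drop = FALSE],
                   M[rev(seq_len(R)), , drop = FALSE])
  nMaps <- 4L * R * C
  out <- matrix(NA_integer_, nMaps, nrow(q))
  k <- 0L
  for (V in variants) {
    for (dr in 0:(R - 1L)) {
      for (dc in 0:(C - 1L)) {
        k <- k + 1L
        shifted <- V[((seq_len(R) - 1L + dr) %% R) + 1L,
                     ((seq_len(C) - 1L + dc) %% C) + 1L, drop = FALSE]
        out[k, ] <- shifted[cbind(q$row + 1L, q$col + 1L)]
      }
    }
  }
  res <- matrix(levels(habf)[out], nMaps, nrow(q),
                dimnames = list(NULL, q$quadrat_id))
  res
}

# TRUE when the samples form a complete rectangular grid under the layout
.isCompleteGrid <- function(layout, sampleIds) {
  if (is.null(layout)) return(FALSE)
  q <- layout@quadrats
  setequal(sampleIds, q$quadrat_id) &&
    nrow(q) == layout@nRows * layout@nCols
}

#' Torus-translation habitat-association test
#'
#' OTUs whose overall mean per-quadrat relative abundance falls below
#' `minRelAbund` are set aside as `filtered` (rare-taxon exclusion,
#' default 0.01%). For the rest, the observed statistic
#' (see [habitatStat()]) is compared against its value under every torus
#' map of the habitat raster ([torusMaps()]); abundances stay fixed to
#' quadrats while the habitat labels move. Two one-sided tests at
#' `alpha/2`: `p_pos` is the share of null maps with a statistic at least
#' the observed one, `p_neg` the share at most the observed one (ties
#' count toward both tails; the observed map is a member of the null set,
#' so no p-value can be zero). Class is `positive` when
#' `p_pos <= alpha/2`, `negative` when `p_neg <= alpha/2`, else
#' `neutral`.
#'
#' On layouts that do not form a complete rectangular grid the null is
#' `fallbackNPerm` seeded random permutations of the habitat labels
#' (observed labelling included).
#'
#' @inheritParams habitatStat
#' @param layout a [PlotLayout-class]; taken from the object if omitted.
#' @param alpha two-sided significance level in (0, 1); default 0.05.
#' @param minRelAbund rare-taxon filter threshold; default `1e-4`.
#' @param fallbackNPerm permutations for the non-grid fallback null.
#' @param seed integer seed (used only by the permutation fallback).
#' @return An [AssociationResult-class].
#' @export
torusTest <- function(otu, hab = NULL, layout = NULL, alpha = 0.05,
                      minRelAbund = 1e-4, fallbackNPerm = 999, seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)",
                                     call. = FALSE)
  counts <- .sampleCounts(otu)
  habf <- .habitatFactor(hab, rownames(counts), otu = otu)
  layout <- .resolveLayout(layout, otu)
  rel <- .relAbundance(counts)
  meanRel <- colMeans(rel)
  filtered <- meanRel < minRelAbund
  lev <- levels(habf)

  onGrid <- .isCompleteGrid(layout, rownames(counts))
  if (onGrid) {
    maps <- torusMaps(habf, layout)
    maps <- maps[, rownames(counts), drop = FALSE]   # align to sample order
    nullType <- "torus"
  } else {
    if (!is.null(layout) && !onGrid)
      message("samples do not form a complete rectangular grid; ",
              "using the habitat-label permutation null")
    set.seed(.subSeed(seed, 97L))
    labs <- as.character(habf)
    maps <- rbind(labs,
                  t(vapply(seq_len(fallbackNPerm), function(b) sample(labs),
                           character(length(labs)))))
    colnames(maps) <- rownames(counts)
    nullType <- "permutation"
  }
  nMaps <- nrow(maps)
  if (alpha / 2 < 1 / nMaps)
    warning(sprintf(paste("alpha/2 = %g is below 1/%d: positive/negative",
                          "classes are unattainable at this grid size"),
                    alpha / 2, nMaps), call. = FALSE)

  relT <- rel[, !filtered, drop = FALSE]
  Sobs <- .habitatStatRel(relT, habf)
  nGE <- matrix(0L, nrow(Sobs), ncol(Sobs))
  nLE <- matrix(0L, nrow(Sobs), ncol(Sobs))
  eps <- 1e-12
  for (m in seq_len(nMaps)) {
    f <- factor(maps[m, ], levels = lev)
    Sm <- .habitatStatRel(relT, f)
    nGE <- nGE + (Sm >= Sobs - eps)
    nLE <- nLE + (Sm <= Sobs + eps)
  }
  pPos <- nGE / nMaps
  pNeg <- nLE / nMaps
  cls <- matrix("neutral", nrow(Sobs), ncol(Sobs))
  cls[pPos <= alpha / 2] <- "positive"
  cls[pNeg <= alpha / 2] <- "negative"

  # assemble long results including filtered OTUs (with observed S)
  SAll <- .habitatStatRel(rel, habf)
  otuIds <- colnames(rel)
  res <- do.call(rbind, lapply(seq_along(lev), function(j) {
    data.frame(otu = otuIds, habitat = lev[j], S_obs = SAll[, j],
               p_pos = NA_real_, p_neg = NA_real_,
               class = "filtered", stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  tested <- !filtered[match(res$otu, otuIds)]
  for (j in seq_along(lev)) {
    sel <- res$habitat == lev[j] & tested
    ord <- match(res$otu[sel], rownames(Sobs))
    res$p_pos[sel] <- pPos[ord, j]
    res$p_neg[sel] <- pNeg[ord, j]
    res$class[sel] <- cls[ord, j]
  }
  res$habitat <- factor(res$habitat, levels = lev)
  res <- res[order(match(res$otu, otuIds), as.integer(res$habitat)), ]
  rownames(res) <- NULL
  new("AssociationResult", results = res, alpha = alpha,
      minRelAbund = minRelAbund, nMaps = as.integer(nMaps),
      nullType = nullType)
}

#' Summarize habitat-association classifications
#'
#' Counts and percentages of OTUs significantly associated with at least
#' one habitat, positively associated, and negatively associated; per
#' habitat positive/negative counts; and the Venn intersections of the
#' positive OTU sets and of the negative OTU sets across habitats. All
#' percentages state their denominator (the number of tested, i.e.
#' unfiltered, OTUs) explicitly.
#'
#' @param res an [AssociationResult-class].
#' @return list with `denominators`, `otuLevel` counts/percentages,
#'   `perHabitat` data.frame, `vennPositive`, `vennNegative` (seven
#'   disjoint region counts each) and `allThreePositive` /
#'   `allThreeNegative` flags.
#' @export
summarizeAssociations <- function(res) {
  stopifnot(is(res, "AssociationResult"))
  r <- res@results
  otus <- unique(r$otu)
  nTotal <- length(otus)
  filteredOtus <- unique(r$otu[r$class == "filtered"])
  tested <- setdiff(otus, filteredOtus)
  nTested <- length(tested)
  posBy <- lapply(habitatLevels(), function(h)
    r$otu[r$habitat == h & r$class == "positive"])
  negBy <- lapply(habitatLevels(), function(h)
    r$otu[r$habitat == h & r$class == "negative"])
  names(posBy) <- names(negBy) <- habitatLevels()
  anyPos <- unique(unlist(posBy))
  anyNeg <- unique(unlist(negBy))
  anySig <- union(anyPos, anyNeg)
  pct <- function(k) if (nTested > 0) round(100 * k / nTested, 2) else 0
  venn <- function(sets) {
    inA <- tested %in% sets[[1L]]; inB <- tested %in% sets[[2L]]
    inC <- tested %in% sets[[3L]]
    code <- inA + 2L * inB + 4L * inC
    stats::setNames(vapply(c(1L, 2L, 4L, 3L, 5L, 6L, 7L),
                           function(k) sum(code == k), integer(1)),
                    c("valley", "midslope", "ridge", "valley&midslope",
                      "valley&ridge", "midslope&ridge",
                      "valley&midslope&ridge"))
  }
  vp <- venn(posBy); vn <- venn(negBy)
  perHab <- data.frame(habitat = habitatLevels(),
                       positive = vapply(posBy, length, integer(1)),
                       negative = vapply(negBy, length, integer(1)),
                       row.names = NULL)
  list(denominators = list(totalOtus = nTotal, testedOtus = nTested,
                           filteredOtus = nTotal - nTested),
       otuLevel = list(
         significant = length(anySig), significantPct = pct(length(anySig)),
         positive = length(anyPos), positivePct = pct(length(anyPos)),
         negative = length(anyNeg), negativePct = pct(length(anyNeg))),
       perHabitat = perHab,
       vennPositive = vp, vennNegative = vn,
       allThreePositive = vp[["valley&midslope&ridge"]] > 0,
       allThreeNegative = vn[["valley&midslope&ridge"]] > 0)
}
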