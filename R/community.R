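# Community-structure layer: richness contrasts, shared/unique OTU
# partitioning, Bray-Curtis dissimilarity, NMDS, rarefaction and ternary
# habitat-enrichment coordinates.

#' Per-sample OTU richness and its habitat contrast
#'
#' Richness is the number of OTUs with count > 0 in each quadrat, computed
#' on raw counts. The habitat contrast is the tie-corrected Kruskal-Wallis
#' rank test (chi-square reference with `groups - 1` degrees of freedom);
#' a one-way ANOVA on the same richness values is also reported for
#' comparison. When every richness value is identical the rank statistic's
#' tie correction degenerates; H is then defined as 0 with p = 1.
#'
#' @param otu an [OtuExperiment-class] or samples x OTUs count matrix.
#' @param hab habitat labels ([HabitatMap-class] or named factor); taken
#'   from the object if omitted.
#' @return list with `richness` (data.frame sample, habitat, richness),
#'   `summary` (per-habitat n, median, mean), `H`, `df`, `p`, and
#'   `anova` (F and p from `aov`).
#' @export
richnessKruskal <- function(otu, hab = NULL) {
  counts <- .sampleCounts(otu)
  habf <- .habitatFactor(hab, rownames(counts), otu = otu)
  if (nlevels(habf) < 2L)
    stop("need at least 2 habitats among the samples", call. = FALSE)
  rich <- rowSums(counts > 0)
  df <- nlevels(habf) - 1L
  if (length(unique(rich)) == 1L) {
    H <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(rich, habf)
    H <- unname(kt$statistic); p <- kt$p.value
  }
  fit <- stats::aov(rich ~ habf)
  an <- summary(fit)[[1L]]
  smry <- do.call(rbind, lapply(levels(habf), function(h) {
    v <- rich[habf == h]
    data.frame(habitat = h, n = length(v), median = stats::median(v),
               mean = mean(v))
  }))
  list(richness = data.frame(sample = rownames(counts), habitat = habf,
                             richness = rich, row.names = NULL),
       summary = smry, H = H, df = df, p = p,
       anova = list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L]))
}

#' Partition OTUs into shared/unique habitat regions
#'
#' An OTU belongs to a habitat when its summed count over that habitat's
#' quadrats exceeds zero (optionally, a minimum overall relative-abundance
#' presence threshold can be applied first). Every OTU with nonzero total
#' count falls in exactly one of the seven Venn regions; the exclusivity
#' percentage is `100 * (# single-habitat OTUs) / (# observed OTUs)`,
#' rounded to two decimals.
#'
#' @inheritParams richnessKruskal
#' @param minRelAbund optional presence threshold on the overall mean
#'   per-quadrat relative abundance (default 0 = off); OTUs below it are
#'   treated as absent everywhere and excluded from the total.
#' @return A [VennSummary-class]. OTUs with zero total count are excluded
#'   from all regions and from the total.
#' @export
partitionOtus <- function(otu, hab = NULL, minRelAbund = 0) {
  counts <- .sampleCounts(otu)
  habf <- .habitatFactor(hab, rownames(counts), otu = otu)
  keep <- colSums(counts) > 0
  if (minRelAbund > 0) {
    rel <- .relAbundance(counts)
    keep <- keep & colMeans(rel) >= minRelAbund
  }
  m <- counts[, keep, drop = FALSE]
  present <- vapply(habitatLevels(), function(h) {
    idx <- which(habf == h)
    if (!length(idx)) return(rep(FALSE, ncol(m)))
    colSums(m[idx, , drop = FALSE]) > 0
  }, logical(ncol(m)))
  if (ncol(m) == 1L) present <- matrix(present, nrow = 1L,
                                       dimnames = list(NULL, habitatLevels()))
  code <- present[, 1L] + 2L * present[, 2L] + 4L * present[, 3L]
  regionNames <- c("valley", "midslope", "ridge", "valley&midslope",
                   "valley&ridge", "midslope&ridge",
                   "valley&midslope&ridge")
  codes <- c(1L, 2L, 4L, 3L, 5L, 6L, 7L)
  regions <- stats::setNames(
    vapply(codes, function(k) sum(code == k), integer(1)), regionNames)
  total <- sum(regions)
  exclusive <- sum(regions[1:3])
  pct <- if (total > 0) round(100 * exclusive / total, 2) else 0
  new("VennSummary", regions = regions, total = as.integer(total),
      exclusivityPct = pct)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = 1 - 2 * sum_i min(x_ai, x_bi) / (sum_i x_ai + sum_i x_bi)`.
#'
#' @inheritParams richnessKruskal
#' @return a `dist` object over samples (symmetric, zero diagonal).
#' @export
brayCurtis <- function(otu) {
  counts <- .sampleCounts(otu)
  tot <- rowSums(counts)
  if (any(tot <= 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(counts)[tot <= 0], collapse = ", "), call. = FALSE)
  vegan::vegdist(counts, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimizes Kruskal stress-1 between monotone (isotonic, primary tie
#' treatment) regressed dissimilarities and configuration distances.
#' Start 1 is the classical metric-scaling configuration; remaining starts
#' are seeded random. The best (lowest-stress) start is returned.
#'
#' @param d a `dist` or symmetric zero-diagonal matrix.
#' @param k number of axes (>= 1).
#' @param nStarts number of restarts (>= 1).
#' @param maxIter iteration cap per start.
#' @param seed integer seed driving the random starts.
#' @return An [OrdinationResult-class].
#' @export
nmdsOrdination <- function(d, k = 2, nStarts = 20, maxIter = 200, seed = 1) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("dissimilarity matrix must be symmetric", call. = FALSE)
    if (any(abs(diag(d)) > 1e-12))
      stop("dissimilarity matrix must have a zero diagonal", call. = FALSE)
    d <- stats::as.dist(d)
  }
  stopifnot(k >= 1, nStarts >= 1)
  n <- attr(d, "Size")
  set.seed(.subSeed(seed, 53L))
  best <- NULL
  for (s in seq_len(nStarts)) {
    init <- if (s == 1L) {
      y <- suppressWarnings(stats::cmdscale(d, k = k))
      if (ncol(y) < k) cbind(y, matrix(stats::rnorm(n * (k - ncol(y)),
                                                    sd = 1e-4), n)) else y
    } else {
      matrix(stats::rnorm(n * k), n, k)
    }
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                          maxit = maxIter, smin = 1e-7, sfgrmin = 1e-9)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  rownames(pts) <- attr(d, "Labels")
  colnames(pts) <- paste0("NMDS", seq_len(k))
  new("OrdinationResult", points = pts, stress = best$stress,
      converged = best$iters < maxIter, nStarts = as.integer(nStarts))
}

#' Expected rarefied richness (closed form)
#'
#' `E[S at depth d] = sum_i [1 - choose(N - N_i, d) / choose(N, d)]` with
#' `N` the sample total and `N_i` the count of OTU i; monotone
#' non-decreasing in `d`.
#'
#' @inheritParams richnessKruskal
#' @param depths integer vector of subsample depths; every depth must not
#'   exceed any sample's total count.
#' @return samples x depths matrix of expected richness.
#' @export
rarefyExpected <- function(otu, depths) {
  counts <- .sampleCounts(otu)
  depths <- as.integer(depths)
  tot <- rowSums(counts)
  if (any(depths < 1)) stop("depths must be >= 1", call. = FALSE)
  bad <- depths > min(tot)
  if (any(bad))
    stop(sprintf("depth %d exceeds the smallest sample total (%d)",
                 min(depths[bad]), as.integer(min(tot))), call. = FALSE)
  out <- vapply(depths, function(d) {
    # vegan::rarefy warns heuristically when the smallest count is not 1;
    # irrelevant for the closed-form expectation on validated input
    withCallingHandlers(
      as.numeric(vegan::rarefy(counts, sample = d)),
      warning = function(w) {
        if (grepl("smallest count", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1L) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(rownames(counts), as.character(depths))
  out
}

#' Ternary habitat-enrichment coordinates per OTU
#'
#' For each OTU the coordinate on habitat h is its mean per-quadrat
#' relative abundance in h, normalized so the three coordinates sum to 1.
#' The assigned habitat is the coordinate argmax; ties are broken in the
#' fixed order valley, midslope, ridge. OTUs absent everywhere are flagged
#' `excluded` and carry NA coordinates.
#'
#' @inheritParams richnessKruskal
#' @return data.frame `otu`, `valley`, `midslope`, `ridge`,
#'   `assigned`, `excluded`.
#' @export
ternaryEnrichment <- function(otu, hab = NULL) {
  counts <- .sampleCounts(otu)
  habf <- .habitatFactor(hab, rownames(counts), otu = otu)
  if (nlevels(habf) != 3L)
    stop("ternary coordinates require exactly 3 habitats", call. = FALSE)
  S <- habitatStat(counts, habf)
  tot <- rowSums(S)
  coords <- S / tot
  excluded <- tot <= 0
  coords[excluded, ] <- NA_real_
  assigned <- rep(NA_character_, nrow(S))
  ok <- which(!excluded)
  if (length(ok))
    assigned[ok] <- habitatLevels()[apply(coords[ok, , drop = FALSE], 1L,
                                          which.max)]
  data.frame(otu = rownames(S), valley = coords[, "valley"],
             midslope = coords[, "midslope"], ridge = coords[, "ridge"],
             assigned = assigned, excluded = excluded, row.names = NULL)
}
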