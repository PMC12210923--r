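# Synthetic study-design generator: gridded plot, habitat map, environmental
# covariates and Dirichlet-multinomial OTU counts with known habitat
# specialists. Emulates a 30-quadrat (20 m) mountain-forest design with
# valley / mid-slope / ridge habitats along an elevation gradient.

#' Generate a gridded plot layout and its habitat map
#'
#' Builds an `nRows` x `nCols` contiguous grid of square quadrats with a
#' smooth monotone elevation gradient plus seeded noise, then assigns
#' habitats by elevation terciles: the lowest third of quadrats become
#' `valley`, the middle third `midslope`, the highest third `ridge`
#' (group sizes differ by at most one).
#'
#' @param nRows,nCols grid dimensions; `nRows * nCols >= 3`.
#' @param quadratSize quadrat side length in metres (default 20).
#' @param seed integer seed; the layout is deterministic given the seed.
#' @return list with elements `layout` ([PlotLayout-class]) and
#'   `habitat` ([HabitatMap-class]).
#' @examples
#' g <- generateLayout(5, 6, 20, seed = 1)
#' table(g$habitat@labels)  # 10 quadrats per habitat
#' @export
generateLayout <- function(nRows, nCols, quadratSize = 20, seed = 1) {
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  n <- nRows * nCols
  if (n < 3L)
    stop("grid must contain at least 3 quadrats to realize three habitats",
         call. = FALSE)
  set.seed(.subSeed(seed, 11L))
  row <- rep(seq_len(nRows) - 1L, each = nCols)
  col <- rep(seq_len(nCols) - 1L, times = nRows)
  # metre positions of quadrat centres
  y <- row * quadratSize
  x <- col * quadratSize
  # monotone gradient dominated by the row direction + seeded roughness
  elevation <- 1200 + 1.0 * y + 0.3 * x + stats::rnorm(n, 0, 1.5)
  q <- data.frame(row = row, col = col,
                  quadrat_id = sprintf("Q%02d", seq_len(n)),
                  elevation = elevation, stringsAsFactors = FALSE)
  layout <- PlotLayout(nRows, nCols, quadratSize, q)
  # tercile split: rank elevations, lowest third -> valley, ...
  sizes <- diff(round(seq(0, n, length.out = 4)))
  lab <- rep(habitatLevels(), times = sizes)
  ord <- order(elevation)
  habitat <- character(n)
  habitat[ord] <- lab
  hm <- HabitatMap(stats::setNames(habitat, q$quadrat_id))
  list(layout = layout, habitat = hm)
}

#' Generate environmental covariates for a plot
#'
#' Produces one row per quadrat with the full covariate set used in
#' mountain-forest soil surveys: soil chemistry (pH, SWC, SOM, P, N),
#' terrain (elevation, slope, aspect, concavity), canopy light (LT, SR,
#' TR, CC, ALA, LAI) and woody-plant community summaries (WA, WR). Soil
#' water content, organic matter and nitrogen are constructed with negative
#' correlation to elevation (valleys are wetter and richer); the light
#' variables share a latent canopy factor.
#'
#' @param layout a [PlotLayout-class].
#' @param hab a [HabitatMap-class] (labels are not used numerically but the
#'   arguments keep the generator stage signature uniform).
#' @param seed integer seed.
#' @return data.frame of 17 finite covariates, rownames = quadrat ids.
#' @export
generateEnvironment <- function(layout, hab = NULL, seed = 1) {
  q <- layout@quadrats
  n <- nrow(q)
  if (n < 1L) stop("layout is empty", call. = FALSE)
  set.seed(.subSeed(seed, 23L))
  z <- as.numeric(scale(q$elevation))      # standardized elevation
  canopy <- stats::rnorm(n)                # latent canopy closure factor
  env <- data.frame(
    pH        = 6.2 + 0.25 * z + stats::rnorm(n, 0, 0.15),
    SWC       = 32 - 7.0 * z + stats::rnorm(n, 0, 2.0),    # % , wetter valleys
    SOM       = 62 - 14 * z + stats::rnorm(n, 0, 5.0),     # g/kg
    P         = 9.5 + stats::rnorm(n, 0, 1.8),             # mg/kg
    N         = 155 - 28 * z + stats::rnorm(n, 0, 12),     # mg/kg
    elevation = q$elevation,
    slope     = pmin(pmax(55 + 6 * z + stats::rnorm(n, 0, 7), 35), 85),
    aspect    = stats::runif(n, 0, 360),
    concavity = -0.4 * z + stats::rnorm(n, 0, 0.6),
    LT        = pmax(12 - 4.5 * canopy + stats::rnorm(n, 0, 1.5), 0.5),
    SR        = pmax(5.5 - 1.8 * canopy + stats::rnorm(n, 0, 0.8), 0.2),
    TR        = pmax(14 - 5.0 * canopy + stats::rnorm(n, 0, 1.8), 0.5),
    CC        = pmin(pmax(0.82 + 0.05 * canopy + stats::rnorm(n, 0, 0.03),
                          0.4), 0.99),
    ALA       = pmin(pmax(42 + 6 * canopy + stats::rnorm(n, 0, 4), 10), 80),
    LAI       = pmax(3.4 + 0.8 * canopy + stats::rnorm(n, 0, 0.4), 0.3),
    WA        = pmax(round(160 - 22 * z + stats::rnorm(n, 0, 18)), 20),
    WR        = pmax(round(38 - 5 * z + stats::rnorm(n, 0, 5)), 5),
    row.names = q$quadrat_id)
  stopifnot(all(vapply(env, function(v) all(is.finite(v)), logical(1))))
  env
}

#' Simulate a quadrat x OTU count table with known habitat specialists
#'
#' Per-quadrat counts are drawn from a Dirichlet-multinomial at the given
#' sequencing depth. Expected relative abundances are built on the log
#' scale as: a log-normal rank-abundance baseline per OTU, plus
#' `effectLogFold` for specialist OTUs inside their habitat, plus a
#' spatially autocorrelated Gaussian field (exponential kernel with range
#' `spatialRange`) independent across OTUs. The Dirichlet perturbation
#' with precision `1/overdispersion` adds per-sample overdispersion.
#'
#' @param layout a [PlotLayout-class].
#' @param hab a [HabitatMap-class].
#' @param nOtus number of OTUs.
#' @param specialistFraction proportion of OTUs that are habitat
#'   specialists (in `[0, 1]`).
#' @param effectLogFold log fold-change a specialist enjoys in its habitat;
#'   `log(8)` by default. Negative values are allowed and recorded as such
#'   in the ground truth.
#' @param depth per-quadrat sequencing depth (positive integer).
#' @param overdispersion Dirichlet overdispersion; the Dirichlet precision
#'   is `1/overdispersion`, so small values give counts close to
#'   multinomial. Default 0.005 (precision 200).
#' @param spatialRange range (m) of the exponential spatial kernel;
#'   defaults to two quadrat widths.
#' @param spatialSd marginal SD of the spatial log-abundance field.
#' @param baselineSd SD of the log-normal rank-abundance baseline.
#' @param seed integer seed; counts are reproducible bit-for-bit.
#' @return An [OtuExperiment-class] with the layout and a ground-truth
#'   data.frame (`otu`, `specialist`, `habitat`, `logFold`) in its
#'   metadata; retrieve with [groundTruth()].
#' @export
generateOtuTable <- function(layout, hab, nOtus = 300,
                             specialistFraction = 0.2,
                             effectLogFold = log(8), depth = 10000,
                             overdispersion = 0.005,
                             spatialRange = 2 * layout@quadratSize,
                             spatialSd = 0.5, baselineSd = 1.5, seed = 1) {
  if (specialistFraction < 0 || specialistFraction > 1)
    stop("specialistFraction must lie in [0, 1]", call. = FALSE)
  if (depth <= 0 || abs(depth - round(depth)) > 0)
    stop("depth must be a positive integer", call. = FALSE)
  if (overdispersion <= 0)
    stop("overdispersion must be positive", call. = FALSE)
  q <- layout@quadrats
  n <- nrow(q)
  habf <- .habitatFactor(hab, q$quadrat_id)
  set.seed(.subSeed(seed, 37L))
  otuIds <- sprintf("OTU%04d", seq_len(nOtus))

  # log-normal rank-abundance baseline
  base <- stats::rnorm(nOtus, 0, baselineSd)

  # specialists and their habitats
  nSpec <- round(specialistFraction * nOtus)
  specIdx <- if (nSpec > 0) sample.int(nOtus, nSpec) else integer(0)
  specHab <- rep(NA_character_, nOtus)
  if (nSpec > 0)
    specHab[specIdx] <- sample(habitatLevels(), nSpec, replace = TRUE)

  # habitat effect matrix (quadrats x OTUs)
  eta <- matrix(base, n, nOtus, byrow = TRUE)
  if (nSpec > 0 && effectLogFold != 0) {
    for (h in habitatLevels()) {
      qs <- which(habf == h)
      os <- which(!is.na(specHab) & specHab == h)
      if (length(qs) && length(os)) eta[qs, os] <- eta[qs, os] + effectLogFold
    }
  }

  # spatially autocorrelated noise: exponential-kernel Gaussian field per OTU
  if (spatialSd > 0) {
    xy <- cbind(q$col, q$row) * layout@quadratSize
    D <- as.matrix(stats::dist(xy))
    K <- spatialSd^2 * exp(-D / spatialRange)
    L <- t(chol(K + diag(1e-9, n)))
    eta <- eta + L %*% matrix(stats::rnorm(n * nOtus), n, nOtus)
  }

  # per-sample Dirichlet-multinomial draw
  precision <- 1 / overdispersion
  counts <- matrix(0, n, nOtus, dimnames = list(q$quadrat_id, otuIds))
  for (i in seq_len(n)) {
    p <- exp(eta[i, ] - max(eta[i, ]))
    p <- p / sum(p)
    g <- stats::rgamma(nOtus, shape = precision * p)
    if (sum(g) <= 0) g <- p            # degenerate guard at tiny precision
    counts[i, ] <- stats::rmultinom(1, depth, g / sum(g))
  }

  gt <- data.frame(otu = otuIds,
                   specialist = seq_len(nOtus) %in% specIdx,
                   habitat = specHab,
                   logFold = ifelse(seq_len(nOtus) %in% specIdx,
                                    effectLogFold, 0),
                   stringsAsFactors = FALSE)
  OtuExperiment(counts, layout = layout, habitat = hab, groundTruth = gt)
}
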