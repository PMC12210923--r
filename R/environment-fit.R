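# Environmental drivers: permutational vector fitting of covariates onto
# an ordination and constrained-ordination (RDA) variance explained.

.stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' Fit environmental vectors to an ordination by permutation
#'
#' For each environmental variable, R2 is the coefficient of
#' determination of that variable regressed on the ordination axes; the
#' permutation p-value is `(1 + #\{R2_perm >= R2_obs\}) / (1 + nPerm)`
#' under seeded permutation of the variable's raw values across samples.
#' Constant variables get R2 = 0, p = 1 and are flagged. Direction
#' cosines of each fitted vector on the axes are returned. R2 is
#' invariant under rigid rotation of the ordination.
#'
#' @param ord an [OrdinationResult-class] or a samples x axes coordinate
#'   matrix.
#' @param env data.frame of numeric covariates, rows matching the
#'   ordination samples.
#' @param nPerm number of permutations (>= 1; default 999).
#' @param seed integer seed.
#' @return A [FactorFit-class].
#' @export
fitEnvVectors <- function(ord, env, nPerm = 999, seed = 1) {
  axes <- if (is(ord, "OrdinationResult")) ord@points else as.matrix(ord)
  env <- as.data.frame(env)
  stopifnot(nrow(env) == nrow(axes), nPerm >= 1)
  n <- nrow(axes)
  set.seed(.subSeed(seed, 307L))
  Xc <- scale(axes, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  vars <- colnames(env)
  k <- ncol(axes)
  tab <- data.frame(variable = vars, r2 = NA_real_, p = NA_real_,
                    stars = "", constant = FALSE, stringsAsFactors = FALSE)
  arrows <- matrix(NA_real_, length(vars), k,
                   dimnames = list(vars, colnames(axes)))
  for (i in seq_along(vars)) {
    v <- as.numeric(env[[i]])
    if (!all(is.finite(v))) stop("non-finite values in ", vars[i],
                                 call. = FALSE)
    vc <- v - mean(v)
    tss <- sum(vc^2)
    if (tss <= 0) {
      tab$r2[i] <- 0; tab$p[i] <- 1; tab$constant[i] <- TRUE
      next
    }
    r2 <- sum(crossprod(Q, vc)^2) / tss
    P <- vapply(seq_len(nPerm), function(b) sample(vc), numeric(n))
    r2p <- colSums(crossprod(Q, P)^2) / tss
    tab$r2[i] <- min(r2, 1)
    tab$p[i] <- (1 + sum(r2p >= r2 - 1e-12)) / (1 + nPerm)
    b <- qr.coef(qrX, vc)[seq_len(qrX$rank)]
    nb <- sqrt(sum(b^2))
    if (nb > 0) arrows[i, seq_along(b)] <- b / nb
  }
  tab$stars <- .stars(tab$p)
  new("FactorFit", table = tab, arrows = arrows,
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Redundancy analysis: variance explained by environmental factors
#'
#' The community matrix (optionally Hellinger-transformed, the default
#' for abundance data) is column-centered and projected onto the
#' environmental space by least squares; the explained proportion is the
#' trace of the fitted sum of squares over the trace of the total sum of
#' squares, and the constrained axes come from the spectral decomposition
#' of the fitted values (computed via [vegan::rda()]).
#'
#' @param otu an [OtuExperiment-class] or samples x OTUs count matrix.
#' @param env data.frame of numeric covariates; columns must be linearly
#'   independent after centering (collinear columns are an error naming
#'   the dependent columns).
#' @param transform `"hellinger"` (default) or `"none"`.
#' @return list with `proportion` (constrained variance proportion),
#'   `eig` (constrained axis eigenvalues), `totalInertia`,
#'   `constrainedInertia`, `siteScores`, `varScores` and `transform`.
#' @export
rdaExplained <- function(otu, env, transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  counts <- .sampleCounts(otu)
  env <- as.data.frame(env)
  stopifnot(nrow(env) == nrow(counts))
  X <- scale(as.matrix(env), center = TRUE, scale = FALSE)
  qrE <- qr(X)
  if (qrE$rank < ncol(X)) {
    dep <- colnames(X)[qrE$pivot[(qrE$rank + 1L):ncol(X)]]
    stop("collinear environmental column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  Y <- if (transform == "hellinger")
    vegan::decostand(counts, method = "hellinger") else counts
  mod <- vegan::rda(Y ~ ., data = env)
  tot <- mod$tot.chi
  con <- if (is.null(mod$CCA)) 0 else mod$CCA$tot.chi
  prop <- if (tot > 0) con / tot else 0
  eig <- if (is.null(mod$CCA)) numeric(0) else mod$CCA$eig
  sc <- tryCatch(
    list(site = vegan::scores(mod, display = "sites",
                              choices = seq_len(max(1L, length(eig)))),
         bp = vegan::scores(mod, display = "bp",
                            choices = seq_len(max(1L, length(eig))))),
    error = function(e) list(site = NULL, bp = NULL))
  list(proportion = prop, eig = eig, totalInertia = tot,
       constrainedInertia = con, siteScores = sc$site,
       varScores = sc$bp, transform = transform)
}
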