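# Compositionality-aware co-occurrence networks: SparCC correlation
# estimation, permutation edge significance, edge thresholding, Louvain
# module detection and strength summaries.

# one SparCC basis estimate from a fraction matrix (samples x OTUs)
.sparccOnce <- function(frac, xIter, exclusionThresh) {
  p <- ncol(frac)
  lf <- log(frac)
  Cv <- stats::cov(lf)
  v <- diag(Cv)
  # variation matrix T_ij = Var(log(x_i/x_j)) = v_i + v_j - 2 C_ij
  Tm <- outer(v, v, "+") - 2 * Cv
  diag(Tm) <- 0
  M <- matrix(1, p, p); diag(M) <- p - 1
  excl <- matrix(FALSE, p, p)
  rho <- NULL
  for (it in seq_len(xIter + 1L)) {
    Tuse <- Tm; Tuse[excl] <- 0
    tvec <- rowSums(Tuse)
    omega <- tryCatch(solve(M, tvec), error = function(e) rep(NA_real_, p))
    if (anyNA(omega)) break
    omega <- pmax(omega, 1e-12)
    denom <- 2 * sqrt(outer(omega, omega))
    cand <- (outer(omega, omega, "+") - Tm) / denom
    cand[cand > 1] <- 1; cand[cand < -1] <- -1
    diag(cand) <- 1
    rho <- cand
    if (it > xIter) break
    # exclude the strongest correlated not-yet-excluded pair above threshold
    a <- abs(cand); diag(a) <- 0; a[excl] <- 0
    mx <- max(a)
    if (mx <= exclusionThresh) break
    ij <- which(a == mx, arr.ind = TRUE)[1L, ]
    i <- ij[1L]; j <- ij[2L]
    # keep each component attached to at least two partners
    if (M[i, i] <= 2 || M[j, j] <= 2) break
    excl[i, j] <- excl[j, i] <- TRUE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
  }
  list(rho = rho, omega = omega)
}

#' SparCC correlation estimate for compositional count data
#'
#' Estimates correlations among the underlying (basis) abundances from a
#' quadrat x OTU count table. For each of `nEst` Dirichlet-resampled
#' fraction estimates (unit pseudocounts), the pairwise log-ratio
#' variation matrix is computed, the sparsity-approximation linear system
#' is solved for basis variances, and the strongest-correlated pair above
#' `exclusionThresh` is iteratively excluded and the system re-solved (up
#' to `xIter` rounds). The final correlation matrix is the component-wise
#' median over the `nEst` estimates, clipped to `[-1, 1]` with unit
#' diagonal.
#'
#' @param otu an [OtuExperiment-class] or samples x OTUs count matrix;
#'   at least 4 OTUs (the basis solve is underdetermined below) and 2
#'   samples; OTU columns with zero total count are an error (filter
#'   first).
#' @param nEst number of Dirichlet resamples (default 20).
#' @param xIter maximum strong-pair exclusion rounds per estimate.
#' @param exclusionThresh |correlation| above which a pair is excluded
#'   from the sparsity approximation.
#' @param seed integer seed; the estimate is deterministic given the seed.
#' @return list with `rho` (OTUs x OTUs median correlation matrix) and
#'   `omega` (median basis variances).
#' @export
sparcc <- function(otu, nEst = 20, xIter = 10, exclusionThresh = 0.1,
                   seed = 1) {
  counts <- .sampleCounts(otu)
  n <- nrow(counts); p <- ncol(counts)
  if (p < 4L)
    stop("SparCC needs at least 4 OTUs (basis solve underdetermined below)",
         call. = FALSE)
  if (n < 2L) stop("SparCC needs at least 2 samples", call. = FALSE)
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("zero-count OTU column(s): ",
         paste(colnames(counts)[zero], collapse = ", "),
         "; filter them before running SparCC", call. = FALSE)
  set.seed(.subSeed(seed, 131L))
  rhos <- array(NA_real_, c(p, p, nEst))
  omegas <- matrix(NA_real_, p, nEst)
  for (e in seq_len(nEst)) {
    g <- matrix(stats::rgamma(n * p, shape = t(counts) + 1), p, n)
    frac <- t(g) / colSums(g)          # samples x OTUs, rows sum to 1
    est <- .sparccOnce(frac, xIter, exclusionThresh)
    if (!is.null(est$rho)) {
      rhos[, , e] <- est$rho
      omegas[, e] <- est$omega
    }
  }
  rho <- apply(rhos, c(1, 2), stats::median, na.rm = TRUE)
  rho <- (rho + t(rho)) / 2
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  list(rho = rho,
       omega = stats::setNames(apply(omegas, 1L, stats::median,
                                     na.rm = TRUE), colnames(counts)))
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' Null datasets are formed by independently permuting each OTU's counts
#' across samples, breaking all between-OTU association while preserving
#' marginal count distributions. SparCC is re-estimated on each null
#' dataset and the two-sided pseudo p-value for pair (i, j) is
#' `(1 + #\{|r_null| >= |r_obs|\}) / (1 + nPerm)`, bounded below by
#' `1/(nPerm + 1)`.
#'
#' @inheritParams sparcc
#' @param rObs observed SparCC correlation matrix (from [sparcc()]).
#' @param nPerm number of permutations; at least 99 for a 0.01 threshold
#'   to be attainable (a warning is raised below that).
#' @return symmetric p-value matrix with unit diagonal.
#' @export
edgeSignificance <- function(otu, rObs, nPerm = 100, nEst = 20, xIter = 10,
                             exclusionThresh = 0.1, seed = 1) {
  counts <- .sampleCounts(otu)
  p <- ncol(counts)
  stopifnot(nrow(rObs) == p, ncol(rObs) == p)
  if (nPerm < 99)
    warning("nPerm < 99: p-values below 0.01 are unattainable",
            call. = FALSE)
  set.seed(.subSeed(seed, 139L))
  absObs <- abs(rObs)
  count <- matrix(0, p, p)
  for (b in seq_len(nPerm)) {
    perm <- apply(counts, 2L, sample)
    rownames(perm) <- rownames(counts)
    rb <- sparcc(perm, nEst = nEst, xIter = xIter,
                 exclusionThresh = exclusionThresh,
                 seed = .subSeed(seed, 1000L + b))$rho
    count <- count + (abs(rb) >= absObs)
  }
  pm <- (1 + count) / (1 + nPerm)
  pm <- (pm + t(pm)) / 2
  diag(pm) <- 1
  dimnames(pm) <- dimnames(rObs)
  pm
}

#' Threshold correlations into a co-occurrence network
#'
#' Keeps unordered OTU pairs with `|r| > rThresh` and `p < pThresh`
#' (defaults 0.7 and 0.01). Isolated nodes are retained in the node list
#' with degree 0.
#'
#' @param r symmetric correlation matrix.
#' @param p symmetric p-value matrix conformable with `r`.
#' @param rThresh,pThresh edge admission thresholds.
#' @return A [CorrelationNetwork-class] (modules not yet assigned).
#' @export
buildNetwork <- function(r, p, rThresh = 0.7, pThresh = 0.01) {
  stopifnot(nrow(r) == ncol(r), all(dim(r) == dim(p)))
  if (!isSymmetric(unname(r), tol = 1e-8) ||
      !isSymmetric(unname(p), tol = 1e-8))
    stop("r and p matrices must be symmetric", call. = FALSE)
  ids <- rownames(r)
  if (is.null(ids)) ids <- sprintf("OTU%04d", seq_len(nrow(r)))
  keep <- which(upper.tri(r) & abs(r) > rThresh & p < pThresh,
                arr.ind = TRUE)
  edges <- data.frame(otu_i = ids[keep[, 1L]], otu_j = ids[keep[, 2L]],
                      r = r[keep], p = p[keep],
                      sign = ifelse(r[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  deg <- stats::setNames(integer(length(ids)), ids)
  if (nrow(edges)) {
    t1 <- table(factor(edges$otu_i, levels = ids))
    t2 <- table(factor(edges$otu_j, levels = ids))
    deg <- as.integer(t1 + t2); names(deg) <- ids
  }
  nodes <- data.frame(otu = ids, degree = as.integer(deg),
                      module = NA_integer_, stringsAsFactors = FALSE)
  new("CorrelationNetwork", nodes = nodes, edges = edges,
      modularity = NA_real_, rThresh = rThresh, pThresh = pThresh)
}

# igraph object on |r| weights, isolated nodes included
.asIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("otu_i", "otu_j")], directed = FALSE,
    vertices = data.frame(name = net@nodes$otu))
  igraph::E(g)$weight <- abs(net@edges$r)
  igraph::E(g)$r <- net@edges$r
  g
}

#' Detect network modules by seeded Louvain
#'
#' Community detection on `|r|` edge weights (sign is retained separately
#' for strength summaries); modularity Q is the Newman weighted modularity
#' of the detected partition. An empty network leaves Q as NA.
#'
#' @param net a [CorrelationNetwork-class].
#' @param seed integer seed (Louvain visits vertices in random order).
#' @return the network with `module` filled in the node table and the
#'   `modularity` slot set.
#' @export
detectModules <- function(net, seed = 1) {
  stopifnot(is(net, "CorrelationNetwork"))
  if (nrow(net@edges) == 0L) {
    net@nodes$module <- seq_len(nrow(net@nodes))
    net@modularity <- NA_real_
    return(net)
  }
  g <- .asIgraph(net)
  set.seed(.subSeed(seed, 211L))
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  net@nodes$module <- as.integer(memb[net@nodes$otu])
  net@modularity <- igraph::modularity(g, memb,
                                       weights = igraph::E(g)$weight)
  net
}

#' Network strength and density summary
#'
#' Descriptive stability proxy: the proportion of positive edges and the
#' mean positive correlation within and between modules (communities
#' linked mainly by strong positive correlations are read as less
#' stable), plus edge density and per-node degree.
#'
#' @param net a [CorrelationNetwork-class], ideally after
#'   [detectModules()].
#' @return list with `nNodes`, `nEdges`, `density`, `positiveEdges`,
#'   `negativeEdges`, `positiveProportion`, `meanPositiveR`,
#'   `meanPositiveWithinModules`, `meanPositiveBetweenModules`,
#'   `modularity`, `nModules`.
#' @export
networkSummary <- function(net) {
  stopifnot(is(net, "CorrelationNetwork"))
  e <- net@edges
  nNodes <- nrow(net@nodes)
  nEdges <- nrow(e)
  density <- if (nNodes > 1) nEdges / choose(nNodes, 2) else 0
  pos <- e$sign == "positive"
  mods <- stats::setNames(net@nodes$module, net@nodes$otu)
  within <- if (nEdges) mods[e$otu_i] == mods[e$otu_j] else logical(0)
  meanIf <- function(v) if (length(v)) mean(v) else NA_real_
  list(nNodes = nNodes, nEdges = nEdges, density = density,
       positiveEdges = sum(pos), negativeEdges = sum(!pos),
       positiveProportion = if (nEdges) mean(pos) else NA_real_,
       meanPositiveR = meanIf(e$r[pos]),
       meanPositiveWithinModules = meanIf(e$r[pos & within]),
       meanPositiveBetweenModules = meanIf(e$r[pos & !within]),
       modularity = net@modularity,
       nModules = if (all(is.na(net@nodes$module))) NA_integer_ else
         length(unique(stats::na.omit(net@nodes$module))))
}

#' Infer a co-occurrence network from an OTU table
#'
#' Convenience wrapper running [sparcc()], [edgeSignificance()],
#' [buildNetwork()] and [detectModules()] in sequence, optionally once per
#' habitat on the habitat's samples only. A warning is raised when fewer
#' than 20 samples back an inference, where SparCC estimates are noisy.
#'
#' @inheritParams sparcc
#' @param hab habitat labels; required when `perHabitat = TRUE`.
#' @param rThresh,pThresh edge admission thresholds.
#' @param nPerm permutations for edge significance.
#' @param perHabitat build one network per habitat instead of one overall.
#' @return A [CorrelationNetwork-class], or a named list of them when
#'   `perHabitat = TRUE`.
#' @export
inferNetwork <- function(otu, hab = NULL, rThresh = 0.7, pThresh = 0.01,
                         nEst = 20, nPerm = 100, perHabitat = FALSE,
                         seed = 1) {
  counts <- .sampleCounts(otu)
  one <- function(m, s) {
    if (nrow(m) < 20)
      warning(sprintf("only %d samples: SparCC estimates will be noisy",
                      nrow(m)), call. = FALSE)
    keep <- colSums(m) > 0
    m <- m[, keep, drop = FALSE]
    r <- sparcc(m, nEst = nEst, seed = s)$rho
    p <- edgeSignificance(m, r, nPerm = nPerm, nEst = nEst,
                          seed = .subSeed(s, 3L))
    detectModules(buildNetwork(r, p, rThresh, pThresh),
                  seed = .subSeed(s, 5L))
  }
  if (!perHabitat) return(one(counts, seed))
  habf <- .habitatFactor(hab, rownames(counts), otu = otu)
  out <- lapply(levels(habf), function(h)
    one(counts[habf == h, , drop = FALSE], .subSeed(seed, match(h, levels(habf)))))
  names(out) <- levels(habf)
  out
}

#' Export a network as GEXF (for Gephi)
#'
#' Writes a minimal GEXF 1.2 document with node module attributes and
#' signed, |r|-weighted edges.
#'
#' @param net a [CorrelationNetwork-class].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeGexf <- function(net, file) {
  stopifnot(is(net, "CorrelationNetwork"))
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph mode="static" defaultedgetype="undirected">')
  w('    <attributes class="node">')
  w('      <attribute id="0" title="module" type="integer"/>')
  w('      <attribute id="1" title="degree" type="integer"/>')
  w('    </attributes>')
  w('    <nodes>')
  nd <- net@nodes
  for (i in seq_len(nrow(nd)))
    w(paste0('      <node id="%s" label="%s"><attvalues>',
             '<attvalue for="0" value="%d"/>',
             '<attvalue for="1" value="%d"/></attvalues></node>'),
      esc(nd$otu[i]), esc(nd$otu[i]),
      ifelse(is.na(nd$module[i]), -1L, nd$module[i]), nd$degree[i])
  w('    </nodes>')
  w('    <edges>')
  e <- net@edges
  for (i in seq_len(nrow(e)))
    w('      <edge id="%d" source="%s" target="%s" weight="%.6f" label="%s"/>',
      i, esc(e$otu_i[i]), esc(e$otu_j[i]), abs(e$r[i]), e$sign[i])
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(file)
}
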