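# Shared fixtures and independent oracles, all generated in code.

# standard 5x6 study grid (30 quadrats, 10 per habitat)
studyGrid <- function(seed = 1) generateLayout(5, 6, 20, seed = seed)

# counts matrix with a prescribed number of habitat-exclusive OTUs:
# 6 samples (2 per habitat); `exclusive` OTUs present in exactly one
# habitat (spread over the three), the rest present in all three.
vennCounts <- function(nOtus, exclusive) {
  stopifnot(exclusive <= nOtus)
  m <- matrix(0L, 6, nOtus,
              dimnames = list(paste0("Q", 1:6),
                              sprintf("OTU%05d", seq_len(nOtus))))
  habCol <- list(valley = 1:2, midslope = 3:4, ridge = 5:6)
  excl <- seq_len(exclusive)
  for (k in excl) m[habCol[[(k %% 3) + 1L]][1L], k] <- 1L
  rest <- setdiff(seq_len(nOtus), excl)
  m[c(1, 3, 5), rest] <- 1L
  # keep every sample total positive
  m[, nOtus] <- 1L
  if (nOtus %in% excl) m[, nOtus] <- c(1L, 0L, 0L, 0L, 0L, 0L)
  m
}

vennHabitats <- function() {
  stats::setNames(rep(habitatLevels(), each = 2), paste0("Q", 1:6))
}

# log-normal basis counts with one planted pair at basis correlation rho
plantedBasisCounts <- function(n = 50, p = 20, rho = 0.95, depth = 5000,
                               seed = 7) {
  set.seed(seed)
  Sig <- diag(p); Sig[1, 2] <- Sig[2, 1] <- rho
  L <- chol(Sig)
  mu <- stats::rnorm(p, 0, 1)
  lw <- matrix(stats::rnorm(n * p), n, p) %*% L +
    matrix(mu, n, p, byrow = TRUE)
  w <- exp(lw)
  counts <- t(apply(w, 1, function(z) stats::rmultinom(1, depth, z / sum(z))))
  dimnames(counts) <- list(sprintf("S%02d", 1:n), sprintf("OTU%02d", 1:p))
  counts
}

# two disconnected 4-cliques as (r, p) matrices; natural partition has
# modularity exactly 1/2
twoCliqueMatrices <- function(r = 0.8) {
  ids <- paste0("O", 1:8)
  R <- matrix(0, 8, 8, dimnames = list(ids, ids))
  P <- matrix(1, 8, 8, dimnames = list(ids, ids))
  for (cl in list(1:4, 5:8)) {
    for (i in cl) for (j in cl) if (i != j) {
      R[i, j] <- r; P[i, j] <- 0.001
    }
  }
  diag(R) <- 1; diag(P) <- 1
  list(r = R, p = P)
}

# Independent brute-force torus-translation oracle: enumerates all
# 4*R*C maps by vector rotation (a different construction from the
# package's matrix-index shifting) and classifies each (OTU, habitat)
# directly from the definition.
naiveTorusClasses <- function(counts, layout, labels, alpha = 0.05,
                              minRelAbund = 1e-4) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("OTU%04d", seq_len(ncol(counts)))
  q <- layout@quadrats
  R <- layout@nRows; C <- layout@nCols
  rel <- counts / rowSums(counts)
  lab <- matrix(NA_character_, R, C)
  for (i in seq_len(nrow(q)))
    lab[q$row[i] + 1L, q$col[i] + 1L] <- as.character(labels[[q$quadrat_id[i]]])
  rotRows <- function(M, k) {
    if (k == 0) return(M)
    rbind(M[(k + 1):nrow(M), , drop = FALSE], M[1:k, , drop = FALSE])
  }
  rotCols <- function(M, k) {
    if (k == 0) return(M)
    cbind(M[, (k + 1):ncol(M), drop = FALSE], M[, 1:k, drop = FALSE])
  }
  maps <- list()
  for (tf in list(identity,
                  function(M) M[, rev(seq_len(ncol(M))), drop = FALSE],
                  function(M) M[rev(seq_len(nrow(M))),
                                rev(seq_len(ncol(M))), drop = FALSE],
                  function(M) M[rev(seq_len(nrow(M))), , drop = FALSE]))
    for (dr in 0:(R - 1)) for (dc in 0:(C - 1))
      maps[[length(maps) + 1L]] <- rotCols(rotRows(tf(lab), dr), dc)
  idx <- cbind(q$row + 1L, q$col + 1L)
  relQ <- rel[q$quadrat_id, , drop = FALSE]
  lev <- habitatLevels()[habitatLevels() %in% unique(as.vector(lab))]
  out <- list()
  meanRel <- colMeans(rel)
  for (j in seq_len(ncol(rel))) {
    for (h in lev) {
      if (meanRel[j] < minRelAbund) {
        cls <- "filtered"
      } else {
        S <- vapply(maps, function(M) mean(relQ[M[idx] == h, j]),
                    numeric(1))
        sObs <- S[1L]   # first map is the identity
        pp <- mean(S >= sObs - 1e-12)
        pn <- mean(S <= sObs + 1e-12)
        cls <- if (pp <= alpha / 2) "positive" else
          if (pn <= alpha / 2) "negative" else "neutral"
      }
      out[[length(out) + 1L]] <- data.frame(
        otu = colnames(rel)[j], habitat = h, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
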