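# Community structure: richness contrast, Venn partition, Bray-Curtis,
# NMDS, rarefaction, ternary enrichment.

test_that("Kruskal-Wallis H matches the tie-free rank formula", {
  # richness per sample: {1,2}, {3,4}, {5,6} across three habitats;
  # hand evaluation of H = 12/(n(n+1)) * sum n_g (Rbar_g - (n+1)/2)^2
  counts <- matrix(0L, 6, 6)
  for (i in 1:6) counts[i, seq_len(i)] <- 1L
  rownames(counts) <- paste0("Q", 1:6)
  hab <- stats::setNames(rep(habitatLevels(), each = 2), paste0("Q", 1:6))
  res <- richnessKruskal(counts, hab)
  expect_equal(res$richness$richness, 1:6, ignore_attr = TRUE)
  expect_equal(res$H, 32 / 7, tolerance = 1e-10)   # 12/42 * (2*4 + 0 + 2*4)
  expect_equal(res$df, 2L)
})

test_that("identical richness everywhere gives H = 0, p = 1", {
  counts <- matrix(1L, 6, 5, dimnames = list(paste0("Q", 1:6), NULL))
  res <- richnessKruskal(counts, vennHabitats())
  expect_equal(res$H, 0)
  expect_equal(res$p, 1)
})

test_that("richness contrast recovers a valley > midslope > ridge gradient", {
  # emulation table with occurrence probability decreasing along the
  # elevation gradient, pushed through the full richness/KW path
  g <- studyGrid(seed = 3)
  elev <- g$layout@quadrats$elevation
  prob <- 0.9 - 0.6 * (rank(elev) - 1) / (length(elev) - 1)
  set.seed(41)
  counts <- t(vapply(prob, function(p) rbinom(200, 5, p), integer(200)))
  rownames(counts) <- g$layout@quadrats$quadrat_id
  res <- richnessKruskal(counts, g$habitat)
  med <- stats::setNames(res$summary$median, res$summary$habitat)
  expect_true(med["valley"] > med["midslope"])
  expect_true(med["midslope"] > med["ridge"])
  expect_lt(res$p, 0.01)
})

test_that("Venn partition is disjoint, exhaustive, and drops absent OTUs", {
  counts <- rbind(
    Q1 = c(1L, 0L, 1L, 0L, 2L),
    Q2 = c(2L, 0L, 0L, 0L, 1L),
    Q3 = c(0L, 3L, 1L, 0L, 1L),
    Q4 = c(0L, 1L, 0L, 0L, 0L),
    Q5 = c(0L, 0L, 1L, 0L, 2L),
    Q6 = c(0L, 0L, 0L, 0L, 1L))
  hab <- vennHabitats()
  v <- partitionOtus(counts, hab)
  r <- vennRegions(v)
  # OTU1 valley-only, OTU2 midslope-only, OTU3 all three, OTU4 absent,
  # OTU5 all three
  expect_equal(unname(r["valley"]), 1L)
  expect_equal(unname(r["midslope"]), 1L)
  expect_equal(unname(r["valley&midslope&ridge"]), 2L)
  expect_equal(sum(r), 4L)
  expect_equal(v@total, 4L)
  expect_equal(v@exclusivityPct, 50)
})

test_that("region counts always sum to the observed OTU total", {
  g <- generateLayout(2, 3, 20, seed = 5)
  for (sd in 1:4) {
    otu <- generateOtuTable(g$layout, g$habitat, nOtus = 80, depth = 200,
                            seed = sd)
    v <- partitionOtus(otu)
    expect_equal(sum(vennRegions(v)),
                 sum(colSums(t(otuCounts(otu))) > 0))
  }
})

test_that("exclusivity percentages reproduce the reporting arithmetic", {
  v <- partitionOtus(vennCounts(200, 121), vennHabitats())
  expect_equal(v@exclusivityPct, round(100 * 121 / 200, 2))
})

test_that("Bray-Curtis matches hand evaluation and its limits", {
  expect_equal(as.numeric(brayCurtis(rbind(a = c(2, 0, 4), b = c(1, 3, 1)))),
               7 / 11, tolerance = 1e-12)
  expect_equal(as.numeric(brayCurtis(rbind(a = c(3, 1), b = c(3, 1)))), 0)
  expect_equal(as.numeric(brayCurtis(rbind(a = c(3, 0), b = c(0, 5)))), 1)
  expect_error(brayCurtis(rbind(a = c(1, 1), b = c(0, 0))), "b")
})

test_that("Bray-Curtis is a proper bounded dissimilarity", {
  g <- generateLayout(2, 3, 20, seed = 6)
  otu <- generateOtuTable(g$layout, g$habitat, nOtus = 50, depth = 300,
                          seed = 2)
  d <- as.matrix(brayCurtis(otu))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("NMDS recovers planar configurations with negligible stress", {
  set.seed(31)
  xy <- matrix(runif(24), 12, 2)
  d <- dist(xy)
  ord <- nmdsOrdination(d, k = 2, nStarts = 5, seed = 1)
  expect_lt(ordinationStress(ord), 1e-3)
  expect_equal(dim(ordinationPoints(ord)), c(12L, 2L))
})

test_that("NMDS stress is scale invariant and improves with restarts", {
  set.seed(32)
  x <- matrix(rnorm(10 * 6), 10, 6)
  d <- as.matrix(dist(x))
  s1 <- ordinationStress(nmdsOrdination(d, k = 2, nStarts = 1, seed = 7))
  s10 <- ordinationStress(nmdsOrdination(d, k = 2, nStarts = 10, seed = 7))
  s2 <- ordinationStress(nmdsOrdination(2 * d, k = 2, nStarts = 1, seed = 7))
  expect_lte(s10, s1 + 1e-12)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("three equidistant samples embed as an equilateral triangle", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  ord <- nmdsOrdination(d, k = 2, nStarts = 3, seed = 2)
  pts <- ordinationPoints(ord)
  side <- as.numeric(dist(pts))
  expect_lt(diff(range(side)) / mean(side), 1e-3)
})

test_that("non-symmetric dissimilarity input is rejected", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nmdsOrdination(m), "symmetric")
})

test_that("rarefaction closed form hits its exact limits", {
  counts <- matrix(c(5L, 3L, 2L, 0L), 1, 4,
                   dimnames = list("Q1", paste0("O", 1:4)))
  expect_equal(as.numeric(rarefyExpected(counts, 10)), 3)  # d = N
  expect_equal(as.numeric(rarefyExpected(counts, 1)), 1)   # d = 1
  r <- as.numeric(rarefyExpected(counts, c(1, 3, 5, 8, 10)))
  expect_true(all(diff(r) >= 0))
  expect_error(rarefyExpected(counts, 11), "exceeds")
})

test_that("rarefaction closed form matches Monte-Carlo subsampling", {
  x <- c(12L, 7L, 4L, 2L, 1L, 1L, 1L)
  counts <- matrix(x, 1, length(x),
                   dimnames = list("Q1", paste0("O", seq_along(x))))
  d <- sum(x) %/% 2
  closed <- as.numeric(rarefyExpected(counts, d))
  set.seed(99)
  pool <- rep(seq_along(x), x)
  mc <- mean(replicate(10000, length(unique(sample(pool, d)))))
  expect_lt(abs(closed - mc) / mc, 0.01)
})

test_that("ternary coordinates normalize, assign, and flag absent OTUs", {
  counts <- rbind(
    Q1 = c(10L, 90L, 0L), Q2 = c(30L, 70L, 0L),
    Q3 = c(20L, 80L, 0L), Q4 = c(20L, 80L, 0L),
    Q5 = c(0L, 100L, 0L), Q6 = c(20L, 80L, 0L))
  tern <- ternaryEnrichment(counts, vennHabitats())
  # hand case: habitat means 0.2, 0.2, 0.1 -> (0.4, 0.4, 0.2), tie to valley
  expect_equal(unlist(tern[1, c("valley", "midslope", "ridge")]),
               c(valley = 0.4, midslope = 0.4, ridge = 0.2),
               tolerance = 1e-12)
  expect_equal(tern$assigned[1], "valley")
  expect_true(tern$excluded[3])
  expect_true(is.na(tern$valley[3]))
  ok <- !tern$excluded
  expect_equal(rowSums(tern[ok, c("valley", "midslope", "ridge")]),
               rep(1, sum(ok)), ignore_attr = TRUE)
})

test_that("a valley-only OTU sits on the valley vertex", {
  counts <- rbind(
    Q1 = c(5L, 5L), Q2 = c(3L, 7L), Q3 = c(0L, 10L),
    Q4 = c(0L, 10L), Q5 = c(0L, 10L), Q6 = c(0L, 10L))
  tern <- ternaryEnrichment(counts, vennHabitats())
  expect_equal(unlist(tern[1, c("valley", "midslope", "ridge")]),
               c(valley = 1, midslope = 0, ridge = 0), tolerance = 1e-12)
})
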