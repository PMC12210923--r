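# Torus-translation habitat association: statistic, map enumeration,
# classification, summaries.

test_that("habitat statistic matches direct arithmetic", {
  counts <- rbind(Q1 = c(2L, 2L), Q2 = c(1L, 3L),
                  Q3 = c(0L, 4L), Q4 = c(3L, 1L))
  hab <- stats::setNames(c("valley", "ridge", "valley", "ridge"),
                         paste0("Q", 1:4))
  S <- habitatStat(counts, hab)
  # otu1 rel: .5, .25, 0, .75 -> valley mean .25, ridge mean .5
  expect_equal(S["OTU0001", "valley"], 0.25, ignore_attr = TRUE)
  expect_equal(S["OTU0001", "ridge"], 0.5, ignore_attr = TRUE)
  expect_equal(S["OTU0002", "valley"], 0.75, ignore_attr = TRUE)
})

test_that("habitat means conserve the overall mean relative abundance", {
  g <- studyGrid(seed = 4)
  otu <- generateOtuTable(g$layout, g$habitat, nOtus = 60, depth = 800,
                          seed = 4)
  S <- habitatStat(otu)
  counts <- t(otuCounts(otu))
  rel <- counts / rowSums(counts)
  habf <- habitats(otu)
  w <- as.numeric(table(habf)[colnames(S)]) / nrow(counts)
  expect_equal(as.numeric(S %*% w), unname(colMeans(rel)),
               tolerance = 1e-12)
})

test_that("an OTU with uniform relative abundance is S-invariant", {
  counts <- matrix(10L, 4, 3, dimnames = list(paste0("Q", 1:4), NULL))
  hab <- stats::setNames(c("valley", "valley", "ridge", "ridge"),
                         paste0("Q", 1:4))
  S <- habitatStat(counts, hab)
  expect_true(all(abs(S - 1 / 3) < 1e-12))
})

test_that("torus maps enumerate 4RC label-preserving maps with identity", {
  g1 <- generateLayout(1, 3, 20, seed = 1)
  m1 <- torusMaps(g1$habitat, g1$layout)
  expect_equal(nrow(m1), 12L)          # 4 * 1 * 3
  g <- generateLayout(2, 3, 20, seed = 2)
  maps <- torusMaps(g$habitat, g$layout)
  expect_equal(nrow(maps), 24L)
  orig <- as.character(g$habitat@labels[colnames(maps)])
  expect_equal(unname(maps[1, ]), orig)  # identity first
  for (i in seq_len(nrow(maps)))
    expect_equal(sort(maps[i, ]), sort(orig), ignore_attr = TRUE)
})

test_that("a single-cell torus yields four identical maps", {
  lay <- PlotLayout(1, 1, 20, data.frame(row = 0L, col = 0L,
                                         quadrat_id = "Q1",
                                         elevation = 0))
  hab <- stats::setNames(factor("valley", levels = habitatLevels()), "Q1")
  maps <- torusMaps(hab, lay)
  expect_equal(nrow(maps), 4L)
  expect_true(all(maps == "valley"))
})

test_that("uniform OTUs are classified neutral everywhere", {
  g <- studyGrid(seed = 5)
  counts <- matrix(7L, 30, 6,
                   dimnames = list(g$layout@quadrats$quadrat_id, NULL))
  res <- torusTest(counts, g$habitat, g$layout, minRelAbund = 0)
  expect_true(all(associations(res)$class == "neutral"))
})

test_that("classifications agree with the exhaustive brute-force oracle", {
  g <- generateLayout(3, 4, 20, seed = 6)
  otu <- generateOtuTable(g$layout, g$habitat, nOtus = 40,
                          specialistFraction = 0.3,
                          effectLogFold = log(8), depth = 2000, seed = 6)
  counts <- t(otuCounts(otu))
  res <- associations(torusTest(otu))
  oracle <- naiveTorusClasses(counts, g$layout,
                              as.list(g$habitat@labels))
  merged <- merge(res, oracle, by = c("otu", "habitat"),
                  suffixes = c("_pkg", "_oracle"))
  expect_equal(nrow(merged), nrow(res))
  expect_equal(merged$class_pkg, merged$class_oracle)
})

test_that("a valley-exclusive OTU on a banded grid is valley-positive", {
  g <- studyGrid(seed = 1)
  q <- g$layout@quadrats
  habf <- g$habitat@labels[q$quadrat_id]
  counts <- matrix(50L, 30, 5, dimnames = list(q$quadrat_id, NULL))
  counts[, 1L] <- ifelse(habf == "valley", 200L, 0L)
  res <- associations(torusTest(counts, g$habitat, g$layout,
                                minRelAbund = 0))
  expect_equal(res$class[res$otu == "OTU0001" & res$habitat == "valley"],
               "positive")
  # the ridge band never overlaps the valley band under many torus
  # shifts, so S_null ties at 0 keep the ridge call from being negative:
  # verify agreement with the oracle rather than asserting a sign
  oracle <- naiveTorusClasses(counts, g$layout,
                              as.list(g$habitat@labels), minRelAbund = 0)
  merged <- merge(res, oracle, by = c("otu", "habitat"),
                  suffixes = c("_pkg", "_oracle"))
  expect_equal(merged$class_pkg, merged$class_oracle)
})

test_that("p-values are never zero and the observed map bounds them", {
  g <- generateLayout(2, 3, 20, seed = 7)
  otu <- generateOtuTable(g$layout, g$habitat, nOtus = 30, depth = 400,
                          seed = 7)
  res <- suppressWarnings(torusTest(otu, minRelAbund = 0))
  a <- associations(res)
  expect_true(all(a$p_pos >= 1 / res@nMaps))
  expect_true(all(a$p_neg >= 1 / res@nMaps))
  expect_true(all(a$p_pos + a$p_neg >= 1))
})

test_that("relabelling habitats permutes rows but preserves p-values", {
  g <- generateLayout(2, 3, 20, seed = 8)
  otu <- generateOtuTable(g$layout, g$habitat, nOtus = 25, depth = 500,
                          seed = 8)
  counts <- t(otuCounts(otu))
  a1 <- associations(suppressWarnings(
    torusTest(counts, g$habitat, g$layout, minRelAbund = 0)))
  # swap valley <-> ridge labels
  sw <- c(valley = "ridge", midslope = "midslope", ridge = "valley")
  hab2 <- HabitatMap(stats::setNames(
    sw[as.character(g$habitat@labels)], names(g$habitat@labels)))
  a2 <- associations(suppressWarnings(
    torusTest(counts, hab2, g$layout, minRelAbund = 0)))
  k1 <- a1[a1$habitat == "valley", c("otu", "p_pos", "p_neg")]
  k2 <- a2[a2$habitat == "ridge", c("otu", "p_pos", "p_neg")]
  expect_equal(k1$p_pos, k2$p_pos[match(k1$otu, k2$otu)])
  expect_equal(k1$p_neg, k2$p_neg[match(k1$otu, k2$otu)])
})

test_that("rare OTUs are filtered at the relative-abundance threshold", {
  g <- generateLayout(2, 3, 20, seed = 9)
  q <- g$layout@quadrats
  counts <- matrix(1000L, 6, 3, dimnames = list(q$quadrat_id, NULL))
  counts[, 2L] <- c(1L, 0L, 0L, 0L, 0L, 0L)   # mean rel ~ 8e-5 < 1e-4
  res <- associations(suppressWarnings(
    torusTest(counts, g$habitat, g$layout)))
  expect_true(all(res$class[res$otu == "OTU0002"] == "filtered"))
  expect_true(all(res$class[res$otu == "OTU0001"] != "filtered"))
})

test_that("non-grid layouts fall back to seeded permutations", {
  g <- generateLayout(2, 3, 20, seed = 10)
  otu <- generateOtuTable(g$layout, g$habitat, nOtus = 20, depth = 300,
                          seed = 10)
  counts <- t(otuCounts(otu))[1:5, ]           # drop a quadrat: not a grid
  habf <- g$habitat@labels[rownames(counts)]
  res1 <- suppressMessages(torusTest(counts, habf, g$layout,
                                     fallbackNPerm = 199, seed = 3,
                                     minRelAbund = 0))
  res2 <- suppressMessages(torusTest(counts, habf, g$layout,
                                     fallbackNPerm = 199, seed = 3,
                                     minRelAbund = 0))
  expect_equal(res1@nullType, "permutation")
  expect_equal(res1@nMaps, 200L)
  expect_identical(associations(res1), associations(res2))
})

test_that("a warning is raised when the grid is too small for alpha", {
  lay <- generateLayout(1, 3, 20, seed = 1)
  counts <- matrix(c(5L, 1L, 9L, 5L, 9L, 1L), 3, 2,
                   dimnames = list(lay$layout@quadrats$quadrat_id, NULL))
  expect_warning(torusTest(counts, lay$habitat, lay$layout,
                           minRelAbund = 0),
                 "unattainable")
})

test_that("association summaries partition, count and recount correctly", {
  g <- studyGrid(seed = 11)
  otu <- generateOtuTable(g$layout, g$habitat, nOtus = 150,
                          specialistFraction = 0.3,
                          effectLogFold = log(8), seed = 11)
  res <- torusTest(otu)
  a <- associations(res)
  s <- summarizeAssociations(res)
  expect_equal(s$denominators$totalOtus, 150L)
  expect_equal(s$denominators$testedOtus + s$denominators$filteredOtus, 150L)
  # independent recount by set algebra
  posSets <- lapply(habitatLevels(), function(h)
    unique(a$otu[a$habitat == h & a$class == "positive"]))
  expect_equal(s$otuLevel$positive, length(Reduce(union, posSets)))
  expect_equal(s$perHabitat$positive,
               vapply(posSets, length, integer(1)))
  expect_equal(sum(s$vennPositive),
               length(Reduce(union, posSets)))
  # per-OTU class partition
  tab <- table(a$class)
  expect_equal(sum(tab), nrow(a))
})

test_that("an all-neutral result summarizes to zero counts", {
  g <- generateLayout(2, 3, 20, seed = 12)
  counts <- matrix(9L, 6, 4,
                   dimnames = list(g$layout@quadrats$quadrat_id, NULL))
  s <- summarizeAssociations(suppressWarnings(
    torusTest(counts, g$habitat, g$layout, minRelAbund = 0)))
  expect_equal(s$otuLevel$significant, 0L)
  expect_equal(s$otuLevel$positivePct, 0)
  expect_false(s$allThreePositive)
})
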