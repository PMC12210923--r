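# Generator: layout/habitat geometry, environment structure, count tables.

test_that("layout realizes the 30-quadrat, 10-per-habitat study design", {
  g <- studyGrid(seed = 1)
  expect_s4_class(g$layout, "PlotLayout")
  expect_equal(nrow(g$layout@quadrats), 30L)
  expect_equal(unname(table(g$habitat@labels)), c(10L, 10L, 10L),
               ignore_attr = TRUE)
  expect_true(all(is.finite(g$layout@quadrats$elevation)))
})

test_that("a 1x3 grid yields one quadrat per habitat", {
  g <- generateLayout(1, 3, 20, seed = 4)
  expect_equal(sort(as.character(g$habitat@labels)),
               sort(habitatLevels()))
})

test_that("grids below 3 quadrats are rejected", {
  expect_error(generateLayout(1, 2, 20, seed = 1), "at least 3")
})

test_that("habitat assignment matches an independent sort-and-split oracle", {
  for (sd in 1:5) {
    g <- generateLayout(4, 7, 10, seed = sd)
    elev <- g$layout@quadrats$elevation
    n <- length(elev)
    # oracle: sort elevations, split into near-equal thirds
    sizes <- diff(round(seq(0, n, length.out = 4)))
    oracle <- character(n)
    oracle[order(elev)] <- rep(habitatLevels(), times = sizes)
    expect_equal(as.character(g$habitat@labels), oracle)
    expect_lte(diff(range(table(g$habitat@labels))), 1)
  }
})

test_that("environment has all covariates, finite, wetter valleys", {
  g <- studyGrid(seed = 2)
  env <- generateEnvironment(g$layout, g$habitat, seed = 2)
  expect_setequal(colnames(env),
                  c("pH", "SWC", "SOM", "P", "N", "elevation", "slope",
                    "aspect", "concavity", "LT", "SR", "TR", "CC", "ALA",
                    "LAI", "WA", "WR"))
  expect_equal(nrow(env), 30L)
  expect_true(all(vapply(env, function(v) all(is.finite(v)), logical(1))))
  expect_lt(cor(env$SWC, env$elevation), 0)
  expect_lt(cor(env$SOM, env$elevation), 0)
  expect_lt(cor(env$N, env$elevation), 0)
  expect_identical(env, generateEnvironment(g$layout, g$habitat, seed = 2))
})

test_that("count tables are reproducible bit-for-bit and respect depth", {
  g <- generateLayout(2, 3, 20, seed = 3)
  o1 <- generateOtuTable(g$layout, g$habitat, nOtus = 40, depth = 500,
                         seed = 9)
  o2 <- generateOtuTable(g$layout, g$habitat, nOtus = 40, depth = 500,
                         seed = 9)
  expect_identical(otuCounts(o1), otuCounts(o2))
  expect_true(all(colSums(otuCounts(o1)) == 500))
  o3 <- generateOtuTable(g$layout, g$habitat, nOtus = 40, depth = 500,
                         seed = 10)
  expect_false(identical(otuCounts(o1), otuCounts(o3)))
})

test_that("specialistFraction = 0 yields a specialist-free ground truth", {
  g <- generateLayout(2, 3, 20, seed = 3)
  otu <- generateOtuTable(g$layout, g$habitat, nOtus = 25,
                          specialistFraction = 0, seed = 1)
  gt <- groundTruth(otu)
  expect_false(any(gt$specialist))
  expect_true(all(gt$logFold == 0))
})

test_that("ground truth records specialists with their habitat and effect", {
  g <- studyGrid(seed = 1)
  otu <- generateOtuTable(g$layout, g$habitat, nOtus = 100,
                          specialistFraction = 0.3, effectLogFold = log(4),
                          depth = 1000, seed = 6)
  gt <- groundTruth(otu)
  expect_equal(sum(gt$specialist), 30L)
  expect_true(all(gt$habitat[gt$specialist] %in% habitatLevels()))
  expect_true(all(is.na(gt$habitat[!gt$specialist])))
  expect_true(all(gt$logFold[gt$specialist] == log(4)))
})

test_that("dilute specialists are enriched about 8-fold in their habitat", {
  # geometric mean of in/out relative-abundance ratios over dilute
  # specialists, pooled over seeds; overdispersion kept small so the
  # Dirichlet noise does not swamp the Monte-Carlo average
  g <- studyGrid(seed = 1)
  lr <- c()
  for (sd in 1:10) {
    otu <- generateOtuTable(g$layout, g$habitat, nOtus = 400,
                            specialistFraction = 0.02,
                            effectLogFold = log(8), depth = 10000,
                            overdispersion = 1e-4, seed = sd)
    gt <- groundTruth(otu)
    hab <- habitats(otu)
    rel <- t(otuCounts(otu)) / colSums(otuCounts(otu))
    mr <- colMeans(rel)
    for (h in habitatLevels()) {
      sp <- gt$otu[gt$specialist & !is.na(gt$habitat) & gt$habitat == h]
      sp <- sp[mr[sp] > 1e-4 & mr[sp] < 0.005]
      if (!length(sp)) next
      lr <- c(lr, log(colMeans(rel[hab == h, sp, drop = FALSE]) /
                        colMeans(rel[hab != h, sp, drop = FALSE])))
    }
  }
  expect_gt(length(lr), 30)
  expect_lt(abs(exp(mean(lr)) - 8) / 8, 0.15)
})

test_that("expected counts scale linearly with depth", {
  g <- generateLayout(3, 4, 20, seed = 2)
  tot1 <- tot3 <- 0
  for (sd in 1:20) {
    o1 <- generateOtuTable(g$layout, g$habitat, nOtus = 100,
                           depth = 10000, seed = sd)
    o3 <- generateOtuTable(g$layout, g$habitat, nOtus = 100,
                           depth = 30000, seed = sd)
    c1 <- rowSums(otuCounts(o1)); c3 <- rowSums(otuCounts(o3))
    top <- names(sort(c1, decreasing = TRUE))[1:30]
    tot1 <- tot1 + sum(c1[top]); tot3 <- tot3 + sum(c3[top])
  }
  expect_lt(abs(tot3 / tot1 - 3) / 3, 0.02)
})

test_that("invalid generator arguments are rejected", {
  g <- generateLayout(2, 3, 20, seed = 3)
  expect_error(generateOtuTable(g$layout, g$habitat, specialistFraction = 1.2),
               "specialistFraction")
  expect_error(generateOtuTable(g$layout, g$habitat, depth = 10.5), "depth")
  expect_error(generateOtuTable(g$layout, g$habitat, overdispersion = 0),
               "overdispersion")
})
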