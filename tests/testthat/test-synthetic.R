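test_that("empty scenes have empty ground truth and render background", {
  sc <- generateScene(sceneParams(n_globules = 0, n_cells = 0, seed = 1,
                                  noise = "none", blur_sigma = 0))
  gt <- groundTruth(sc)
  expect_identical(nrow(gt$globules), 0L)
  expect_identical(nrow(gt$crescents), 0L)
  expect_identical(nrow(gt$cells), 0L)
  expect_true(is.na(groundTruthCellularShare(sc)))
  stack <- renderChannels(sc)
  expect_true(all(rnaChannel(stack) == 50))
})

test_that("exact-count incidence places that many distinct owners", {
  sc <- generateScene(sceneParams(n_globules = 100, crescent_count = 30,
                                  n_cells = 0, seed = 5))
  gt <- groundTruth(sc)
  expect_identical(nrow(gt$crescents), 30L)
  expect_identical(length(unique(gt$crescents$owner_id)), 30L)
  expect_identical(sum(gt$globules$has_crescent), 30L)
  expect_error(sceneParams(n_globules = 10, crescent_count = 11))
})

test_that("identical seeds give identical scenes and identical pixels", {
  p <- sceneParams(seed = 1234, n_cells = 5)
  a <- generateScene(p); b <- generateScene(p)
  expect_identical(groundTruth(a), groundTruth(b))
  sa <- renderChannels(a); sb <- renderChannels(b)
  expect_identical(dicChannel(sa), dicChannel(sb))
  expect_identical(rnaChannel(sa), rnaChannel(sb))
  expect_identical(dnaChannel(sa), dnaChannel(sb))
  # a different seed changes the scene
  expect_false(identical(groundTruth(a),
                         groundTruth(generateScene(sceneParams(seed = 1235,
                                                               n_cells = 5)))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- .Random.seed
  invisible(generateScene(sceneParams(seed = 1, n_globules = 20)))
  expect_identical(.Random.seed, before)
})

test_that("pre-noise RNA signal is conserved exactly, and under blur", {
  p <- sceneParams(seed = 6, blur_sigma = 0, noise = "none", n_cells = 6)
  sc <- generateScene(p)
  stack <- renderChannels(sc)
  gt <- groundTruth(sc)
  excess <- sum(rnaChannel(stack)) - length(rnaChannel(stack)) * 50
  expect_equal(excess, sum(gt$crescents$rna_signal) +
                 sum(gt$cells$rna_signal))
  dnaExcess <- sum(dnaChannel(stack)) - length(dnaChannel(stack)) * 50
  expect_equal(dnaExcess, sum(gt$cells$dna_signal))

  # blur displaces but conserves total signal (objects sit off the border)
  pb <- sceneParams(seed = 6, blur_sigma = 1, noise = "none", n_cells = 6)
  stB <- renderChannels(generateScene(pb))
  excessB <- sum(rnaChannel(stB)) - length(rnaChannel(stB)) * 50
  expect_lt(abs(excessB - excess) / excess, 0.001)
})

test_that("crescent pixels carry no DNA signal (channel separation)", {
  p <- sceneParams(seed = 8, blur_sigma = 0, noise = "none", n_cells = 3)
  sc <- generateScene(p)
  stack <- renderChannels(sc)
  crescentPx <- rnaChannel(stack) > 50 & dnaChannel(stack) == 50
  cellPx <- dnaChannel(stack) > 50
  gt <- groundTruth(sc)
  expect_equal(sum(crescentPx), sum(gt$crescents$area_px2))
  expect_equal(sum(cellPx), sum(gt$cells$area_px2))
})

test_that("globule placement honours the minimum separation", {
  sc <- generateScene(sceneParams(seed = 15, n_globules = 120,
                                  min_separation = 6))
  g <- groundTruth(sc)$globules
  d <- as.matrix(dist(g[, c("x", "y")]))
  clearance <- d - outer(g$radius, g$radius, `+`)
  diag(clearance) <- Inf
  expect_gte(min(clearance), 6)
})

test_that("infeasible packings fail with an informative error", {
  expect_error(generateScene(sceneParams(width = 64, height = 64,
                                         n_globules = 500)),
               "infeasible")
})

test_that("share calibration hits the requested cellular share exactly", {
  for (target in c(35, 8)) {
    # few enough cells that the balancing crescent count stays feasible
    n_cells <- if (target >= 20) 15 else 4
    p <- calibrateSceneParams(sceneParams(n_cells = n_cells, seed = 99),
                              target)
    sc <- generateScene(p)
    expect_equal(groundTruthCellularShare(sc), target)
    # effective level stays within a sane factor of the base level
    eff <- sceneParameters(sc)$crescent_rna_level_effective
    expect_gt(eff / 400, 1 / 4)
    expect_lt(eff / 400, 4)
  }
  expect_error(generateScene(
    sceneParams(n_cells = 0, target_cellular_share = 10)), "requires")
})
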