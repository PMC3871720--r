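test_that("uniform planes yield no objects, with a warning under Otsu", {
  flat <- matrix(5, 64, 64)
  expect_warning(g <- segmentGlobules(flat, synthSegParams()),
                 "zero-variance")
  expect_identical(nrow(g$records), 0L)
  expect_warning(r <- segmentChannelObjects(flat, 5, segmentationParams()),
                 "zero-variance")
  expect_identical(nrow(r$objects), 0L)
})

test_that("a single rasterized disk is recovered with tight centroid/area", {
  plane <- diskPlane(129, 129, 64, 64, 20, value = 300)
  truth <- sum(plane > 0)   # pixel-count oracle on the raster
  g <- segmentGlobules(plane, synthSegParams(smoothing_sigma = 0))
  expect_identical(nrow(g$records), 1L)
  rec <- g$records
  expect_lt(abs(rec$x - 64), 0.5)
  expect_lt(abs(rec$y - 64), 0.5)
  expect_identical(rec$area_px2, as.numeric(truth))
  expect_lt(abs(rec$area_px2 - pi * 400) / (pi * 400), 0.05)
  expect_gt(rec$circularity, 0.9)
})

test_that("the gradient strategy recovers a rim-only (DIC-style) globule", {
  h <- 129
  d2 <- outer(((1:h) - 65)^2, ((1:h) - 65)^2, `+`)
  plane <- matrix(500, h, h)
  plane[d2 <= 20^2 & d2 >= 18^2] <- 800   # bright rim, hollow interior
  g <- segmentGlobules(plane, segmentationParams(
    globule_strategy = "gradient"))
  expect_identical(nrow(g$records), 1L)
  expect_lt(abs(g$records$x - 64), 0.5)
  # hole-filled: area is the disk, not the annulus
  expect_gt(g$records$area_px2, 0.85 * pi * 400)
})

test_that("noise-free renders give exactly one detection per true globule", {
  sc <- quickScene(seed = 21, blur_sigma = 0, noise = "none")
  g <- segmentGlobules(dicChannel(renderChannels(sc)),
                       synthSegParams(smoothing_sigma = 0))
  expect_identical(nrow(g$records), nrow(groundTruth(sc)$globules))
})

test_that("the channel area filter and intensity arithmetic are exact", {
  plane <- matrix(10, 64, 64)
  plane[10:14, 10:19] <- 100   # 50 px blob
  plane[40:44, 40:45] <- 100   # 30 px blob
  p <- segmentationParams(threshold_method = "fixed",
                          fixed_thresholds = c(rna = 55),
                          smoothing_sigma = 0)
  r <- segmentChannelObjects(plane, min_area = 40, p)
  expect_identical(nrow(r$objects), 1L)
  # background = median below threshold = 10; 50 px * (100 - 10)
  expect_equal(r$objects$integrated_intensity, 4500)
  expect_equal(r$objects$area_px2, 50)
  r2 <- segmentChannelObjects(plane, min_area = 20, p)
  expect_identical(nrow(r2$objects), 2L)
})

test_that("thin diagonal chains stay one object (8-connectivity)", {
  plane <- matrix(0, 32, 32)
  for (k in 0:10) plane[10 + k, 10 + k] <- 100
  p <- segmentationParams(threshold_method = "fixed",
                          fixed_thresholds = c(rna = 50),
                          smoothing_sigma = 0)
  r <- segmentChannelObjects(plane, min_area = 5, p)
  expect_identical(nrow(r$objects), 1L)
  expect_equal(r$objects$area_px2, 11)
})

test_that("colocalization classifies by DNA overlap with inclusive boundary", {
  lab <- matrix(0L, 32, 32)
  lab[5, 1:10] <- 1L    # object 1: 10 px
  lab[20, 1:10] <- 2L   # object 2: 10 px
  objs <- data.frame(object_id = 1:2, x = c(4.5, 4.5), y = c(4, 19),
                     area_px2 = c(10, 10), integrated_intensity = c(1, 1))
  p <- segmentationParams(coloc_fraction = 0.3, dna_dilation_px = 0L)
  # object 1: exactly 3 of 10 px overlap -> fraction 0.3 -> cell (inclusive)
  dna <- matrix(FALSE, 32, 32)
  dna[5, 1:3] <- TRUE
  cls <- classifyRnaObjects(lab, objs, dna, p)
  expect_identical(nrow(cls$cells), 1L)
  expect_identical(nrow(cls$crescents), 1L)
  expect_equal(cls$cells$dna_overlap_fraction, 0.3)
  expect_identical(cls$crescents$object_id, 2L)

  # full overlap -> cell; zero overlap -> crescent
  dnaFull <- matrix(TRUE, 32, 32)
  expect_identical(nrow(classifyRnaObjects(lab, objs, dnaFull, p)$cells), 2L)
  dnaNone <- matrix(FALSE, 32, 32)
  expect_identical(nrow(classifyRnaObjects(lab, objs, dnaNone, p)$crescents),
                   2L)
  expect_error(classifyRnaObjects(lab, objs, matrix(FALSE, 32, 31), p),
               "shape")
})

test_that("every RNA object lands in exactly one class (partition)", {
  sc <- quickScene(seed = 31)
  stack <- renderChannels(sc)
  p <- synthSegParams()
  r <- segmentChannelObjects(rnaChannel(stack), p$min_rna_area, p)
  d <- segmentChannelObjects(dnaChannel(stack), p$min_dna_area, p, "dna")
  for (cf in c(0, 0.3, 0.7, 1)) {
    pc <- synthSegParams(coloc_fraction = cf)
    cls <- classifyRnaObjects(r$labels, r$objects, d$labels > 0, pc)
    expect_identical(nrow(cls$crescents) + nrow(cls$cells),
                     nrow(r$objects))
  }
})

test_that("raising min_area or coloc_fraction never increases counts", {
  sc <- quickScene(seed = 32)
  stack <- renderChannels(sc)
  p <- synthSegParams()
  r <- segmentChannelObjects(rnaChannel(stack), p$min_rna_area, p)
  d <- segmentChannelObjects(dnaChannel(stack), p$min_dna_area, p, "dna")
  nObj <- vapply(c(5, 20, 60, 150), function(a)
    nrow(segmentChannelObjects(rnaChannel(stack), a, p)$objects), numeric(1))
  expect_true(all(diff(nObj) <= 0))
  nCells <- vapply(c(0.1, 0.3, 0.6, 0.9), function(cf)
    nrow(classifyRnaObjects(r$labels, r$objects, d$labels > 0,
                            synthSegParams(coloc_fraction = cf))$cells),
    numeric(1))
  expect_true(all(diff(nCells) <= 0))
})

test_that("per-object areas sum to the nonzero label-map pixel count", {
  sc <- quickScene(seed = 33)
  stack <- renderChannels(sc)
  p <- synthSegParams()
  g <- segmentGlobules(dicChannel(stack), p)
  expect_identical(sum(g$records$area_px2), as.numeric(sum(g$labels > 0)))
  r <- segmentChannelObjects(rnaChannel(stack), p$min_rna_area, p)
  expect_identical(sum(r$objects$area_px2), as.numeric(sum(r$labels > 0)))
})

test_that("a signal-free noisy plane yields no objects (contrast guard)", {
  set.seed(99)
  noise <- matrix(pmax(rnorm(96 * 96, 50, 5), 0), 96, 96)
  r <- segmentChannelObjects(noise, 5, segmentationParams(), "dna")
  expect_identical(nrow(r$objects), 0L)
})
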