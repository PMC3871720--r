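test_that("ChannelStack validity enforces shape, finiteness and pixel size", {
  z <- matrix(0, 16, 16)
  expect_s4_class(ChannelStack(z, z, z), "ChannelStack")
  expect_error(ChannelStack(z, z, matrix(0, 16, 15)),
               "identical height and width")
  bad <- z; bad[1] <- -1
  expect_error(ChannelStack(z, bad, z), "negative")
  expect_error(ChannelStack(z, z, z, pixelSize = 0), "positive")
})

test_that("multi-page TIFF loads with a caller-declared channel map", {
  sc <- quickScene(seed = 3, width = 96, height = 96, n_globules = 4,
                   n_cells = 1, blur_sigma = 0, noise = "none")
  stack <- renderChannels(sc)
  f <- tempfile(fileext = ".tif")
  writeChannelStack(stack, f)
  # permuted map follows the declaration, not page order
  back <- loadChannelStack(f, list(rna = 2, dna = 3, dic = 1))
  expect_identical(dim(back), dim(stack))
  expect_equal(dicChannel(back), unname(dicChannel(stack)))
  expect_error(loadChannelStack(f, list(dic = 1, rna = 2)), "exactly")
  expect_error(loadChannelStack(f, list(dic = 1, rna = 2, dna = 9)),
               "3 plane")
  expect_error(loadChannelStack(tempfile(), list(dic = 1, rna = 2, dna = 3)),
               "not found")
})

test_that("per-channel files validate shapes and name the offending channel", {
  dir <- tempfile(); dir.create(dir)
  w <- function(m, name) {
    p <- file.path(dir, name)
    tiff::writeTIFF(m / 255, p, bits.per.sample = 8L)
    p
  }
  a <- w(matrix(7, 128, 128), "a.tif")
  b <- w(matrix(9, 128, 128), "b.tif")
  c_ <- w(matrix(11, 128, 127), "c.tif")
  expect_error(
    loadChannelStack(NA, list(dic = a, rna = b, dna = c_)),
    "dna")
  good <- w(matrix(11, 128, 128), "d.tif")
  stack <- loadChannelStack(NA, list(dic = a, rna = b, dna = good))
  expect_identical(dim(stack), c(128L, 128L))
  expect_identical(stack@bitDepth, 8L)
})

test_that("write/read round-trip is bit-exact for integer planes", {
  set.seed(11)
  mk <- function() matrix(sample(0:65535, 64 * 48, TRUE) + 0, 48, 64)
  stack <- ChannelStack(mk(), mk(), mk(), imageId = "rt")
  f <- tempfile(fileext = ".tif")
  writeChannelStack(stack, f)
  back <- loadChannelStack(f, list(dic = 1, rna = 2, dna = 3))
  expect_identical(rnaChannel(back), unname(rnaChannel(stack)))
  expect_identical(dnaChannel(back), unname(dnaChannel(stack)))

  # rendered noise-free scenes are integer-valued and round-trip too
  sc <- quickScene(seed = 5, width = 128, height = 128, n_globules = 8,
                   n_cells = 2, blur_sigma = 0, noise = "none")
  st <- renderChannels(sc)
  writeChannelStack(st, f)
  back <- loadChannelStack(f, list(dic = 1, rna = 2, dna = 3))
  expect_equal(rnaChannel(back), unname(rnaChannel(st)))
})

test_that("tiling handles the single-tile and documented 4-tile cases", {
  z <- matrix(0, 100, 100)
  st <- ChannelStack(z, z, z)
  one <- tileIterator(st, 100, 10)
  expect_length(one, 1)
  expect_identical(coreBounds(one[[1]]), c(0L, 100L, 0L, 100L))

  four <- tileIterator(st, 60, 10)
  expect_length(four, 4)
  areas <- vapply(four, function(t) {
    cb <- coreBounds(t)
    (cb[2] - cb[1]) * (cb[4] - cb[3])
  }, numeric(1))
  expect_identical(sum(areas), 10000)
  # every tile fits within tile_size
  for (t in four) expect_true(all(dim(t@stack@dic) <= 60))
  expect_error(tileIterator(st, 20, 10), "exceed")
})

test_that("degenerate 1-pixel-high strip tiles cover every pixel once", {
  z <- matrix(0, 1, 157)
  tiles <- tileIterator(ChannelStack(z, z, z), 60, 10)
  cov <- integer(157)
  for (t in tiles) {
    cb <- coreBounds(t)
    expect_identical(cb[3:4], c(0L, 1L))
    cov[(cb[1] + 1):cb[2]] <- cov[(cb[1] + 1):cb[2]] + 1L
  }
  expect_true(all(cov == 1L))
})

test_that("tile cores partition arbitrary image sizes exactly", {
  set.seed(42)
  for (rep in 1:25) {
    h <- sample(5:400, 1); w <- sample(5:400, 1)
    overlap <- sample(0:12, 1)
    tile <- overlap * 2 + sample(10:120, 1)
    z <- matrix(0, h, w)
    tiles <- tileIterator(ChannelStack(z, z, z), tile, overlap)
    cov <- matrix(0L, h, w)
    for (t in tiles) {
      cb <- coreBounds(t)
      cov[(cb[3] + 1):cb[4], (cb[1] + 1):cb[2]] <-
        cov[(cb[3] + 1):cb[4], (cb[1] + 1):cb[2]] + 1L
      d <- dim(t@stack@dic)
      expect_true(all(d <= c(tile, tile)))
      # core lies within the tile extent
      expect_true(cb[1] >= t@originX && cb[2] <= t@originX + d[2])
      expect_true(cb[3] >= t@originY && cb[4] <= t@originY + d[1])
    }
    expect_true(all(cov == 1L))
  }
})

test_that("object table reports both px^2 and um^2 areas", {
  res <- new("SceneResult", imageId = "img",
             globules = data.frame(globule_id = 1L, x = 12.5, y = 40.0,
                                   area_px2 = 314, equiv_radius = 10,
                                   circularity = 1),
             crescents = data.frame(crescent_id = integer(0), x = numeric(0),
                                    y = numeric(0), area_px2 = numeric(0),
                                    integrated_intensity = numeric(0),
                                    dna_overlap_fraction = numeric(0),
                                    linked_globule_id = integer(0),
                                    link_distance = numeric(0),
                                    orphan = logical(0)),
             cells = data.frame(), labels = list(), params = list(),
             summary = NULL)
  tab <- objectTable(res, pixel_size = 0.5)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$area_um2, 78.5)
  expect_equal(tab$x, 12.5)
})

test_that("object table CSV round-trips, and empty input gives header only", {
  f <- tempfile(fileext = ".csv")
  writeObjectTable(.emptyTableFixture(), f)
  lines <- readLines(f)
  expect_length(lines, 1)
  expect_match(lines, "image_id.*object_id.*kind.*area_um2.*flags")

  sc <- quickScene(seed = 8, width = 160, height = 160, n_globules = 10,
                   n_cells = 2)
  res <- analyzeStack(renderChannels(sc), synthSegParams())
  tab <- objectTable(res, pixel_size = 0.5)
  writeObjectTable(tab, f)
  back <- readObjectTable(f)
  expect_identical(nrow(back), nrow(tab))
  expect_equal(back$x, tab$x)
  expect_equal(back$area_um2, tab$area_um2)
  expect_identical(back$kind, tab$kind)
})
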