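test_that("relative scale is the geometric-mean side fraction", {
  expect_equal(relativeScale(512, 360, c(360, 512)), 1)
  expect_equal(relativeScale(30, 30, c(360, 512)), sqrt(900 / 184320))
  ## homogeneity: scaling a box by a scales its relative scale by exactly a
  r1 <- relativeScale(20, 14, c(360, 512))
  expect_equal(relativeScale(20 * 0.37, 14 * 0.37, c(360, 512)), 0.37 * r1)
  expect_error(relativeScale(0, 5, c(100, 100)), "degenerate")
})

test_that("dataset scale statistics average relative scales", {
  a1 <- boxAnnotationSet(data.frame(class = 0L, cx = .5, cy = .5,
                                    w = 0.05, h = 0.05), c(100L, 100L))
  s1 <- datasetScaleStats(list(a1))
  expect_equal(s1@s, 0.05)
  expect_equal(s1@nObjects, 1L)
  a2 <- boxAnnotationSet(data.frame(class = 0L, cx = c(.3, .6), cy = c(.3, .6),
                                    w = c(0.04, 0.08), h = c(0.04, 0.08)),
                         c(100L, 100L))
  expect_equal(datasetScaleStats(list(a2))@s, 0.06)
  expect_equal(sum(datasetScaleStats(list(a1, a2))@histogram), 3)
  expect_error(datasetScaleStats(list()), "no annotated")
})

test_that("sampled corpora recover their configured mean scale", {
  set.seed(51)
  anns <- lapply(1:3, function(i)
    generateScene(sceneConfig(imageSize = c(128, 128), countRange = c(60, 80),
                              meanScale = 0.05), seed = 50 + i)$annotations)
  st <- datasetScaleStats(anns)
  se <- stats::sd(teadetect:::.collectScales(anns)) / sqrt(st@nObjects)
  expect_lt(abs(st@s - 0.05), 3 * se + 0.005)
})

test_that("rescaling an object is the identity at factor 1", {
  set.seed(52)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  out <- rescaleObject(img, c(20, 20, 12, 12), 1)
  expect_identical(out$image, img)
  expect_identical(out$boxPx, c(20, 20, 12, 12))
})

test_that("downscaling fills every vacated pixel from surrounding context", {
  ## constant context 0.2, saturated object patch 1.0: after halving, the
  ## pasted patch keeps its value and the entire vacated ring is filled
  ## with the context value -- all 1200 ring pixels accounted for
  img <- array(0.2, c(60, 60, 1))
  img[11:50, 11:50, 1] <- 1
  out <- rescaleObject(img, c(30, 30, 40, 40), 0.5)
  expect_equal(out$boxPx, c(30, 30, 20, 20))
  inner <- out$image[21:40, 21:40, 1]
  expect_true(all(inner == 1))
  ring <- out$image
  ring[21:40, 21:40, 1] <- NA
  expect_true(all(ring[!is.na(ring)] == 0.2))
  expect_equal(sum(out$image == 1), 400)   # exactly the pasted patch
  expect_false(any(is.na(out$image[, , 1]) & TRUE))
})

test_that("upscaling at a corner clips to image bounds", {
  img <- array(runif(50 * 50), c(50, 50, 1))
  out <- rescaleObject(img, c(5, 5, 10, 10), 2)
  b <- out$boxPx
  expect_true(b[1] - b[3] / 2 >= 0 && b[2] - b[4] / 2 >= 0)
  expect_lte(b[3] * b[4], 50 * 50)
  expect_true(all(is.finite(out$image)))
})

test_that("degenerate shrink factors clamp with a warning", {
  img <- array(runif(30 * 30), c(30, 30, 1))
  expect_warning(out <- rescaleObject(img, c(15, 15, 4, 4), 0.05), "clamp")
  expect_gte(out$boxPx[3], 0.5)
})

test_that("matching a dataset moves its mean scale to the target", {
  set.seed(54)
  samples <- lapply(1:3, function(i) {
    g <- generateScene(sceneConfig(imageSize = c(192, 192), countRange = c(30, 45),
                                   meanScale = 0.08), seed = 540 + i)
    list(image = g$triplet@rgb, boxes = annBoxes(g$annotations))
  })
  before <- datasetScaleStats(samples)
  res <- matchDataset(samples, targetS = 0.04)
  after <- datasetScaleStats(res$samples)
  expect_equal(res$factor, 0.04 / before@s)
  expect_lt(abs(after@s - 0.04) / 0.04, 0.10)
  ## conservation of objects and classes
  expect_equal(sum(vapply(res$samples, function(s) nrow(s$boxes), integer(1))),
               sum(vapply(samples, function(s) nrow(s$boxes), integer(1))))
  expect_equal(unlist(lapply(res$samples, function(s) s$boxes$class)),
               unlist(lapply(samples, function(s) s$boxes$class)))
  ## a dataset already below target is untouched
  small <- matchDataset(res$samples, targetS = 1)
  expect_equal(small$nAdjusted, 0L)
  expect_identical(small$samples[[1]]$image, res$samples[[1]]$image)
  ## second pass with the same target is near-identity: its factor is ~1
  ## and the mean scale stays on target
  again <- matchDataset(res$samples, targetS = 0.04)
  expect_equal(again$factor, 1, tolerance = 0.1)
  expect_lt(abs(datasetScaleStats(again$samples)@s - 0.04) / 0.04, 0.10)
  expect_error(matchDataset(list(), 0.05), "empty")
})

test_that("box centers are fixed points of rescaling away from boundaries", {
  set.seed(55)
  img <- array(runif(80 * 80 * 3), c(80, 80, 3))
  for (f in c(0.4, 0.7, 1.6)) {
    out <- rescaleObject(img, c(40, 37, 16, 12), f)
    expect_equal(out$boxPx[1:2], c(40, 37))
    expect_equal(out$boxPx[3:4], f * c(16, 12), tolerance = 0.15)
  }
})
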