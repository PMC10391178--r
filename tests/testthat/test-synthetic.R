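test_that("scene generation is bit-reproducible for a fixed seed", {
  cfg <- tinySceneConfig()
  a <- generateScene(cfg, seed = 61)
  b <- generateScene(cfg, seed = 61)
  expect_identical(a$triplet@rgb, b$triplet@rgb)
  expect_identical(a$triplet@ir, b$triplet@ir)
  expect_identical(a$triplet@depth, b$triplet@depth)
  expect_identical(annBoxes(a$annotations), annBoxes(b$annotations))
  c <- generateScene(cfg, seed = 62)
  expect_false(identical(a$triplet@rgb, c$triplet@rgb))
  ## the generator restores the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generateScene(cfg, seed = 61)); after <- runif(3)
  expect_identical(before, after)
})

test_that("default scenes realize the configured density and scale structure", {
  counts <- integer(0); fracs <- numeric(0)
  for (s in 1:20) {
    ann <- generateScene(sceneConfig(), seed = 600 + s)$annotations
    b <- annBoxes(ann)
    counts <- c(counts, nrow(b))
    fracs <- c(fracs, mean(relativeScale(b$w, b$h) < 0.05))
  }
  expect_true(all(counts >= 200 & counts <= 400))
  expect_gte(mean(fracs), 0.85)
})

test_that("every emitted label is inside bounds and survives the 2 px filter", {
  for (s in 1:3) {
    sc <- generateScene(tinySceneConfig(), seed = 630 + s)
    ann <- sc$annotations
    b <- annBoxes(ann)
    expect_true(all(b$cx - b$w / 2 >= -1e-9 & b$cx + b$w / 2 <= 1 + 1e-9))
    expect_true(all(b$cy - b$h / 2 >= -1e-9 & b$cy + b$h / 2 <= 1 + 1e-9))
    expect_equal(nrow(annBoxes(filterAnnotations(ann, 2))), nrow(b))
  }
})

test_that("zero color contrast hides objects in RGB but not in depth/IR or labels", {
  cfg <- tinySceneConfig(colorContrast = 0)
  base <- tinySceneConfig(colorContrast = 0.3)
  sc0 <- generateScene(cfg, seed = 64)
  sc1 <- generateScene(base, seed = 64)
  ## same geometry (same seed), but the invisible scene's RGB is pure background
  expect_identical(annBoxes(sc0$annotations), annBoxes(sc1$annotations))
  expect_lt(max(abs(sc0$triplet@rgb - sc1$triplet@rgb)) , 1)   # they differ...
  ## objects still imprint the depth map: inside each box the nearest
  ## (smallest nonzero) depth undercuts the local surroundings for most
  ## boxes, despite the global depth gradient
  d <- sc0$triplet@depth
  b <- annBoxes(sc0$annotations)
  hw <- annImageSize(sc0$annotations)
  nearer <- vapply(seq_len(min(nrow(b), 30)), function(i) {
    rows <- max(1, floor((b$cy[i] - b$h[i] / 2) * hw[1])):min(hw[1], ceiling((b$cy[i] + b$h[i] / 2) * hw[1]))
    cols <- max(1, floor((b$cx[i] - b$w[i] / 2) * hw[2])):min(hw[2], ceiling((b$cx[i] + b$w[i] / 2) * hw[2]))
    srows <- max(1, min(rows) - 8):min(hw[1], max(rows) + 8)
    scols <- max(1, min(cols) - 8):min(hw[2], max(cols) + 8)
    inObj <- d[rows, cols]; around <- d[srows, scols]
    min(inObj[inObj > 0]) < stats::median(around[around > 0])
  }, logical(1))
  expect_gt(mean(nearer), 0.8)
})

test_that("modalities are pixel-aligned by construction", {
  ## with contrast only in IR and no speckle/voids, the IR object footprint
  ## must coincide with the RGB chromatic footprint
  cfg <- sceneConfig(imageSize = c(96, 128), countRange = c(8, 10),
                     colorContrast = 0.5, irContrast = 0.5,
                     irSpeckle = 1e-4, depthVoidRate = 0)
  sc <- generateScene(cfg, seed = 65)
  cfg0 <- sceneConfig(imageSize = c(96, 128), countRange = c(8, 10),
                      colorContrast = 0, irContrast = 0,
                      irSpeckle = 1e-4, depthVoidRate = 0)
  sc0 <- generateScene(cfg0, seed = 65)
  rgbFoot <- apply(abs(sc$triplet@rgb - sc0$triplet@rgb), c(1, 2), max) > 0.05
  irFoot <- abs(sc$triplet@ir - sc0$triplet@ir) > 0.05
  ## footprints overlap almost perfectly
  expect_gt(sum(rgbFoot & irFoot) / sum(rgbFoot | irFoot), 0.8)
})

test_that("corpora round-trip through disk and recover sub-corpus scales", {
  td <- withr::local_tempdir()
  cfg <- tinySceneConfig()
  man <- generateCorpus(cfg, n = 2, dir = td, seed = 66)
  expect_equal(nrow(man), 2L)
  samples <- loadCorpus(td)
  expect_equal(length(samples), 2L)
  ## reloaded labels identical to the written ones
  sc <- generateScene(cfg, seed = 66 * 10000L + 1L)
  expect_lt(max(abs(as.matrix(samples[[1]]$boxes) -
                      as.matrix(annBoxes(sc$annotations)))), 1e-5)
  ## paired corpora with different mean scales
  td2 <- withr::local_tempdir()
  generatePairedCorpora(sceneConfig(imageSize = c(128, 128), countRange = c(40, 60)),
                        n = 3, dir = td2,
                        meanScales = c(fine = 0.04, coarse = 0.08), seed = 67)
  fine <- loadCorpus(file.path(td2, "fine"))
  coarse <- loadCorpus(file.path(td2, "coarse"))
  sFine <- datasetScaleStats(fine)@s
  sCoarse <- datasetScaleStats(coarse)@s
  expect_lt(abs(sFine - 0.04) / 0.04, 0.10)
  expect_lt(abs(sCoarse - 0.08) / 0.08, 0.10)
  ## fused modality loading works and respects channel contracts
  fused <- loadCorpus(td, modality = "rgba")
  expect_equal(dim(fused[[1]]$image)[3], 4L)
  expect_error(generateCorpus(cfg, n = 0, dir = td), "n must be")
})
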