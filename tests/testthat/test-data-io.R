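test_that("triplet write/load round-trips with declared bit depths", {
  sc <- generateScene(tinySceneConfig(), seed = 41)
  td <- withr::local_tempdir()
  p <- writeTriplet(sc$triplet, td)
  tr <- loadTriplet(p["rgb"], p["ir"], p["depth"])
  expect_equal(tr@bitDepths, c(rgb = 8L, ir = 16L, depth = 8L))
  ## 16-bit infrared is lossless at its stored quantization
  expect_equal(tr@ir, round(sc$triplet@ir * 65535) / 65535, tolerance = 1e-12)
  expect_equal(tr@rgb, round(sc$triplet@rgb * 255) / 255, tolerance = 1e-12)
})

test_that("misaligned or under-resolved modalities are rejected by name", {
  sc <- generateScene(tinySceneConfig(), seed = 42)
  td <- withr::local_tempdir()
  p <- writeTriplet(sc$triplet, td)
  ## wrong-size infrared
  bad <- file.path(td, "bad_ir.tif")
  tiff::writeTIFF(matrix(0.5, 10, 10), bad, bits.per.sample = 16)
  expect_error(loadTriplet(p["rgb"], bad, p["depth"]), "'ir'")
  ## 8-bit file in the infrared slot: rejected under strict, promoted otherwise
  eight <- file.path(td, "ir8.png")
  png::writePNG(matrix(0.5, 96, 128), eight)
  expect_error(loadTriplet(p["rgb"], eight, p["depth"]), "16-bit")
  tr <- loadTriplet(p["rgb"], eight, p["depth"], strict = FALSE)
  expect_equal(tr@bitDepths[["ir"]], 16L)
  expect_lt(max(abs(tr@ir - 0.5)), 1 / 255)   # 8-bit quantization of 0.5
})

test_that("field-of-view cropping removes rows evenly and re-projects labels exactly", {
  set.seed(43)
  H <- 424L; W <- 512L
  rgb <- array(runif(H * W * 3), c(H, W, 3))
  tr <- new("ModalityTriplet", rgb = rgb, ir = matrix(runif(H * W), H, W),
            depth = matrix(runif(H * W), H, W),
            bitDepths = c(rgb = 8L, ir = 16L, depth = 8L),
            frameId = "f", aligned = TRUE)
  boxes <- data.frame(class = 0L,
                      cx = c(0.5, 0.5, 0.5, 0.3),
                      cy = c(0.5, 0.02, 0.076, 0.9),
                      w = c(0.06, 0.04, 0.05, 0.04),
                      h = c(0.06, 0.03, 0.05, 0.04))
  ann <- boxAnnotationSet(boxes, c(H, W))
  out <- cropFov(tr, ann, targetH = 360L)
  expect_equal(dim(out$triplet@rgb), c(360, 512, 3))
  ## rows removed evenly: 32 from the top (even remainder)
  expect_equal(out$triplet@rgb[1, , ], rgb[33, , ])
  b <- annBoxes(out$annotations)
  ## the fully-out-of-view box (cy=0.02 -> rows 4..16) is dropped
  expect_equal(nrow(b), 3L)
  ## surviving uncut boxes keep their pixel center up to the crop offset
  expect_equal(b$cy[1] * 360, 0.5 * 424 - 32)
  expect_equal(b$cx[1], 0.5)
  ## the straddling box (center row 32.2) is clipped to positive area
  expect_true(all(b$w > 0 & b$h > 0))
  ## identity crop
  idn <- cropFov(tr, ann, targetH = H)
  expect_identical(idn$triplet@rgb, rgb)
  expect_equal(annBoxes(idn$annotations), boxes)
  expect_error(cropFov(tr, ann, targetH = 500L), "exceeds")
})

test_that("the small-box filter keeps only boxes strictly above the pixel threshold", {
  ann <- boxAnnotationSet(data.frame(class = 0L,
                                     cx = c(0.5, 0.5, 0.5), cy = c(0.5, 0.5, 0.5),
                                     w = c(2, 3, 10) / 100, h = c(2, 3, 10) / 100),
                          c(100L, 100L))
  out <- filterAnnotations(ann, minSidePx = 2)
  expect_equal(nrow(annBoxes(out)), 2L)            # 2x2 removed, 3x3 kept
  expect_equal(annBoxes(out)$w, c(0.03, 0.10))
  empty <- boxAnnotationSet(annBoxes(ann)[0, ], c(100L, 100L))
  expect_equal(nrow(annBoxes(filterAnnotations(empty))), 0L)
})

test_that("COCO and YOLO label formats convert exactly and round-trip", {
  td <- withr::local_tempdir()
  ## known conversion: COCO top-left (10, 20, 30, 30) in 512 x 360
  ann <- boxAnnotationSet(data.frame(class = 0L,
                                     cx = (10 + 15) / 512, cy = (20 + 15) / 360,
                                     w = 30 / 512, h = 30 / 360),
                          c(360L, 512L), "img1")
  yp <- file.path(td, "a.txt")
  writeLabels(ann, yp, "yolo_txt")
  v <- as.numeric(strsplit(readLines(yp), " ")[[1]])
  expect_equal(v[2:5], c(0.048828, 0.097222, 0.058594, 0.083333), tolerance = 1e-6)
  back <- readLabels(yp, "yolo_txt", imageSize = c(360, 512))
  expect_lt(max(abs(as.matrix(annBoxes(back)) - as.matrix(annBoxes(ann)))), 1e-6)
  cp <- file.path(td, "a.json")
  writeLabels(ann, cp, "coco_json")
  backC <- readLabels(cp, "coco_json")
  expect_equal(as.matrix(annBoxes(backC)), as.matrix(annBoxes(ann)), tolerance = 1e-9)
  expect_equal(annImageSize(backC), c(360L, 512L))
  ## malformed records carry diagnostics
  writeLines(c("0 0.5 0.5 0.1 0.1", "0 0.5 0.5"), file.path(td, "bad.txt"))
  expect_error(readLabels(file.path(td, "bad.txt"), "yolo_txt", imageSize = c(100, 100)),
               "line 2")
  writeLines("0 0.5 0.5 -0.1 0.1", file.path(td, "neg.txt"))
  expect_error(readLabels(file.path(td, "neg.txt"), "yolo_txt", imageSize = c(100, 100)),
               "nonpositive")
  badAnn <- ann; badAnn@boxes$w <- -1
  expect_error(writeLabels(badAnn, file.path(td, "x.txt"), "yolo_txt"), "annotation 1")
})

test_that("label sharing: one annotation set evaluates identically for every modality", {
  sc <- generateScene(tinySceneConfig(), seed = 44)
  ann <- sc$annotations
  hw <- annImageSize(ann)
  truths <- teadetect:::.boxesToXYXY(annBoxes(ann), hw)
  ## perfect detections derived from the shared labels match identically no
  ## matter which modality the image came from
  det <- data.frame(x1 = truths[, 1], y1 = truths[, 2], x2 = truths[, 3],
                    y2 = truths[, 4], score = 0.9)
  for (modality in c("rgb", "ir", "depth")) {
    m <- matchDetections(det, as.data.frame(truths), 0.5)
    expect_equal(m$tp, nrow(truths))
    expect_equal(m$fp + m$fn, 0L)
  }
})
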