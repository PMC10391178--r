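.mkBoxes <- function(n, size = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cx <- runif(n, 10, size - 10); cy <- runif(n, 10, size - 10)
  w <- runif(n, 4, 15); h <- runif(n, 4, 15)
  data.frame(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2)
}

test_that("perfect detections match all truths; corrupted sets count as stated", {
  tr <- .mkBoxes(10, seed = 71)
  det <- cbind(tr, score = seq(0.95, 0.5, length.out = 10))
  m <- matchDetections(det, tr, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(10L, 0L, 0L))
  ## 8 matched + 2 spurious detections over 10 truths
  det2 <- rbind(cbind(tr[1:8, ], score = 0.9),
                cbind(.mkBoxes(2, seed = 72) + 40, score = 0.8))
  m2 <- matchDetections(det2, tr, 0.5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(8L, 2L, 2L))
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$recall, 0.8)
})

test_that("greedy matching attains the exhaustive optimum on small instances", {
  set.seed(73)
  for (rep_ in 1:25) {
    ## well-separated truths (as in real scenes), jittered detections + noise
    nT <- sample(1:8, 1); nD <- sample(1:8, 1)
    cx <- (seq_len(nT) %% 3) * 30 + 15 + runif(nT, -3, 3)
    cy <- (seq_len(nT) %/% 3) * 30 + 15 + runif(nT, -3, 3)
    w <- runif(nT, 8, 14); h <- runif(nT, 8, 14)
    tr <- data.frame(x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2)
    pick <- sample(nT, nD, replace = TRUE)
    det <- tr[pick, ] + matrix(runif(nD * 4, -3, 3), nD, 4)
    det <- data.frame(x1 = pmin(det$x1, det$x2), y1 = pmin(det$y1, det$y2),
                      x2 = pmax(det$x1, det$x2) + 1, y2 = pmax(det$y1, det$y2) + 1)
    det$score <- runif(nD)
    m <- matchDetections(det, tr, 0.3)
    opt <- bruteForceMaxMatches(det[, 1:4], tr, 0.3)
    expect_equal(m$tp, opt)
  }
})

test_that("average precision integrates the interpolated precision envelope", {
  expect_equal(averagePrecision(1, 1), 1)                      # single perfect detection
  expect_equal(averagePrecision(c(1.0, 0.5), c(0.5, 1.0)), 0.75)
  ## order of samples does not matter
  expect_equal(averagePrecision(c(0.5, 1.0), c(1.0, 0.5)), 0.75)
  ## monotone envelope: a dominated sample changes nothing
  expect_equal(averagePrecision(c(1.0, 0.4, 0.5), c(0.5, 0.7, 1.0)), 0.75)
})

test_that("the package evaluator agrees with an independent COCO-style evaluator", {
  set.seed(74)
  for (rep_ in 1:4) {
    nImg <- 4
    truths <- lapply(1:nImg, function(i) as.matrix(.mkBoxes(sample(5:15, 1))))
    dets <- lapply(truths, function(tr) {
      n <- nrow(tr)
      hit <- tr[sample(n, round(0.7 * n)), , drop = FALSE] +
        matrix(runif(4 * round(0.7 * n), -2, 2), ncol = 4)
      fp <- as.matrix(.mkBoxes(sample(2:5, 1))) + 30
      d <- as.data.frame(rbind(hit, fp))
      names(d) <- c("x1", "y1", "x2", "y2")
      d$score <- runif(nrow(d))
      d
    })
    ours <- teadetect:::.apAtIoU(dets, truths, 0.5)$ap
    ref <- cocoStyleAP(dets, lapply(truths, as.data.frame), 0.5)
    expect_lt(abs(ours - ref), 0.01)
  }
})

test_that("metric computation is invariant to detection input order", {
  set.seed(75)
  tr <- .mkBoxes(8)
  det <- cbind(.mkBoxes(12), score = runif(12))
  m1 <- matchDetections(det, tr, 0.4)
  perm <- sample(12)
  m2 <- matchDetections(det[perm, ], tr, 0.4)
  expect_equal(c(m1$tp, m1$fp, m1$fn), c(m2$tp, m2$fp, m2$fn))
})

test_that("decoded detections land where the raw predictions point", {
  set.seed(76)
  cfg <- modelPreset("improved", imgSize = 64)
  ## craft raw maps with one confident prediction at P3 cell (3, 5), anchor 2
  no <- 6L
  preds <- list(array(-12, c(8, 8, 18)), array(-12, c(4, 4, 18)),
                array(-12, c(2, 2, 18)))
  z <- c(0, 0, 0, 0, 6, 0)   # centered offsets, anchor-sized box, high conf
  preds[[1]][3, 5, no + 1:6] <- z
  d <- decodeDetections(preds, cfg, confThr = 0.25)
  expect_equal(nrow(d), 1L)
  ## center at (gi + 0.5) * stride with the sigmoid decode at logit 0
  expect_equal((d$x1 + d$x2) / 2, (5 - 1 + 0.5) * 8)
  expect_equal((d$y1 + d$y2) / 2, (3 - 1 + 0.5) * 8)
  expect_equal(d$x2 - d$x1, cfg@anchors[2, 1, 1])
  expect_equal(d$y2 - d$y1, cfg@anchors[2, 2, 1])
  expect_equal(d$score, stats::plogis(6))
})
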