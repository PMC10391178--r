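test_that("spectral transform satisfies DC, round-trip and Parseval identities", {
  set.seed(21)
  ## constant map -> single DC coefficient c*M*N
  x <- array(0.7, c(6, 10, 2))
  s <- spectralTransform(x, "forward")
  expect_equal(Mod(s[1, 1, 1]), 0.7 * 60)
  expect_lt(max(Mod(s)[-c(1, 61)]), 1e-10)
  ## round trip on random maps
  for (r in 1:3) {
    x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
    err <- max(abs(spectralTransform(spectralTransform(x, "forward"), "inverse") - x))
    expect_lt(err, 1e-5)
  }
  ## Parseval: sum |x|^2 = (1/MN) sum |X|^2, against brute-force sums
  x <- array(rnorm(12 * 8 * 3), c(12, 8, 3))
  s <- spectralTransform(x, "forward")
  expect_equal(sum(x^2), sum(Mod(s)^2) / (12 * 8), tolerance = 1e-10)
  expect_error(spectralTransform(array(NaN, c(4, 4, 1)), "forward"), "finite")
})

test_that("round-trip error stays below 1e-5 up to 64x64 maps", {
  set.seed(22)
  for (side in c(16, 32, 64)) {
    x <- array(rnorm(side * side * 2), c(side, side, 2))
    err <- max(abs(spectralTransform(spectralTransform(x, "forward"), "inverse") - x))
    expect_lt(err, 1e-5)
  }
})

test_that("channel refinement yields sigmoid-range weights and preserves phase", {
  set.seed(23)
  ffa <- ffaBlock(8)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8)); y <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  sR <- spectralTransform(x, "forward"); sD <- spectralTransform(y, "forward")
  cr <- channelRefine(sR, sD, ffa)
  expect_true(all(cr$wRgb > 0 & cr$wRgb < 1))
  expect_true(all(cr$wDir > 0 & cr$wDir < 1))
  ## real positive weights leave the phase untouched
  expect_equal(Arg(cr$sRgb), Arg(sR), tolerance = 1e-12)
  ## zeroed perceptron -> every weight exactly 1/2, spectrum halved entrywise
  ffa$mlp1_W1[] <- 0; ffa$mlp1_W2[] <- 0
  cr2 <- channelRefine(sR, sD, ffa)
  expect_equal(cr2$wRgb, rep(0.5, 8))
  expect_equal(cr2$sRgb, 0.5 * sR)
  expect_equal(cr2$sDir, 0.5 * sD)
  expect_error(channelRefine(sR, spectralTransform(array(0, c(8, 8, 4)), "forward"), ffa))
})

test_that("frequency refinement yields per-frequency sigmoid weights and preserves phase", {
  set.seed(24)
  ffa <- ffaBlock(4)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4)); y <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  sR <- spectralTransform(x, "forward"); sD <- spectralTransform(y, "forward")
  fr <- frequencyRefine(sR, sD, ffa)
  expect_equal(dim(fr$wRgb), c(6, 6))
  expect_true(all(fr$wRgb > 0 & fr$wRgb < 1))
  expect_equal(Arg(fr$sRgb), Arg(sR), tolerance = 1e-12)
  ## zeroed second convolution -> uniform 1/2 maps, spectrum halved
  ffa$mlp2_W2[] <- 0
  fr2 <- frequencyRefine(sR, sD, ffa)
  expect_equal(fr2$wRgb, matrix(0.5, 6, 6))
  expect_equal(fr2$sRgb, 0.5 * sR)
})

test_that("the full module is shape-preserving and reduces to cross-addition", {
  set.seed(25)
  ffa <- ffaBlock(4)
  x <- array(rnorm(8 * 12 * 4), c(8, 12, 4)); y <- array(rnorm(8 * 12 * 4), c(8, 12, 4))
  out <- ffaForward(ffa, x, y)
  expect_equal(dim(out$fRgb), dim(x))
  expect_equal(dim(out$fDir), dim(y))
  expect_true(all(is.finite(out$fRgb)) && all(is.finite(out$fDir)))
  ## unit attention + identity re-enhancement -> exact symmetric cross-add
  ffaSetIdentityEnhance(ffa)
  red <- ffaForward(ffa, x, y, pinWeights = TRUE)
  expect_equal(red$fRgb, x + y, tolerance = 1e-12)
  expect_equal(red$fDir, y + x, tolerance = 1e-12)
  ## zero input with (default) zero biases -> zero output
  z <- array(0, c(4, 4, 4))
  ffa2 <- ffaBlock(4)
  zz <- ffaForward(ffa2, z, z)
  expect_equal(max(abs(zz$fRgb)), 0)
  expect_error(ffaForward(ffa2, x, array(0, c(8, 12, 2))), "differ")
})

test_that("a scalar objective has nonzero gradient to every learnable entry", {
  set.seed(26)
  C <- 2
  ffa <- ffaBlock(C)
  x <- array(rnorm(4 * 4 * C), c(4, 4, C)); y <- array(rnorm(4 * 4 * C), c(4, 4, C))
  ## keep the single hidden ReLU unit of each perceptron active so the
  ## connectivity check is not confounded by a dead rectifier
  ffa$mlp1_b1[] <- 0.5; ffa$mlp2_b1[] <- 0.5
  lossOf <- function() {
    o <- ffaForward(ffa, x, y)
    sum(o$fRgb^2) + sum(o$fDir^2)
  }
  eps <- 1e-5
  paramRefs <- list(
    c("mlp1_W1"), c("mlp1_b1"), c("mlp1_W2"), c("mlp1_b2"),
    c("mlp2_W1"), c("mlp2_b1"), c("mlp2_W2"), c("mlp2_b2"))
  for (nm in paramRefs) {
    p <- ffa[[nm]]
    grads <- vapply(seq_along(p), function(i) {
      old <- p[i]
      ffa[[nm]][i] <- old + eps; lp <- lossOf()
      ffa[[nm]][i] <- old - eps; lm <- lossOf()
      ffa[[nm]][i] <- old
      (lp - lm) / (2 * eps)
    }, numeric(1))
    expect_true(any(abs(grads) > 1e-8), info = nm)
  }
  for (s in c("rgb", "dir")) for (w in c("W1", "b1", "W2", "b2")) {
    p <- ffa$enh[[s]][[w]]
    i <- sample(length(p), 1)
    old <- p[i]
    ffa$enh[[s]][[w]][i] <- old + eps; lp <- lossOf()
    ffa$enh[[s]][[w]][i] <- old - eps; lm <- lossOf()
    ffa$enh[[s]][[w]][i] <- old
    expect_gt(abs((lp - lm) / (2 * eps)), 1e-8)
  }
})

test_that("dual-stream fusion obeys symmetry, stride and parameter contracts", {
  set.seed(27)
  cfg <- modelPreset("improved", imgSize = 64)
  mm <- buildMultimodalDetector(cfg, useFFA = FALSE)
  ## tie the two backbones
  wA <- detectorWeights(mm$streamA)
  setDetectorWeights(mm$streamB, wA)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  out <- multimodalForward(mm, x, x)
  ## identical inputs + tied weights: BP_k is twice the single-stream feature
  single <- teadetect:::.runSegment(mm$streamA, vector("list", length(mm$streamA$nodes)),
                                    0L, 10L, list(x))
  for (k in 1:3)
    expect_equal(out$bp[[k]], 2 * single[[mm$stageIds[k]]][[1]], tolerance = 1e-9)
  ## stride contract on the fused pyramid
  expect_equal(vapply(out$bp, function(b) dim(b)[1], numeric(1)), c(8, 4, 2))
  expect_equal(lapply(out$heads, function(h) dim(h[[1]])[1:2]),
               list(c(8, 8), c(4, 4), c(2, 2)))
  ## FFA toggling changes only fusion internals; parameters strictly decrease
  set.seed(27)
  mmF <- buildMultimodalDetector(cfg, useFFA = TRUE)
  expect_gt(multimodalParameters(mmF), multimodalParameters(mm))
  expect_error(multimodalForward(mm, x, array(0, c(32, 32, 3))), "misaligned")
})
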