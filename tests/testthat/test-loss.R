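test_that("complete-IoU value and gradient match a frozen-alpha finite difference", {
  set.seed(81)
  for (rep_ in 1:20) {
    p <- c(runif(2, 0, 10), runif(2, 0.5, 6))
    t <- p + c(runif(2, -2, 2), runif(2, -1, 1) * 0.5)
    t[3:4] <- pmax(t[3:4], 0.3)
    cg <- ciouWithGrad(p, t)
    expect_lte(cg$ciou, 1)
    ## the aspect coefficient is treated as a constant in differentiation;
    ## compare against the finite difference of the alpha-frozen surrogate
    surrogate <- function(pp) {
      full <- ciouWithGrad(pp, t)
      v <- (4 / pi^2) * (atan(t[3] / t[4]) - atan(pp[3] / pp[4]))^2
      full$ciou + full$alpha * v - cg$alpha * v
    }
    num <- vapply(1:4, function(i) {
      e <- 1e-6
      pp <- p; pp[i] <- p[i] + e; up <- surrogate(pp)
      pp[i] <- p[i] - e; dn <- surrogate(pp)
      (up - dn) / (2 * e)
    }, numeric(1))
    expect_equal(cg$grad, num, tolerance = 1e-4)
  }
  ## identical boxes: perfect CIoU
  expect_equal(ciouWithGrad(c(1, 2, 3, 4), c(1, 2, 3, 4))$ciou, 1, tolerance = 1e-6)
})

test_that("loss breakdown is exactly additive and terms are nonnegative", {
  set.seed(82)
  cfg <- modelPreset("improved", imgSize = 64)
  m <- buildDetector(cfg)
  xs <- list(array(runif(64 * 64 * 3), c(64, 64, 3)),
             array(runif(64 * 64 * 3), c(64, 64, 3)))
  tg <- list(data.frame(class = 0L, cx = 0.4, cy = 0.5, w = 0.12, h = 0.1),
             data.frame(class = 0L, cx = c(0.2, 0.7), cy = c(0.3, 0.6),
                        w = c(0.1, 0.14), h = c(0.12, 0.1)))
  pr <- detectorForward(m, xs, training = TRUE)
  ls <- computeLoss(pr, tg, cfg, c(64, 64))
  expect_identical(ls$total, ls$box + ls$confidence + ls$classification)
  expect_true(all(c(ls$box, ls$confidence, ls$classification) >= 0))
  expect_gt(ls$nMatched, 0)
  detectorZeroGrad(m)
})

test_that("zero targets with zero logits give the closed-form all-negative confidence loss", {
  cfg <- modelPreset("improved", imgSize = 64)
  preds <- list(list(array(0, c(8, 8, 18))), list(array(0, c(4, 4, 18))),
                list(array(0, c(2, 2, 18))))
  ls <- computeLoss(preds, list(NULL), cfg, c(64, 64))
  expect_equal(ls$box, 0)
  expect_equal(ls$classification, 0)
  ## each level contributes balance * mean(BCE at logit 0, target 0) = b*log(2)
  expect_equal(ls$confidence, (4.0 + 1.0 + 0.4) * log(2), tolerance = 1e-12)
})

test_that("an injected near-perfect prediction drives the loss to near zero", {
  ## anchors chosen so exactly one anchor passes the wh-ratio gate
  anch <- array(0, c(3, 2, 3))
  anch[1, , 1] <- 8; anch[2, , 1] <- 64; anch[3, , 1] <- 512
  anch[, , 2] <- 512; anch[, , 3] <- 1024   # no match on P4/P5
  cfg <- modelPreset("improved", imgSize = 64, anchors = anch)
  ## one anchor-sized target at grid position (3.3, 3.3) on the P3 level
  tg <- data.frame(class = 0L, cx = 3.3 / 8, cy = 3.3 / 8, w = 8 / 64, h = 8 / 64)
  mkLevel <- function(g) array(-30, c(g, g, 18))
  preds <- list(mkLevel(8), mkLevel(4), mkLevel(2))
  ## invert the decode at the three assigned cells: sigma(z) = (off + 0.5)/2
  zOf <- function(off) log(((off + 0.5) / 2) / (1 - (off + 0.5) / 2))
  put <- function(gi, gj, offx, offy)
    preds[[1]][gj + 1, gi + 1, 1:6] <<- c(zOf(offx), zOf(offy), 0, 0, 30, 0)
  put(3, 3, 0.3, 0.3)   # center cell
  put(2, 3, 1.3, 0.3)   # left neighbour
  put(3, 2, 0.3, 1.3)   # upper neighbour
  ls <- computeLoss(lapply(preds, list), list(tg), cfg, c(64, 64))
  expect_lt(ls$box, 1e-3)
  expect_lt(ls$total, 1e-3)
})

test_that("loss gradients match finite differences through random predictions", {
  set.seed(83)
  cfg <- modelPreset("baseline", imgSize = 64)
  preds <- list(list(array(rnorm(8 * 8 * 18, sd = 0.5), c(8, 8, 18))),
                list(array(rnorm(4 * 4 * 18, sd = 0.5), c(4, 4, 18))),
                list(array(rnorm(2 * 2 * 18, sd = 0.5), c(2, 2, 18))))
  tg <- list(data.frame(class = 0L, cx = c(0.31, 0.72), cy = c(0.44, 0.2),
                        w = c(0.1, 0.2), h = c(0.15, 0.18)))
  ls <- computeLoss(preds, tg, cfg, c(64, 64), withGrad = TRUE)
  f <- function(pp) computeLoss(pp, tg, cfg, c(64, 64))$total
  e <- 1e-5
  idxs <- list(c(1, 3, 4, 5), c(1, 3, 4, 1), c(2, 2, 2, 11), c(3, 1, 2, 15))
  for (ix in idxs) {
    l <- ix[1]
    pp <- preds
    pp[[l]][[1]][ix[2], ix[3], ix[4]] <- preds[[l]][[1]][ix[2], ix[3], ix[4]] + e
    up <- f(pp)
    pp[[l]][[1]][ix[2], ix[3], ix[4]] <- preds[[l]][[1]][ix[2], ix[3], ix[4]] - e
    dn <- f(pp)
    expect_equal(ls$grad[[l]][[1]][ix[2], ix[3], ix[4]], (up - dn) / (2 * e),
                 tolerance = 1e-5, info = paste(ix, collapse = ","))
  }
})
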