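## Training loop: stochastic gradient descent with momentum warm-up, cosine
## learning-rate decay, optional online augmentation, per-iteration loss
## logging, and the scale-matched transfer-learning workflow.

.sgdStep <- function(layers, lr, momentum, weightDecay) {
  for (ly in layers) {
    for (nm in c("W", "b", "g", "be")) {
      gname <- paste0("d_", nm)
      gr <- ly[[gname]]
      if (is.null(gr)) next
      wd <- if (nm == "W") weightDecay else 0
      vname <- paste0("v_", nm)
      v <- ly[[vname]]
      if (is.null(v)) v <- 0
      v <- momentum * v + gr + wd * ly[[nm]]
      ly[[vname]] <- v
      ly[[nm]] <- ly[[nm]] - lr * v
    }
  }
}

#' Learning-rate and momentum schedule
#'
#' Linear warm-up from near zero to \code{lr0} (with momentum ramping from
#' \code{warmupMomentum} to \code{momentum}) over the warm-up iterations,
#' then cosine decay from \code{lr0} to \code{lrf}.
#'
#' @param iter current iteration (1-based).
#' @param totalIters total planned iterations.
#' @param lr0,lrf initial and final learning rates.
#' @param momentum,warmupMomentum terminal and warm-up momenta.
#' @param warmupIters warm-up length in iterations.
#' @return list(lr =, momentum =).
#' @export
trainSchedule <- function(iter, totalIters, lr0 = 1e-2, lrf = 1e-5,
                          momentum = 0.937, warmupMomentum = 0.8,
                          warmupIters = max(3, round(0.1 * totalIters))) {
  if (iter <= warmupIters) {
    f <- iter / warmupIters
    list(lr = lr0 * f, momentum = warmupMomentum + f * (momentum - warmupMomentum))
  } else {
    prog <- (iter - warmupIters) / max(totalIters - warmupIters, 1)
    list(lr = lrf + (lr0 - lrf) * (1 + cos(pi * prog)) / 2, momentum = momentum)
  }
}

.applyAugment <- function(batch, dataset, augment) {
  lapply(batch, function(s) {
    if (isTRUE(augment$mosaic) && stats::runif(1) < augment$mosaicP) {
      others <- dataset[sample.int(length(dataset), 3L, replace = TRUE)]
      s <- augMosaic(c(list(s), others))
    }
    if (isTRUE(augment$hflip) && stats::runif(1) < 0.5) s <- augHFlip(s)
    if (isTRUE(augment$rotate)) s <- augRotate(s, maxDeg = augment$maxDeg)
    if (isTRUE(augment$color)) s <- augColor(s, strength = augment$colorStrength)
    s
  })
}

.augDefaults <- function() list(hflip = FALSE, rotate = FALSE, color = FALSE,
                                mosaic = FALSE, mosaicP = 1.0, maxDeg = 10,
                                colorStrength = 0.2)

#' Train a detector
#'
#' Stochastic gradient descent with momentum over shuffled mini-batches.
#' Defaults follow the reference schedule of this model family: initial
#' learning rate 1e-2 decaying cosine-style to 1e-5, momentum 0.8 during
#' warm-up then 0.937, weight decay 5e-3, batch size 4; horizontal flip,
#' random rotation, color jitter and mosaic composition are available as
#' online augmentations (all off by default here; enable via
#' \code{augment}). The best-loss weights are retained and restored at the
#' end when \code{keepBest} is set.
#'
#' @param model a \code{Detector} (modified in place; also returned).
#' @param dataset list of samples \code{list(image =, boxes =)}; images must
#'   already be at a 32-divisible size (see \code{\link{letterbox}}).
#' @param iterations number of optimizer steps.
#' @param batchSize images per step.
#' @param lr0,lrf,momentum,warmupMomentum,warmupIters,weightDecay schedule
#'   parameters, see \code{\link{trainSchedule}}.
#' @param gains loss gains override (see \code{\link{computeLoss}}).
#' @param augment list of augmentation switches merged over the defaults
#'   (\code{hflip}, \code{rotate}, \code{color}, \code{mosaic}, ...).
#' @param valDataset optional validation set; its box loss is recorded
#'   before the first step and then every \code{valEvery} iterations.
#' @param valEvery validation cadence in iterations.
#' @param keepBest restore the lowest-total-loss weights at the end.
#' @param verbose print a line every 10 iterations.
#' @return the model, with \code{$log} (per-iteration loss breakdown
#'   data.frame) and \code{$valLog} attached.
#' @export
fitDetector <- function(model, dataset, iterations = 100L, batchSize = 4L,
                        lr0 = 1e-2, lrf = 1e-5, momentum = 0.937,
                        warmupMomentum = 0.8,
                        warmupIters = max(3, round(0.1 * iterations)),
                        weightDecay = 5e-3, gains = list(),
                        augment = list(), valDataset = NULL, valEvery = 10L,
                        keepBest = FALSE, verbose = FALSE) {
  if (!length(dataset)) stop("dataset is empty")
  augment <- utils::modifyList(.augDefaults(), augment)
  layers <- detectorLayers(model)
  log <- data.frame()
  valLog <- data.frame()
  if (!is.null(valDataset)) {
    vl <- validationLoss(model, valDataset, batchSize = batchSize, gains = gains)
    valLog <- rbind(valLog, cbind(iter = 0L, as.data.frame(vl[c("total", "box", "confidence", "classification")])))
  }
  order_ <- sample.int(length(dataset))
  cursor <- 0L
  bestLoss <- Inf; bestW <- NULL
  for (it in seq_len(iterations)) {
    idx <- integer(0)
    while (length(idx) < batchSize) {
      if (cursor >= length(order_)) { order_ <- sample.int(length(dataset)); cursor <- 0L }
      take <- min(batchSize - length(idx), length(order_) - cursor)
      idx <- c(idx, order_[cursor + seq_len(take)])
      cursor <- cursor + take
    }
    batch <- .applyAugment(dataset[idx], dataset, augment)
    xs <- lapply(batch, `[[`, "image")
    tg <- lapply(batch, `[[`, "boxes")
    detectorZeroGrad(model)
    preds <- detectorForward(model, xs, training = TRUE)
    hw <- dim(xs[[1]])[1:2]
    ls <- computeLoss(preds, tg, model$config, hw, gains = gains, withGrad = TRUE)
    if (!is.finite(ls$total))
      stop("training diverged at iteration ", it, " (total loss ", ls$total, ")")
    detectorBackward(model, ls$grad)
    sch <- trainSchedule(it, iterations, lr0, lrf, momentum, warmupMomentum, warmupIters)
    .sgdStep(layers, sch$lr, sch$momentum, weightDecay)
    log <- rbind(log, data.frame(iter = it, lr = sch$lr, total = ls$total,
                                 box = ls$box, confidence = ls$confidence,
                                 classification = ls$classification))
    if (keepBest && ls$total < bestLoss) { bestLoss <- ls$total; bestW <- detectorWeights(model) }
    if (!is.null(valDataset) && it %% valEvery == 0L) {
      vl <- validationLoss(model, valDataset, batchSize = batchSize, gains = gains)
      valLog <- rbind(valLog, cbind(iter = it, as.data.frame(vl[c("total", "box", "confidence", "classification")])))
    }
    if (verbose && it %% 10L == 0L)
      message(sprintf("iter %d  lr %.4g  loss %.4f (box %.4f obj %.4f)",
                      it, sch$lr, ls$total, ls$box, ls$confidence))
  }
  if (keepBest && !is.null(bestW)) setDetectorWeights(model, bestW)
  detectorZeroGrad(model)
  model$log <- log
  model$valLog <- valLog
  model
}

#' Loss on a held-out set
#'
#' Computes the loss breakdown over a dataset without updating weights.
#' Batch statistics are used for normalization so the measurement reflects
#' the weights rather than the maturity of the running statistics.
#'
#' @param model a \code{Detector}.
#' @param dataset list of samples.
#' @param batchSize forward batch size.
#' @param gains loss gains override.
#' @return list(total, box, confidence, classification), averaged over
#'   batches.
#' @export
validationLoss <- function(model, dataset, batchSize = 4L, gains = list()) {
  tot <- c(total = 0, box = 0, confidence = 0, classification = 0)
  nb <- 0L
  for (at in seq(1L, length(dataset), by = batchSize)) {
    idx <- at:min(at + batchSize - 1L, length(dataset))
    xs <- lapply(dataset[idx], `[[`, "image")
    tg <- lapply(dataset[idx], `[[`, "boxes")
    preds <- detectorForward(model, xs, training = TRUE)
    ls <- computeLoss(preds, tg, model$config, dim(xs[[1]])[1:2], gains = gains)
    tot <- tot + c(ls$total, ls$box, ls$confidence, ls$classification)
    nb <- nb + 1L
  }
  detectorZeroGrad(model)
  as.list(tot / nb)
}

#' Scale-matched transfer-learning workflow
#'
#' Trains a source model on the (scale-matched) source dataset, then trains
#' the target model twice from the same target data: once initialized from
#' the best source weights and once from random initialization, recording
#' both validation box-loss traces. Pre-training on a scale-matched source
#' typically starts the localization loss much lower and converges faster.
#'
#' @param config \linkS4class{ModelConfig} shared by both runs.
#' @param sourceDataset training samples of the (scale-matched) source.
#' @param targetDataset training samples of the target.
#' @param valDataset validation samples of the target (defaults to
#'   \code{targetDataset}).
#' @param iterSource,iterTarget iteration budgets.
#' @param ... passed to \code{\link{fitDetector}}.
#' @return list with \code{model} (fine-tuned), \code{sourceModel},
#'   \code{pretrainedTrace} and \code{scratchTrace} (validation loss logs;
#'   row \code{iter == 0} is the pre-step measurement).
#' @export
transferWorkflow <- function(config, sourceDataset, targetDataset,
                             valDataset = targetDataset,
                             iterSource = 50L, iterTarget = 30L, ...) {
  src <- buildDetector(config)
  src <- fitDetector(src, sourceDataset, iterations = iterSource,
                     keepBest = TRUE, ...)
  pre <- buildDetector(config)
  setDetectorWeights(pre, detectorWeights(src))
  pre <- fitDetector(pre, targetDataset, iterations = iterTarget,
                     valDataset = valDataset, ...)
  scr <- buildDetector(config)
  scr <- fitDetector(scr, targetDataset, iterations = iterTarget,
                     valDataset = valDataset, ...)
  list(model = pre, sourceModel = src,
       pretrainedTrace = pre$valLog, scratchTrace = scr$valLog)
}
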