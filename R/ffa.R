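## Frequency-domain cross-modal fusion attention (FFA): per-channel 2-D
## FFT of both streams, channel attention from pooled magnitude spectra,
## per-frequency attention from 1x1 convolutions over stacked magnitudes,
## inverse FFT, and cross-wired convolutional re-enhancement. Attention
## weights are real and act on magnitudes, so phase spectra are preserved
## through both refinement stages.

#' Per-channel 2-D discrete Fourier transform of a feature map
#'
#' The forward direction applies the unnormalized 2-D DFT to each channel;
#' the inverse applies the 1/(M N)-normalized inverse transform and returns
#' the real part (the residual imaginary part of a round trip is at
#' floating-point noise level).
#'
#' @param x (H, W, C) numeric array (forward) or complex array (inverse).
#' @param direction \code{"forward"} or \code{"inverse"}.
#' @return complex (forward) or numeric (inverse) (H, W, C) array.
#' @export
spectralTransform <- function(x, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (any(!is.finite(Mod(x)))) stop("non-finite values in input")
  d <- dim(x)
  if (direction == "forward") {
    out <- array(complex(real = 0), d)
    for (c in seq_len(d[3])) out[, , c] <- stats::fft(x[, , c])
  } else {
    out <- array(0, d)
    for (c in seq_len(d[3]))
      out[, , c] <- Re(stats::fft(x[, , c], inverse = TRUE)) / (d[1] * d[2])
  }
  out
}

#' Create an FFA block
#'
#' Learnable state: a shared two-layer perceptron for channel attention
#' (input 4C: max- and average-pooled magnitude spectra of both streams;
#' hidden C/2; output 2C split into the two per-stream weight vectors), a
#' two-layer 1x1 convolution stack for per-frequency attention (input 2C,
#' hidden C/2, output 2 maps), and two plain 1x1 convolutions per stream
#' for cross re-enhancement (initialized near identity). Seed the RNG
#' before calling for reproducible initialization.
#'
#' @param C channel count of each stream's feature map (>= 2).
#' @param reduction hidden-width reduction of both attention MLPs.
#' @return an environment of class \code{FFABlock}.
#' @export
ffaBlock <- function(C, reduction = 2) {
  stopifnot(C >= 2)
  h <- max(1L, as.integer(C / reduction))
  e <- new.env(parent = emptyenv())
  e$C <- as.integer(C); e$h <- h
  rnd <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  e$mlp1_W1 <- rnd(4L * C, h); e$mlp1_b1 <- numeric(h)
  e$mlp1_W2 <- rnd(h, 2L * C); e$mlp1_b2 <- numeric(2L * C)
  e$mlp2_W1 <- rnd(2L * C, h); e$mlp2_b1 <- numeric(h)
  e$mlp2_W2 <- rnd(h, 2L); e$mlp2_b2 <- numeric(2L)
  ## re-enhancement 1x1 convs, near-identity start
  e$enh <- list(
    rgb = list(W1 = diag(C) + rnd(C, C) * 0.05, b1 = numeric(C),
               W2 = diag(C) + rnd(C, C) * 0.05, b2 = numeric(C)),
    dir = list(W1 = diag(C) + rnd(C, C) * 0.05, b1 = numeric(C),
               W2 = diag(C) + rnd(C, C) * 0.05, b2 = numeric(C)))
  class(e) <- "FFABlock"
  e
}

#' Pin an FFA block to its identity limit
#'
#' Sets the re-enhancement convolutions to exact identity (for use with
#' \code{pinWeights = TRUE} in \code{\link{ffaForward}}), under which the
#' whole module reduces to symmetric cross-addition.
#'
#' @param ffa an \code{FFABlock}.
#' @return the block, invisibly.
#' @export
ffaSetIdentityEnhance <- function(ffa) {
  C <- ffa$C
  for (s in c("rgb", "dir")) {
    ffa$enh[[s]]$W1 <- diag(C); ffa$enh[[s]]$b1 <- numeric(C)
    ffa$enh[[s]]$W2 <- diag(C); ffa$enh[[s]]$b2 <- numeric(C)
  }
  invisible(ffa)
}

#' Count learnable parameters of an FFA block
#' @param ffa an \code{FFABlock}.
#' @return numeric count.
#' @export
ffaParameters <- function(ffa) {
  n <- length(ffa$mlp1_W1) + length(ffa$mlp1_b1) + length(ffa$mlp1_W2) +
    length(ffa$mlp1_b2) + length(ffa$mlp2_W1) + length(ffa$mlp2_b1) +
    length(ffa$mlp2_W2) + length(ffa$mlp2_b2)
  for (s in c("rgb", "dir"))
    n <- n + length(ffa$enh[[s]]$W1) + length(ffa$enh[[s]]$b1) +
      length(ffa$enh[[s]]$W2) + length(ffa$enh[[s]]$b2)
  n
}

## per-pixel linear map over channels: (H, W, Cin) x (Cin, Cout)
.conv1x1 <- function(x, W, b) {
  d <- dim(x)
  y <- matrix(x, d[1] * d[2], d[3]) %*% W
  y <- sweep(y, 2, b, "+")
  array(y, c(d[1], d[2], ncol(W)))
}

#' Channel-attention refinement of a spectral pair
#'
#' Magnitude spectra of both streams are global max- and average-pooled per
#' channel, the four vectors concatenated, passed through the shared
#' two-layer perceptron and a sigmoid, and split into two per-stream weight
#' vectors in (0, 1) that multiply the complex spectra channelwise (phase
#' preserved).
#'
#' @param sRgb,sDir complex (H, W, C) spectra (matching shapes).
#' @param ffa an \code{FFABlock}.
#' @return list(sRgb =, sDir =, wRgb =, wDir =).
#' @export
channelRefine <- function(sRgb, sDir, ffa) {
  if (!identical(dim(sRgb), dim(sDir))) stop("stream shapes differ")
  C <- dim(sRgb)[3]
  if (C != ffa$C) stop("channel mismatch: spectra have ", C, ", block expects ", ffa$C)
  mR <- Mod(sRgb); mD <- Mod(sDir)
  poolMax <- function(m) apply(m, 3, max)
  poolAvg <- function(m) apply(m, 3, mean)
  v <- c(poolMax(mR), poolAvg(mR), poolMax(mD), poolAvg(mD))
  z <- pmax(drop(v %*% ffa$mlp1_W1) + ffa$mlp1_b1, 0)
  w <- sigmoid(drop(z %*% ffa$mlp1_W2) + ffa$mlp1_b2)
  wRgb <- w[seq_len(C)]; wDir <- w[C + seq_len(C)]
  out1 <- sweep(sRgb, 3, wRgb, "*")
  out2 <- sweep(sDir, 3, wDir, "*")
  list(sRgb = out1, sDir = out2, wRgb = wRgb, wDir = wDir)
}

#' Per-frequency refinement of a spectral pair
#'
#' The two refined magnitude spectra are stacked along channels and passed
#' through 1x1 convolution, ReLU, 1x1 convolution and sigmoid, yielding two
#' 1 x M x N weight maps in (0, 1) that multiply the complex spectra
#' broadcast over channels.
#'
#' @param sRgb,sDir complex (H, W, C) channel-refined spectra.
#' @param ffa an \code{FFABlock}.
#' @return list(sRgb =, sDir =, wRgb =, wDir =) with (H, W) weight maps.
#' @export
frequencyRefine <- function(sRgb, sDir, ffa) {
  if (!identical(dim(sRgb), dim(sDir))) stop("stream shapes differ")
  mag <- array(c(Mod(sRgb), Mod(sDir)), c(dim(sRgb)[1:2], 2L * dim(sRgb)[3]))
  z <- .conv1x1(mag, ffa$mlp2_W1, ffa$mlp2_b1)
  z <- pmax(z, 0)
  w <- sigmoid(.conv1x1(z, ffa$mlp2_W2, ffa$mlp2_b2))
  wRgb <- w[, , 1]; wDir <- w[, , 2]
  out1 <- sRgb * as.vector(wRgb)   # broadcast over channels (H,W fastest)
  out2 <- sDir * as.vector(wDir)
  list(sRgb = out1, sDir = out2, wRgb = wRgb, wDir = wDir)
}

#' Full FFA forward pass on a feature pair
#'
#' FFT of both streams, channel refinement, per-frequency refinement,
#' inverse FFT, then cross re-enhancement: the purified depth/infrared map
#' is passed through two 1x1 convolutions and added to the original RGB
#' feature, and symmetrically for the other stream (note the cross wiring).
#' Output shapes equal input shapes. With \code{pinWeights = TRUE} all
#' attention weights are forced to one; combined with
#' \code{\link{ffaSetIdentityEnhance}} the module reduces exactly to
#' symmetric cross-addition.
#'
#' @param ffa an \code{FFABlock}.
#' @param fRgb,fDir real (H, W, C) feature maps with C, H, W >= 2.
#' @param pinWeights force both attention stages to unit weights.
#' @return list(fRgb =, fDir =) refreshed feature maps.
#' @export
ffaForward <- function(ffa, fRgb, fDir, pinWeights = FALSE) {
  if (!identical(dim(fRgb), dim(fDir))) stop("stream shapes differ")
  d <- dim(fRgb)
  if (any(d < 2)) stop("C, H and W must each be at least 2")
  sR <- spectralTransform(fRgb, "forward")
  sD <- spectralTransform(fDir, "forward")
  if (!pinWeights) {
    cr <- channelRefine(sR, sD, ffa)
    fr <- frequencyRefine(cr$sRgb, cr$sDir, ffa)
    sR <- fr$sRgb; sD <- fr$sDir
  }
  pR <- spectralTransform(sR, "inverse")
  pD <- spectralTransform(sD, "inverse")
  eR <- .conv1x1(.conv1x1(pD, ffa$enh$rgb$W1, ffa$enh$rgb$b1),
                 ffa$enh$rgb$W2, ffa$enh$rgb$b2)
  eD <- .conv1x1(.conv1x1(pR, ffa$enh$dir$W1, ffa$enh$dir$b1),
                 ffa$enh$dir$W2, ffa$enh$dir$b2)
  list(fRgb = eR + fRgb, fDir = eD + fDir)
}

#' Build a dual-stream multimodal detector
#'
#' Two unshared improved backbones process the RGB and D_IR_IR streams.
#' After each of the three pyramid-producing backbone stages the features
#' are exchanged: through an FFA block (\code{useFFA = TRUE}) or by direct
#' summation re-injection (the \code{Without_FFA} ablation). The fused
#' pyramid features BP3/BP4/BP5 (elementwise sums of the two streams'
#' post-exchange outputs) feed the single neck and detection heads.
#'
#' @param config a \linkS4class{ModelConfig} for both streams (3-channel).
#' @param useFFA include FFA blocks (TRUE) or plain summation (FALSE).
#' @return object of class \code{MultimodalDetector}.
#' @export
buildMultimodalDetector <- function(config = modelPreset("improved"),
                                    useFFA = TRUE) {
  stopifnot(config@inChannels == 3L)
  streamA <- buildDetector(config)
  streamB <- buildDetector(config)
  ## pyramid-producing backbone node ids: stage-2 CSP (P3), stage-3 CSP
  ## (P4), post-SPP (P5)
  stageIds <- c(5L, 7L, 10L)
  chans <- vapply(stageIds, function(i) streamA$nodes[[i]]$block$cOut, integer(1))
  ffas <- if (useFFA) lapply(chans, ffaBlock) else NULL
  structure(list(config = config, streamA = streamA, streamB = streamB,
                 stageIds = stageIds, ffas = ffas, useFFA = useFFA),
            class = "MultimodalDetector")
}

#' Count parameters of a multimodal detector
#' @param mm a \code{MultimodalDetector}.
#' @param countConvention see \code{\link{blockParameters}}.
#' @return numeric count (both streams' backbones, fusion blocks, neck and
#'   heads).
#' @export
multimodalParameters <- function(mm, countConvention = "fused") {
  nodes <- mm$streamA$nodes
  full <- sum(vapply(nodes, function(nd)
    blockParameters(nd$block, countConvention), numeric(1)))
  backboneB <- sum(vapply(nodes[seq_len(max(mm$stageIds))], function(nd)
    blockParameters(nd$block, countConvention), numeric(1)))
  nFfa <- if (mm$useFFA) sum(vapply(mm$ffas, ffaParameters, numeric(1))) else 0
  full + backboneB + nFfa
}

## forward one stream's backbone segment [fromId+1 .. toId]
.runSegment <- function(model, outs, fromId, toId, xs) {
  for (id in (fromId + 1L):toId) {
    nd <- model$nodes[[id]]
    e <- model$rt[[id]]
    if (nd$block$kind %in% c("Concat", "Add")) {
      srcs <- lapply(nd$from, function(f) if (f == 0L) xs else outs[[f]])
      outs[[id]] <- if (nd$block$kind == "Concat")
        do.call(Map, c(list(catChannels), srcs))
      else Reduce(function(u, v) Map(`+`, u, v), srcs)
    } else {
      ins <- if (nd$from[1] == 0L) xs else outs[[nd$from[1]]]
      outs[[id]] <- .blockForward(e, ins, FALSE)
    }
  }
  outs
}

#' Dual-stream multimodal forward pass
#'
#' @param mm a \code{MultimodalDetector}.
#' @param rgb,dirir (H, W, 3) arrays (aligned, H and W divisible by 32);
#'   build the second stream with \code{\link{makeDIrIr}}.
#' @return list with raw head outputs \code{heads} (three levels) and the
#'   fused pyramid features \code{bp} (BP3, BP4, BP5).
#' @export
multimodalForward <- function(mm, rgb, dirir) {
  if (!identical(dim(rgb), dim(dirir))) stop("misaligned stream inputs")
  A <- mm$streamA; B <- mm$streamB
  outsA <- vector("list", length(A$nodes))
  outsB <- vector("list", length(B$nodes))
  prev <- 0L
  bp <- vector("list", 3L)
  for (k in seq_along(mm$stageIds)) {
    id <- mm$stageIds[k]
    outsA <- .runSegment(A, outsA, prev, id, list(rgb))
    outsB <- .runSegment(B, outsB, prev, id, list(dirir))
    fa <- outsA[[id]][[1]]; fb <- outsB[[id]][[1]]
    if (mm$useFFA) {
      ## cross re-enhancement refreshes both streams before they continue
      ex <- ffaForward(mm$ffas[[k]], fa, fb)
      outsA[[id]] <- list(ex$fRgb); outsB[[id]] <- list(ex$fDir)
      bp[[k]] <- ex$fRgb + ex$fDir
    } else {
      ## summation ablation: the fused pyramid taps the plain sum while
      ## each stream continues with its own features
      bp[[k]] <- fa + fb
    }
    prev <- id
  }
  ## neck and heads of stream A consume the fused pyramid
  for (k in seq_along(mm$stageIds)) outsA[[mm$stageIds[k]]] <- list(bp[[k]])
  outsA <- .runSegment(A, outsA, max(mm$stageIds), length(A$nodes), list(rgb))
  list(heads = outsA[A$headIds], bp = bp)
}
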