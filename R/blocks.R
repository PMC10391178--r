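## Network building blocks as countable layer specifications.
##
## Every block used by the detector family is described as an ordered list of
## atomic layers (convolutions, pools, resamplings). Atoms carry enough
## information to (a) count learnable parameters under either of two published
## conventions and (b) count floating-point operations at a given input size,
## and they double as the construction plan for the runtime network.

#' Atomic layer specification
#'
#' @param cIn,cOut input/output channel counts.
#' @param k kernel size (px).
#' @param s stride.
#' @param outDiv total spatial downscale of this atom's output relative to
#'   the block input (captures stride and any space-to-depth slicing).
#' @param norm whether the layer carries a normalization stage.
#' @param bias whether the convolution has an explicit bias.
#' @param op \code{"conv"}, \code{"dsconv"}, \code{"pool"} or \code{"resample"}.
#' @param tag short role label used by the runtime builder.
#' @return a \code{LayerSpec} list.
#' @keywords internal
layerSpec <- function(cIn, cOut, k = 1L, s = 1L, outDiv = s, norm = TRUE,
                      bias = FALSE, op = "conv", tag = "") {
  stopifnot(cIn >= 1, cOut >= 1, k >= 1, s >= 1)
  structure(list(cIn = as.integer(cIn), cOut = as.integer(cOut),
                 k = as.integer(k), s = as.integer(s), outDiv = outDiv,
                 norm = norm, bias = bias, op = op, tag = tag),
            class = "LayerSpec")
}

## Supported block kinds. "CSP2" is the shortcut-free C3 used in the neck;
## "C3_DSConv" substitutes blockwise-quantized DSConv kernels for its inner
## 3x3 convolutions.
.blockKinds <- c("ConvBNAct", "Focus", "CSP1_n", "CSP2", "C3_DSConv",
                 "SPP", "SPPF", "Detect", "Upsample", "Concat", "Add")

## DSConv bookkeeping: blockwise variable-quantized kernel with a
## per-block distribution-shift scale. Block length along the flattened
## receptive field; 4-bit kernel entries are emulated in float.
.dsconvBlockLen <- 32L

#' Construct a network building block
#'
#' Returns a \code{Block}: an ordered list of atomic \code{LayerSpec}s plus
#' the block-level contract (input/output channels, spatial divisor). The
#' forward contract maps (cIn, H, W) to (cOut, H/s, W/s). The slicing stem
#' (\code{Focus}) rearranges each 2x2 neighbourhood into channels (so 4 cIn
#' channels enter its k=3 convolution at half resolution); the replacement
#' stem is a single k=6, stride-2 convolution with identical parameter count.
#'
#' @param kind one of \code{"ConvBNAct"}, \code{"Focus"}, \code{"CSP1_n"},
#'   \code{"CSP2"}, \code{"C3_DSConv"}, \code{"SPP"}, \code{"SPPF"},
#'   \code{"Detect"}, \code{"Upsample"}, \code{"Concat"}, \code{"Add"}.
#' @param cIn,cOut channel counts.
#' @param k kernel size (ConvBNAct/Focus only).
#' @param s stride (ConvBNAct only).
#' @param n internal repeat count (CSP kinds only), >= 1.
#' @param e hidden-channel expansion of CSP kinds (default 0.5).
#' @param poolK pooling kernel set for SPP/SPPF (default c(5, 9, 13); SPPF
#'   applies the first entry serially, with identical parameters).
#' @return an object of class \code{Block}.
#' @examples
#' b <- makeBlock("ConvBNAct", 3, 32, k = 6, s = 2)
#' blockParameters(b)                  # 3456 weights + 64 affine terms
#' blockParameters(b, "fused")         # 3456 weights + 32 folded biases
#' @export
makeBlock <- function(kind, cIn, cOut, k = 1L, s = 1L, n = 1L, e = 0.5,
                      poolK = c(5L, 9L, 13L)) {
  kind <- match.arg(kind, .blockKinds)
  cIn <- as.integer(cIn); cOut <- as.integer(cOut)
  if (kind %in% c("ConvBNAct", "Focus", "CSP1_n", "CSP2", "C3_DSConv",
                  "SPP", "SPPF", "Detect") && (cIn < 1L || cOut < 1L))
    stop("channel counts must be positive")
  if (kind %in% c("CSP1_n", "CSP2", "C3_DSConv") && n < 1L)
    stop("repeat count n must be >= 1 for CSP kinds")
  layers <- switch(kind,
    ConvBNAct = list(layerSpec(cIn, cOut, k, s, tag = "conv")),
    Focus = list(layerSpec(4L * cIn, cOut, 3L, 1L, outDiv = 2L, tag = "focus_conv")),
    CSP1_n = .cspLayers(cIn, cOut, n, e, shortcut = TRUE, ds = FALSE),
    CSP2 = .cspLayers(cIn, cOut, n, e, shortcut = FALSE, ds = FALSE),
    C3_DSConv = .cspLayers(cIn, cOut, n, e, shortcut = FALSE, ds = TRUE),
    SPP = .sppLayers(cIn, cOut, poolK, serial = FALSE),
    SPPF = .sppLayers(cIn, cOut, poolK, serial = TRUE),
    Detect = list(layerSpec(cIn, cOut, 1L, 1L, norm = FALSE, bias = TRUE, tag = "head")),
    Upsample = list(layerSpec(cIn, cOut, 1L, 1L, outDiv = 0.5, op = "resample", tag = "upsample")),
    Concat = list(),
    Add = list())
  spatialDiv <- switch(kind, ConvBNAct = s, Focus = 2L, Upsample = 0.5, 1L)
  structure(list(kind = kind, cIn = cIn, cOut = cOut, n = as.integer(n),
                 layers = layers, spatialDiv = spatialDiv),
            class = "Block")
}

## C3-family layer plan: two parallel 1x1 projections to c_ hidden channels,
## n bottleneck units (1x1 then 3x3) on one branch, concatenation, 1x1 fuse.
.cspLayers <- function(cIn, cOut, n, e, shortcut, ds) {
  ch <- as.integer(floor(cOut * e))
  inner <- if (ds) "dsconv" else "conv"
  out <- list(
    layerSpec(cIn, ch, 1L, tag = "cv1"),
    layerSpec(cIn, ch, 1L, tag = "cv2"))
  for (i in seq_len(n)) {
    out <- c(out, list(
      layerSpec(ch, ch, 1L, tag = sprintf("b%d_cv1", i)),
      layerSpec(ch, ch, 3L, op = inner, tag = sprintf("b%d_cv2", i))))
  }
  c(out, list(layerSpec(2L * ch, cOut, 1L, tag = "cv3")))
}

.sppLayers <- function(cIn, cOut, poolK, serial) {
  ch <- cIn %/% 2L
  pools <- if (serial) rep(poolK[1], 3L) else poolK
  out <- list(layerSpec(cIn, ch, 1L, tag = "cv1"))
  for (i in seq_along(pools))
    out <- c(out, list(layerSpec(ch, ch, as.integer(pools[i]), op = "pool",
                                 tag = sprintf("pool%d", i))))
  c(out, list(layerSpec(ch * (length(pools) + 1L), cOut, 1L, tag = "cv2")))
}

.atomParameters <- function(a, convention) {
  if (!a$op %in% c("conv", "dsconv")) return(0)
  w <- as.numeric(a$cIn) * a$cOut * a$k * a$k
  extra <- if (a$op == "dsconv")
    a$cOut * ceiling(a$cIn * a$k * a$k / .dsconvBlockLen) else 0
  affine <- if (convention == "train") {
    (if (a$norm) 2 else 0) * a$cOut + (if (a$bias) 1 else 0) * a$cOut
  } else {
    (if (a$norm || a$bias) 1 else 0) * a$cOut
  }
  w + extra + affine
}

#' Count learnable parameters of a block
#'
#' Two counting conventions are supported. \code{"train"} counts the
#' training-time parameterization: convolution weights, explicit biases and
#' both normalization affine terms (scale and shift) per channel; running
#' statistics are never counted. \code{"fused"} counts the deployed network
#' after normalization folding, where each convolution carries its weights
#' plus a single per-channel bias; this is the convention under which the
#' published variant totals of this model family are quoted, and the default
#' used by \code{\link{modelSummary}}.
#'
#' @param block a \code{Block} from \code{\link{makeBlock}}.
#' @param convention \code{"train"} or \code{"fused"}.
#' @return numeric parameter count.
#' @export
blockParameters <- function(block, convention = c("train", "fused")) {
  convention <- match.arg(convention)
  if (!length(block$layers)) return(0)
  sum(vapply(block$layers, .atomParameters, numeric(1), convention = convention))
}

#' Count floating-point operations of a block
#'
#' Convolution cost per layer at its output size H_out x W_out. The
#' \code{"mac2"} convention counts two operations per multiply-accumulate,
#' \code{2 * cIn * k^2 * cOut * Hout * Wout}, the convention under which
#' model-total GFLOPs are quoted. The \code{"literal"} convention subtracts
#' the one saved addition per output element,
#' \code{(2 * cIn * k^2 - 1) * cOut * Hout * Wout}. Pooling, resampling,
#' normalization and activations are not counted (they are folded or
#' negligible at the quoted precision).
#'
#' @param block a \code{Block}.
#' @param inputHW integer(2), (H, W) of the block input.
#' @param convention \code{"mac2"} or \code{"literal"}.
#' @return numeric operation count (FLOPs, not GFLOPs).
#' @export
blockFlops <- function(block, inputHW, convention = c("mac2", "literal")) {
  convention <- match.arg(convention)
  stopifnot(length(inputHW) == 2L, all(inputHW > 0))
  total <- 0
  for (a in block$layers) {
    if (!a$op %in% c("conv", "dsconv")) next
    hw <- prod(floor(inputHW / a$outDiv))
    mult <- a$cIn * a$k * a$k
    per <- if (convention == "mac2") 2 * mult else 2 * mult - 1
    total <- total + per * hw * a$cOut
  }
  total
}
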