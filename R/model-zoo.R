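## Declarative model zoo: every architectural variant of the detector family
## is built from a ModelConfig through a shared blueprint (an ordered DAG of
## Blocks), which serves both exact parameter/FLOP accounting and the runtime
## network builder.

## Default three-level anchor priors (w, h in px at 640 input), strides 8/16/32.
.defaultAnchors <- function() {
  a <- array(0, c(3, 2, 3))
  a[, , 1] <- matrix(c(10, 13, 16, 30, 33, 23), 3, 2, byrow = TRUE)
  a[, , 2] <- matrix(c(30, 61, 62, 45, 59, 119), 3, 2, byrow = TRUE)
  a[, , 3] <- matrix(c(116, 90, 156, 198, 373, 326), 3, 2, byrow = TRUE)
  a
}

#' Small-object anchor priors
#'
#' Three-level anchor set shrunk toward the tiny-object regime of dense
#' plant scenes (objects of a few to a few tens of pixels), for use via
#' \code{modelConfig(anchors = smallObjectAnchors())}. With priors close to
#' the object sizes, the wh-ratio assignment gate admits tiny boxes and the
#' box-regression loss is informative from the first iterations.
#'
#' @return 3 x 2 x 3 numeric array of (w, h) priors in px.
#' @export
smallObjectAnchors <- function() {
  a <- array(0, c(3, 2, 3))
  a[, , 1] <- matrix(c(4, 5, 6, 8, 9, 11), 3, 2, byrow = TRUE)
  a[, , 2] <- matrix(c(12, 16, 19, 14, 16, 24), 3, 2, byrow = TRUE)
  a[, , 3] <- matrix(c(28, 22, 24, 38, 44, 40), 3, 2, byrow = TRUE)
  a
}

#' Create a model configuration
#'
#' @param stem \code{"focus"} or \code{"conv6"}.
#' @param stageRepeats nominal CSP1_n repeats of the four backbone stages.
#' @param depthMultiple,widthMultiple depth/width scaling (0.33 / 0.50 for
#'   the "s" scale used throughout).
#' @param neck \code{"panet"} or \code{"fpn"}.
#' @param neckCsp \code{"csp2"} or \code{"c3_dsconv"}.
#' @param spp \code{"sppf"} (serial, fast) or \code{"spp"} (parallel);
#'   identical parameter counts for the (5, 9, 13) kernel set.
#' @param inChannels 3, or 4 for the RGBA data-layer fusion input.
#' @param numClasses number of object classes (1 for tea shoots).
#' @param anchors 3 x 2 x 3 array of anchor priors, (w, h) by level.
#' @param imgSize nominal input size, divisible by 32.
#' @return a \linkS4class{ModelConfig}.
#' @seealso \code{\link{modelPreset}}, \code{\link{buildDetector}},
#'   \code{\link{modelSummary}}
#' @export
modelConfig <- function(stem = "conv6", stageRepeats = c(3, 6, 9, 3),
                        depthMultiple = 0.33, widthMultiple = 0.50,
                        neck = "panet", neckCsp = "csp2", spp = "sppf",
                        inChannels = 3, numClasses = 1,
                        anchors = .defaultAnchors(), imgSize = 640) {
  new("ModelConfig", stem = stem, stageRepeats = as.integer(stageRepeats),
      depthMultiple = depthMultiple, widthMultiple = widthMultiple,
      neck = neck, neckCsp = neckCsp, spp = spp,
      inChannels = as.integer(inChannels), numClasses = as.integer(numClasses),
      anchors = anchors, imgSize = as.integer(imgSize))
}

#' Named model presets
#'
#' \describe{
#'   \item{baseline}{slicing (Focus) stem, nominal repeats 3,6,9,3, SPP-family
#'     pooling, path-aggregation (PANet) neck, standard neck CSP2.}
#'   \item{improved}{k=6 convolution stem, repeats 8,8,3,3 (more capacity at
#'     high resolution), top-down FPN neck, DSConv neck CSP.}
#'   \item{improved_4ch}{improved variant with a 4-channel (RGBA) input.}
#'   \item{baseline_4ch}{baseline with a 4-channel input.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed to \code{\link{modelConfig}}.
#' @return a \linkS4class{ModelConfig}.
#' @export
modelPreset <- function(name = c("baseline", "improved", "improved_4ch",
                                 "baseline_4ch"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    baseline = list(stem = "focus", stageRepeats = c(3, 6, 9, 3),
                    neck = "panet", neckCsp = "csp2"),
    improved = list(stem = "conv6", stageRepeats = c(8, 8, 3, 3),
                    neck = "fpn", neckCsp = "c3_dsconv"),
    improved_4ch = list(stem = "conv6", stageRepeats = c(8, 8, 3, 3),
                        neck = "fpn", neckCsp = "c3_dsconv", inChannels = 4),
    baseline_4ch = list(stem = "focus", stageRepeats = c(3, 6, 9, 3),
                        neck = "panet", neckCsp = "csp2", inChannels = 4))
  do.call(modelConfig, utils::modifyList(base, list(...)))
}

#' Effective repeat count under a depth multiple
#'
#' Nominal stage repeats are scaled by the depth multiple and rounded half
#' up, never below one: \code{max(floor(n * d + 0.5), 1)}. Distinct nominal
#' allocations that map to the same effective vector build identical
#' networks (e.g. 8,8,3,3 and 9,8,2,2 at depth multiple 0.33 both realize
#' 3,3,1,1).
#'
#' @param nNominal nominal repeat count(s), >= 1.
#' @param depthMultiple scaling fraction in (0, 1].
#' @return integer effective repeat count(s).
#' @examples
#' effectiveDepth(c(3, 6, 9, 3), 0.33)  # 1 2 3 1
#' effectiveDepth(c(8, 8, 3, 3), 0.33)  # 3 3 1 1
#' @export
effectiveDepth <- function(nNominal, depthMultiple) {
  stopifnot(all(nNominal >= 1), depthMultiple > 0, depthMultiple <= 1)
  pmax(as.integer(floor(nNominal * depthMultiple + 0.5)), 1L)
}

## Channel width under the width multiple, rounded up to a multiple of 8.
makeDivisible <- function(x, divisor = 8L) as.integer(ceiling(x / divisor) * divisor)

#' Expand a configuration into an ordered blueprint
#'
#' The blueprint is the single source of architectural truth: a list of
#' nodes, each holding a \code{Block}, the indices of its input node(s)
#' (\code{0} = network input) and its role. Parameter counting, FLOP
#' accounting and the runtime network builder all consume it.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @return list of nodes with elements \code{id}, \code{from}, \code{block},
#'   \code{role}; detection head nodes are tagged \code{role = "head"} with a
#'   \code{stride} field.
#' @keywords internal
buildBlueprint <- function(config) {
  gw <- config@widthMultiple
  gd <- config@depthMultiple
  cw <- function(c) makeDivisible(c * gw)
  dn <- function(n) effectiveDepth(n, gd)
  r <- config@stageRepeats
  no <- 3L * (config@numClasses + 5L)
  neckKind <- if (config@neckCsp == "csp2") "CSP2" else "C3_DSConv"

  nodes <- list()
  addNode <- function(from, block, role = "body", stride = NA_integer_) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, from = as.integer(from), block = block,
                         role = role, stride = stride)
    id
  }

  c64 <- cw(64); c128 <- cw(128); c256 <- cw(256); c512 <- cw(512); c1024 <- cw(1024)

  ## backbone
  stemBlock <- if (config@stem == "focus")
    makeBlock("Focus", config@inChannels, c64, k = 3L)
  else makeBlock("ConvBNAct", config@inChannels, c64, k = 6L, s = 2L)
  i0 <- addNode(0L, stemBlock)                                          # P1/2
  i1 <- addNode(i0, makeBlock("ConvBNAct", c64, c128, k = 3L, s = 2L))  # P2/4
  i2 <- addNode(i1, makeBlock("CSP1_n", c128, c128, n = dn(r[1])))
  i3 <- addNode(i2, makeBlock("ConvBNAct", c128, c256, k = 3L, s = 2L)) # P3/8
  i4 <- addNode(i3, makeBlock("CSP1_n", c256, c256, n = dn(r[2])))
  i5 <- addNode(i4, makeBlock("ConvBNAct", c256, c512, k = 3L, s = 2L)) # P4/16
  i6 <- addNode(i5, makeBlock("CSP1_n", c512, c512, n = dn(r[3])))
  i7 <- addNode(i6, makeBlock("ConvBNAct", c512, c1024, k = 3L, s = 2L)) # P5/32
  i8 <- addNode(i7, makeBlock("CSP1_n", c1024, c1024, n = dn(r[4])))
  i9 <- addNode(i8, makeBlock(toupper(config@spp), c1024, c1024))

  if (config@neck == "panet") {
    i10 <- addNode(i9, makeBlock("ConvBNAct", c1024, c512, k = 1L))
    i11 <- addNode(i10, makeBlock("Upsample", c512, c512))
    i12 <- addNode(c(i11, i6), makeBlock("Concat", c512 + c512, c512 + c512))
    i13 <- addNode(i12, makeBlock(neckKind, c512 + c512, c512, n = dn(3)))
    i14 <- addNode(i13, makeBlock("ConvBNAct", c512, c256, k = 1L))
    i15 <- addNode(i14, makeBlock("Upsample", c256, c256))
    i16 <- addNode(c(i15, i4), makeBlock("Concat", c256 + c256, c256 + c256))
    i17 <- addNode(i16, makeBlock(neckKind, c256 + c256, c256, n = dn(3)))
    i18 <- addNode(i17, makeBlock("ConvBNAct", c256, c256, k = 3L, s = 2L))
    i19 <- addNode(c(i18, i14), makeBlock("Concat", c256 + c256, c256 + c256))
    i20 <- addNode(i19, makeBlock(neckKind, c256 + c256, c512, n = dn(3)))
    i21 <- addNode(i20, makeBlock("ConvBNAct", c512, c512, k = 3L, s = 2L))
    i22 <- addNode(c(i21, i10), makeBlock("Concat", c512 + c512, c512 + c512))
    i23 <- addNode(i22, makeBlock(neckKind, c512 + c512, c1024, n = dn(3)))
    addNode(i17, makeBlock("Detect", c256, no), role = "head", stride = 8L)
    addNode(i20, makeBlock("Detect", c512, no), role = "head", stride = 16L)
    addNode(i23, makeBlock("Detect", c1024, no), role = "head", stride = 32L)
  } else {
    ## top-down feature pyramid: a full C3 stage on P5, then two top-down
    ## fuse steps; heads read the three top-down C3 outputs directly.
    i10 <- addNode(i9, makeBlock(neckKind, c1024, c1024, n = dn(3)))
    i11 <- addNode(i10, makeBlock("ConvBNAct", c1024, c512, k = 1L))
    i12 <- addNode(i11, makeBlock("Upsample", c512, c512))
    i13 <- addNode(c(i12, i6), makeBlock("Concat", c512 + c512, c512 + c512))
    i14 <- addNode(i13, makeBlock(neckKind, c512 + c512, c512, n = dn(3)))
    i15 <- addNode(i14, makeBlock("ConvBNAct", c512, c256, k = 1L))
    i16 <- addNode(i15, makeBlock("Upsample", c256, c256))
    i17 <- addNode(c(i16, i4), makeBlock("Concat", c256 + c256, c256 + c256))
    i18 <- addNode(i17, makeBlock(neckKind, c256 + c256, c256, n = dn(3)))
    addNode(i18, makeBlock("Detect", c256, no), role = "head", stride = 8L)
    addNode(i14, makeBlock("Detect", c512, no), role = "head", stride = 16L)
    addNode(i10, makeBlock("Detect", c1024, no), role = "head", stride = 32L)
  }
  nodes
}

## Spatial size (H, W) at each node output for a given input size.
.blueprintSizes <- function(nodes, inputHW) {
  sizes <- vector("list", length(nodes))
  for (nd in nodes) {
    src <- if (nd$from[1] == 0L) inputHW else sizes[[nd$from[1]]]
    sizes[[nd$id]] <- src / nd$block$spatialDiv
  }
  sizes
}

#' Summarize a model variant: parameters and GFLOPs
#'
#' Builds the blueprint for a configuration (or takes it from a built
#' detector) and reports the total learnable parameter count, total GFLOPs
#' at the given input size and a per-node breakdown table.
#'
#' @param x a \linkS4class{ModelConfig} or a \code{Detector}.
#' @param imgSize square input size in px, divisible by 32.
#' @param countConvention parameter counting convention (see
#'   \code{\link{blockParameters}}); the \code{"fused"} default is the
#'   convention under which this model family's published totals are quoted.
#' @param flopConvention see \code{\link{blockFlops}}.
#' @return list with \code{parameters}, \code{gflops} and a data.frame
#'   \code{breakdown}.
#' @examples
#' s <- modelSummary(modelPreset("baseline"))
#' s$parameters   # 7012822
#' round(s$gflops, 1)  # 15.8
#' @export
modelSummary <- function(x, imgSize = NULL,
                         countConvention = c("fused", "train"),
                         flopConvention = c("mac2", "literal")) {
  countConvention <- match.arg(countConvention)
  flopConvention <- match.arg(flopConvention)
  config <- if (is(x, "ModelConfig")) x
    else if (inherits(x, "Detector")) x$config
    else stop("x must be a ModelConfig or a Detector")
  if (is.null(imgSize)) imgSize <- config@imgSize
  if (imgSize %% 32 != 0) stop("imgSize must be divisible by 32")
  nodes <- buildBlueprint(config)
  sizes <- .blueprintSizes(nodes, c(imgSize, imgSize))
  pars <- vapply(nodes, function(nd) blockParameters(nd$block, countConvention), numeric(1))
  flops <- vapply(nodes, function(nd) {
    src <- if (nd$from[1] == 0L) c(imgSize, imgSize) else sizes[[nd$from[1]]]
    blockFlops(nd$block, src, flopConvention)
  }, numeric(1))
  breakdown <- data.frame(
    id = vapply(nodes, `[[`, integer(1), "id"),
    kind = vapply(nodes, function(nd) nd$block$kind, character(1)),
    cOut = vapply(nodes, function(nd) nd$block$cOut, integer(1)),
    parameters = pars, flops = flops)
  list(parameters = sum(pars), gflops = sum(flops) / 1e9, breakdown = breakdown)
}

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig:", object@stem, "stem |",
      paste(object@stageRepeats, collapse = ","), "stages |",
      object@neck, "neck |", object@neckCsp, "|",
      object@inChannels, "ch in |", object@numClasses, "classes\n")
  s <- modelSummary(object)
  cat(sprintf("  parameters: %s (fused) | GFLOPs @%d: %.1f\n",
              format(s$parameters, big.mark = ","), object@imgSize, s$gflops))
})
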