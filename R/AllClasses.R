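#' @import methods
NULL

#' Architectural genotype of a detector variant
#'
#' A \code{ModelConfig} captures everything needed to build (and to count the
#' parameters / floating-point operations of) one variant of the one-stage
#' detector family used throughout this package: the stem type, the nominal
#' cross-stage-partial (CSP1) repeat counts of the four backbone stages, the
#' depth and width multiples that scale them, the neck topology, the neck CSP
#' realization, the number of input channels and classes, the anchor priors
#' and the nominal input size.
#'
#' @slot stem \code{"focus"} (space-to-depth slicing stem) or \code{"conv6"}
#'   (single k=6, stride-2 convolution stem).
#' @slot stageRepeats integer(4), nominal CSP1_n repeats of the four backbone
#'   stages (e.g. \code{c(3,6,9,3)} for the baseline, \code{c(8,8,3,3)} for
#'   the improved allocation).
#' @slot depthMultiple,widthMultiple numeric scalars scaling repeats and
#'   channel widths (0.33 / 0.50 for the "s" scale).
#' @slot neck \code{"panet"} (top-down + bottom-up path aggregation) or
#'   \code{"fpn"} (top-down feature pyramid only).
#' @slot neckCsp \code{"csp2"} (standard C3 without shortcut) or
#'   \code{"c3_dsconv"} (inner 3x3 convolutions replaced by blockwise
#'   quantized DSConv kernels).
#' @slot spp \code{"sppf"} or \code{"spp"}; identical parameter counts for
#'   the (5, 9, 13) kernel set, SPPF is the faster serial form.
#' @slot inChannels integer, 3 or 4.
#' @slot numClasses integer >= 1.
#' @slot anchors 3x2xL numeric array of anchor priors (w, h in pixels) for
#'   the three detection levels at strides 8/16/32.
#' @slot imgSize integer, nominal square input size (divisible by 32).
#' @export
setClass("ModelConfig", representation(
  stem = "character", stageRepeats = "integer",
  depthMultiple = "numeric", widthMultiple = "numeric",
  neck = "character", neckCsp = "character", spp = "character",
  inChannels = "integer", numClasses = "integer",
  anchors = "array", imgSize = "integer"
))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@stem %in% c("focus", "conv6")) msg <- c(msg, "stem must be 'focus' or 'conv6'")
  if (length(object@stageRepeats) != 4L || any(object@stageRepeats < 1L))
    msg <- c(msg, "stageRepeats must be 4 integers >= 1")
  if (!object@neck %in% c("panet", "fpn")) msg <- c(msg, "neck must be 'panet' or 'fpn'")
  if (!object@neckCsp %in% c("csp2", "c3_dsconv")) msg <- c(msg, "neckCsp must be 'csp2' or 'c3_dsconv'")
  if (!object@spp %in% c("spp", "sppf")) msg <- c(msg, "spp must be 'spp' or 'sppf'")
  if (!object@inChannels %in% c(3L, 4L)) msg <- c(msg, "inChannels must be 3 or 4")
  if (object@numClasses < 1L) msg <- c(msg, "numClasses must be >= 1")
  if (object@depthMultiple <= 0 || object@depthMultiple > 1) msg <- c(msg, "depthMultiple must be in (0, 1]")
  if (object@imgSize %% 32L != 0L) msg <- c(msg, "imgSize must be divisible by 32")
  if (length(msg)) msg else TRUE
})

#' One aligned RGB / infrared / depth frame set
#'
#' Container for one spatially aligned multimodal frame: an 8-bit-per-channel
#' RGB image, a 16-bit single-channel infrared intensity image and an 8-bit
#' single-channel depth image, all stored as numeric arrays in [0, 1] with
#' the source bit depth kept as metadata. Annotations are shared across the
#' three modalities (label sharing), so a triplet carries at most one
#' \linkS4class{BoxAnnotationSet}.
#'
#' @slot rgb numeric H x W x 3 array in [0, 1].
#' @slot ir numeric H x W matrix in [0, 1] (16-bit source scale).
#' @slot depth numeric H x W matrix in [0, 1] (8-bit source scale).
#' @slot bitDepths named integer vector (rgb, ir, depth).
#' @slot frameId character frame identifier.
#' @slot aligned logical, whether the modalities are pixel-aligned.
#' @export
setClass("ModalityTriplet", representation(
  rgb = "array", ir = "matrix", depth = "matrix",
  bitDepths = "integer", frameId = "character", aligned = "logical"
))

setValidity("ModalityTriplet", function(object) {
  msg <- character()
  drgb <- dim(object@rgb)
  if (length(drgb) != 3L || drgb[3] != 3L) msg <- c(msg, "rgb must be H x W x 3")
  if (!identical(dim(object@ir), drgb[1:2])) msg <- c(msg, "ir size differs from rgb")
  if (!identical(dim(object@depth), drgb[1:2])) msg <- c(msg, "depth size differs from rgb")
  if (!all(c("rgb", "ir", "depth") %in% names(object@bitDepths)))
    msg <- c(msg, "bitDepths must name rgb, ir, depth")
  for (nm in c("rgb", "ir", "depth")) {
    v <- slot(object, nm)
    if (length(v) && (min(v) < 0 || max(v) > 1)) msg <- c(msg, paste0(nm, " values must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Object box annotations for one image
#'
#' Boxes are stored in normalized center form (class id, cx, cy, w, h, all
#' coordinates divided by image width/height), the unit of label sharing
#' across modalities. Pixel coordinates are 0-based with half-open boxes
#' [x, x + w).
#'
#' @slot boxes data.frame with columns \code{class}, \code{cx}, \code{cy},
#'   \code{w}, \code{h} (normalized).
#' @slot imageId character.
#' @slot imageSize integer(2), (H, W) in pixels.
#' @export
setClass("BoxAnnotationSet", representation(
  boxes = "data.frame", imageId = "character", imageSize = "integer"
))

setValidity("BoxAnnotationSet", function(object) {
  b <- object@boxes
  need <- c("class", "cx", "cy", "w", "h")
  if (!all(need %in% names(b))) return("boxes must have columns class, cx, cy, w, h")
  if (length(object@imageSize) != 2L || any(object@imageSize < 1L)) return("imageSize must be (H, W)")
  if (nrow(b)) {
    if (any(b$w <= 0 | b$h <= 0)) return("box widths/heights must be positive")
    if (any(b$cx < 0 | b$cx > 1 | b$cy < 0 | b$cy > 1)) return("box centers must lie in [0, 1]")
  }
  TRUE
})

#' Per-dataset relative-scale summary
#'
#' Mean relative scale of all annotated objects in a dataset and its
#' histogram; the quantity that drives object-based scale matching. The
#' relative scale of a box is \code{sqrt((w * h) / (W * H))}, the geometric
#' mean side fraction.
#'
#' @slot s mean relative scale, in (0, 1].
#' @slot histogram numeric vector of bin counts.
#' @slot breaks numeric vector of bin edges.
#' @slot nObjects integer, number of objects summarized.
#' @export
setClass("ScaleStats", representation(
  s = "numeric", histogram = "numeric", breaks = "numeric", nObjects = "integer"
))

setValidity("ScaleStats", function(object) {
  if (object@s <= 0 || object@s > 1) return("s must be in (0, 1]")
  if (sum(object@histogram) != object@nObjects) return("histogram mass must equal nObjects")
  TRUE
})

#' Configuration of the synthetic aligned-triplet scene generator
#'
#' Defaults emulate the statistical structure of a dense tea-shoot field
#' frame: a 512 x 360 crop holding 200-400 tiny elongated objects whose
#' relative scale lies mostly below 0.05, low chromatic contrast to the
#' background, a 0.5-1.0 m depth range with void-prone depth and a
#' speckle-laden infrared channel.
#'
#' @slot imageSize integer(2) (H, W).
#' @slot countRange integer(2), objects per image.
#' @slot meanScale numeric, target mean relative scale of object boxes.
#' @slot scaleSpread numeric, log-sd of the relative-scale distribution.
#' @slot colorContrast numeric in [0, 1], chromatic offset of objects from
#'   the background (0 = chromatically invisible).
#' @slot depthRange numeric(2), scene depth range in metres (mapped to the
#'   stored 8-bit range).
#' @slot depthVoidRate numeric in [0, 1], fraction of depth pixels zeroed as
#'   sensor voids.
#' @slot irContrast numeric, object reflectance contrast in the IR channel.
#' @slot irSpeckle numeric, multiplicative speckle level of the IR channel.
#' @export
setClass("SceneConfig", representation(
  imageSize = "integer", countRange = "integer",
  meanScale = "numeric", scaleSpread = "numeric",
  colorContrast = "numeric", depthRange = "numeric",
  depthVoidRate = "numeric", irContrast = "numeric", irSpeckle = "numeric"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (any(object@imageSize < 32L)) msg <- c(msg, "imageSize too small")
  if (length(object@countRange) != 2L || any(object@countRange < 1L) ||
      object@countRange[1] > object@countRange[2])
    msg <- c(msg, "countRange must be an increasing positive pair")
  if (object@meanScale <= 0 || object@meanScale >= 1) msg <- c(msg, "meanScale must be in (0, 1)")
  if (object@depthVoidRate < 0 || object@depthVoidRate > 1) msg <- c(msg, "depthVoidRate must be in [0, 1]")
  if (length(object@depthRange) != 2L || object@depthRange[1] >= object@depthRange[2])
    msg <- c(msg, "depthRange must be an increasing pair")
  if (length(msg)) msg else TRUE
})
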