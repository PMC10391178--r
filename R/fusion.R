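## Data-layer fusion of aligned RGB / infrared / depth frames. All
## operators act pixelwise on normalized [0, 1] images, so they commute
## with spatial cropping; re-quantization to 8 bits happens only on write.

#' Normalize a stored-integer image to unit range
#'
#' Linear map to [0, 1] by division with \code{2^bits - 1}.
#'
#' @param image numeric array of raw integer code values.
#' @param sourceBitDepth 8 or 16.
#' @return image in [0, 1].
#' @examples
#' normalizeModality(255, 8)     # 1
#' normalizeModality(32767, 16)  # 0.49999237
#' @export
normalizeModality <- function(image, sourceBitDepth) {
  if (!sourceBitDepth %in% c(8L, 16L))
    stop("unsupported bit depth: ", sourceBitDepth)
  image / (2^sourceBitDepth - 1)
}

.checkAligned <- function(rgb, ir, depth) {
  hw <- dim(rgb)[1:2]
  if (!identical(dim(ir)[1:2], hw)) stop("ir is not aligned with rgb")
  if (!identical(dim(depth)[1:2], hw)) stop("depth is not aligned with rgb")
  hw
}

#' Weighted pixel-level fusion (method 1)
#'
#' \code{out = w_rgb * rgb + w_ir * ir + w_depth * depth}, the single-channel
#' modalities broadcast across the three color channels. The study weights
#' are (0.6, 0.2, 0.2); any nonnegative weights summing to at most one keep
#' the output in range.
#'
#' @param rgb H x W x 3 array in [0, 1].
#' @param ir,depth H x W matrices in [0, 1].
#' @param weights numeric(3): (w_rgb, w_ir, w_depth).
#' @return H x W x 3 fused image.
#' @export
fuseWeighted <- function(rgb, ir, depth, weights = c(0.6, 0.2, 0.2)) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  .checkAligned(rgb, ir, depth)
  out <- weights[1] * rgb
  add <- weights[2] * ir + weights[3] * depth
  for (c in 1:3) out[, , c] <- out[, , c] + add
  out
}

#' RGBA channel-stacking fusion (method 2)
#'
#' The alpha plane is the weighted sum of infrared and depth
#' (\code{w_ir2 * ir + w_depth2 * depth}, study weights 0.5/0.5); the first
#' three channels are the RGB image untouched.
#'
#' @param rgb H x W x 3 array.
#' @param ir,depth H x W matrices.
#' @param weights numeric(2): (w_ir2, w_depth2).
#' @return H x W x 4 array (R, G, B, A).
#' @export
fuseRgba <- function(rgb, ir, depth, weights = c(0.5, 0.5)) {
  stopifnot(length(weights) == 2L, all(weights >= 0))
  hw <- .checkAligned(rgb, ir, depth)
  out <- array(0, c(hw, 4L))
  out[, , 1:3] <- rgb
  out[, , 4] <- weights[1] * ir + weights[2] * depth
  out
}

#' Depth/infrared channel stitching (method 3)
#'
#' Builds the three-channel D_IR_IR composite fed to the second stream of
#' the dual-stream model: channel 1 = depth, channels 2 and 3 = infrared.
#'
#' @param depth,ir H x W matrices in [0, 1].
#' @param order channel order; default \code{c("depth", "ir", "ir")}.
#' @return H x W x 3 array.
#' @export
makeDIrIr <- function(depth, ir, order = c("depth", "ir", "ir")) {
  if (!identical(dim(depth), dim(ir))) stop("depth and ir are not aligned")
  stopifnot(length(order) == 3L, all(order %in% c("depth", "ir")))
  out <- array(0, c(dim(depth), 3L))
  for (c in 1:3) out[, , c] <- if (order[c] == "depth") depth else ir
  out
}
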