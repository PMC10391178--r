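## Online augmentations for detection training. All operators take and
## return list(image =, boxes =) samples with normalized center-form boxes.

## EBImage stores images x-first; our arrays are (H, W, C).
.toEB <- function(x) {
  if (length(dim(x)) == 2L) t(x) else aperm(x, c(2, 1, 3))
}
.fromEB <- function(x) {
  if (length(dim(x)) == 2L) t(x) else aperm(x, c(2, 1, 3))
}

.resizeArray <- function(x, H, W) {
  eb <- EBImage::resize(.toEB(x), w = W, h = H)
  y <- .fromEB(EBImage::imageData(eb))
  pmin(pmax(y, 0), 1)
}

#' Horizontal flip
#' @param sample list(image, boxes).
#' @return flipped sample.
#' @export
augHFlip <- function(sample) {
  d <- dim(sample$image)
  sample$image <- sample$image[, d[2]:1, , drop = FALSE]
  if (nrow(sample$boxes)) sample$boxes$cx <- 1 - sample$boxes$cx
  sample
}

#' Random rotation (axis-aligned box envelope remapping)
#'
#' Rotates the image about its center by a uniform angle in
#' \code{[-maxDeg, maxDeg]} (nearest-neighbour resampling, background
#' filled with the grey pad value) and replaces each box by the envelope of
#' its rotated corners, clipped to the image; boxes reduced below 2 px a
#' side are dropped.
#'
#' @param sample list(image, boxes).
#' @param maxDeg maximum absolute rotation in degrees.
#' @param fill background fill value.
#' @return rotated sample.
#' @export
augRotate <- function(sample, maxDeg = 10, fill = 114 / 255) {
  ang <- stats::runif(1, -maxDeg, maxDeg)
  d <- dim(sample$image)
  H <- d[1]; W <- d[2]
  th <- ang * pi / 180
  cyc <- (H + 1) / 2; cxc <- (W + 1) / 2
  ## inverse nearest-neighbour map
  gx <- matrix(rep(seq_len(W), each = H), H, W)
  gy <- matrix(rep(seq_len(H), W), H, W)
  sx <- cxc + cos(th) * (gx - cxc) + sin(th) * (gy - cyc)
  sy <- cyc - sin(th) * (gx - cxc) + cos(th) * (gy - cyc)
  si <- round(sy); sj <- round(sx)
  ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
  out <- array(fill, d)
  for (c in seq_len(d[3])) {
    plane <- matrix(fill, H, W)
    src <- sample$image[, , c]
    plane[ok] <- src[cbind(si[ok], sj[ok])]
    out[, , c] <- plane
  }
  sample$image <- out
  b <- sample$boxes
  if (nrow(b)) {
    keep <- logical(nrow(b))
    for (i in seq_len(nrow(b))) {
      px <- (b$cx[i] + c(-1, 1, 1, -1) * b$w[i] / 2) * W
      py <- (b$cy[i] + c(-1, -1, 1, 1) * b$h[i] / 2) * H
      ## forward-rotate corners
      rx <- cxc + cos(th) * (px - cxc) - sin(th) * (py - cyc)
      ry <- cyc + sin(th) * (px - cxc) + cos(th) * (py - cyc)
      x1 <- max(min(rx), 0); x2 <- min(max(rx), W)
      y1 <- max(min(ry), 0); y2 <- min(max(ry), H)
      if (x2 - x1 >= 2 && y2 - y1 >= 2) {
        keep[i] <- TRUE
        b$cx[i] <- (x1 + x2) / 2 / W; b$cy[i] <- (y1 + y2) / 2 / H
        b$w[i] <- (x2 - x1) / W; b$h[i] <- (y2 - y1) / H
      }
    }
    sample$boxes <- b[keep, , drop = FALSE]
  }
  sample
}

#' Random color jitter
#'
#' Per-channel gain, global brightness and gamma perturbation, clamped to
#' [0, 1]; box geometry is untouched.
#'
#' @param sample list(image, boxes).
#' @param strength jitter strength in [0, 1].
#' @return jittered sample.
#' @export
augColor <- function(sample, strength = 0.2) {
  d <- dim(sample$image)
  gains <- stats::runif(d[3], 1 - strength, 1 + strength)
  bright <- stats::runif(1, -strength / 2, strength / 2)
  gamma <- exp(stats::runif(1, -strength, strength))
  x <- sweep(sample$image, 3, gains, "*") + bright
  sample$image <- pmin(pmax(x, 0), 1)^gamma
  sample
}

#' Mosaic of four samples
#'
#' Composes one training image from four source samples: a random split
#' point divides the canvas into four quadrants, each filled with a
#' same-sized crop of one source image; boxes are shifted into canvas
#' coordinates and clipped, dropping boxes reduced below 2 px a side.
#'
#' @param samples list of exactly 4 samples.
#' @return one composed sample; \code{$srcQuadrant} records which source
#'   filled each quadrant.
#' @export
augMosaic <- function(samples) {
  stopifnot(length(samples) == 4L)
  d <- dim(samples[[1]]$image)
  H <- d[1]; W <- d[2]; C <- d[3]
  py <- round(stats::runif(1, 0.3, 0.7) * H)
  px <- round(stats::runif(1, 0.3, 0.7) * W)
  canvas <- array(114 / 255, c(H, W, C))
  quads <- list(c(1, py, 1, px), c(1, py, px + 1, W),
                c(py + 1, H, 1, px), c(py + 1, H, px + 1, W))
  boxes <- list()
  for (q in 1:4) {
    qy <- quads[[q]][1]:quads[[q]][2]
    qx <- quads[[q]][3]:quads[[q]][4]
    qh <- length(qy); qw <- length(qx)
    s <- samples[[q]]
    sh <- dim(s$image)[1]; sw <- dim(s$image)[2]
    oy <- sample.int(max(sh - qh, 0) + 1L, 1L) - 1L
    ox <- sample.int(max(sw - qw, 0) + 1L, 1L) - 1L
    cy <- pmin(oy + seq_len(qh), sh); cx <- pmin(ox + seq_len(qw), sw)
    canvas[qy, qx, ] <- s$image[cy, cx, , drop = FALSE]
    b <- s$boxes
    if (nrow(b)) {
      ## source-pixel corners -> canvas pixels
      x1 <- (b$cx - b$w / 2) * sw - ox + qx[1] - 1
      x2 <- (b$cx + b$w / 2) * sw - ox + qx[1] - 1
      y1 <- (b$cy - b$h / 2) * sh - oy + qy[1] - 1
      y2 <- (b$cy + b$h / 2) * sh - oy + qy[1] - 1
      x1 <- pmax(x1, qx[1] - 1); x2 <- pmin(x2, qx[1] - 1 + qw)
      y1 <- pmax(y1, qy[1] - 1); y2 <- pmin(y2, qy[1] - 1 + qh)
      keep <- (x2 - x1) >= 2 & (y2 - y1) >= 2
      if (any(keep)) {
        boxes[[q]] <- data.frame(class = b$class[keep],
                                 cx = (x1 + x2)[keep] / 2 / W,
                                 cy = (y1 + y2)[keep] / 2 / H,
                                 w = (x2 - x1)[keep] / W,
                                 h = (y2 - y1)[keep] / H)
      }
    }
  }
  out <- list(image = canvas,
              boxes = if (length(boxes)) do.call(rbind, boxes) else
                data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                           w = numeric(0), h = numeric(0)))
  out$srcQuadrant <- seq_len(4L)
  out
}

#' Letterbox an image (and boxes) to a target size
#'
#' Aspect-preserving resize followed by symmetric grey padding.
#'
#' @param sample list(image, boxes).
#' @param newHW integer(2) target (H, W).
#' @param fill pad value.
#' @return letterboxed sample.
#' @export
letterbox <- function(sample, newHW, fill = 114 / 255) {
  d <- dim(sample$image)
  H <- d[1]; W <- d[2]
  r <- min(newHW[1] / H, newHW[2] / W)
  nh <- round(H * r); nw <- round(W * r)
  resized <- .resizeArray(sample$image, nh, nw)
  top <- (newHW[1] - nh) %/% 2L; left <- (newHW[2] - nw) %/% 2L
  out <- array(fill, c(newHW[1], newHW[2], d[3]))
  out[top + seq_len(nh), left + seq_len(nw), ] <- resized
  b <- sample$boxes
  if (nrow(b)) {
    b$cx <- (b$cx * W * r + left) / newHW[2]
    b$cy <- (b$cy * H * r + top) / newHW[1]
    b$w <- b$w * W * r / newHW[2]
    b$h <- b$h * H * r / newHW[1]
  }
  list(image = out, boxes = b)
}
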