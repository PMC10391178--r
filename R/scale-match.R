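## Object-based scale matching: align one dataset's object-scale
## distribution to a reference dataset's by cutting each over-scale object
## out of its image, resampling it by the dataset-level scale factor,
## pasting it back centered at the original position, and filling vacated
## pixels from adjacent context.

#' Relative scale of a box
#'
#' The geometric-mean side fraction \code{sqrt((w * h) / (W * H))}: 1 for a
#' full-image box, and homogeneous of degree one in the box size (scaling a
#' box by a multiplies its relative scale by exactly a).
#'
#' @param w,h box size in px (or normalized; then leave \code{imageHW} NULL).
#' @param imageHW integer(2) (H, W) when w, h are in px.
#' @return relative scale in (0, 1].
#' @examples
#' relativeScale(30, 30, c(360, 512))  # ~0.0699
#' @export
relativeScale <- function(w, h, imageHW = NULL) {
  if (any(w <= 0) || any(h <= 0)) stop("degenerate box: nonpositive size")
  if (is.null(imageHW)) sqrt(w * h)
  else sqrt((w * h) / (imageHW[1] * imageHW[2]))
}

#' Relative-scale summary of a dataset
#'
#' @param annotations list of \linkS4class{BoxAnnotationSet} objects, or of
#'   samples holding a normalized \code{boxes} data.frame.
#' @param binWidth histogram bin width on the relative-scale axis.
#' @return a \linkS4class{ScaleStats}.
#' @export
datasetScaleStats <- function(annotations, binWidth = 0.01) {
  scales <- .collectScales(annotations)
  if (!length(scales)) stop("no annotated objects in input")
  breaks <- seq(0, ceiling(max(scales) / binWidth) * binWidth + binWidth, by = binWidth)
  hg <- graphics::hist(scales, breaks = breaks, plot = FALSE)
  new("ScaleStats", s = mean(scales), histogram = as.numeric(hg$counts),
      breaks = hg$breaks, nObjects = length(scales))
}

.collectScales <- function(annotations) {
  unlist(lapply(annotations, function(a) {
    b <- if (is(a, "BoxAnnotationSet")) a@boxes else a$boxes
    if (is.null(b) || !nrow(b)) return(numeric(0))
    relativeScale(b$w, b$h)
  }))
}

setMethod("show", "ScaleStats", function(object) {
  cat(sprintf("<ScaleStats> %d objects, mean relative scale %.4f\n",
              object@nObjects, object@s))
})

## Nearest context pixel outside a (1-based, inclusive) rectangle, used to
## fill vacated pixels from the pre-edit image.
.nearestOutside <- function(y, x, y1, y2, x1, x2, H, W) {
  dTop <- y - (y1 - 1); dBot <- (y2 + 1) - y
  dLeft <- x - (x1 - 1); dRight <- (x2 + 1) - x
  cand <- rbind(
    c(y1 - 1, x, dTop), c(y2 + 1, x, dBot),
    c(y, x1 - 1, dLeft), c(y, x2 + 1, dRight))
  cand <- cand[cand[, 1] >= 1 & cand[, 1] <= H & cand[, 2] >= 1 & cand[, 2] <= W, ,
               drop = FALSE]
  if (!nrow(cand)) return(c(min(max(y, 1), H), min(max(x, 1), W)))
  cand[which.min(cand[, 3]), 1:2]
}

#' Cut, rescale and re-paste one object
#'
#' The pixel patch under the box is resampled by \code{factor} (bilinear)
#' and pasted back centered at the original box center. For factors below
#' one the vacated ring is filled with the nearest context pixel of the
#' pre-edit image outside the original box, so no pixel is left unassigned;
#' for factors above one the enlarged patch overwrites underlying pixels
#' and is clipped at the image bounds. A factor of one returns the input
#' unchanged. Factors that would shrink the patch below one pixel are
#' clamped with a warning.
#'
#' @param image (H, W, C) array or (H, W) matrix in [0, 1].
#' @param boxPx numeric(4): center-form box (cx, cy, w, h) in px.
#' @param factor scale factor > 0.
#' @return list(image =, boxPx =) with the updated image and box.
#' @export
rescaleObject <- function(image, boxPx, factor) {
  stopifnot(factor > 0)
  if (factor == 1) return(list(image = image, boxPx = boxPx))
  mat <- length(dim(image)) == 2L
  if (mat) dim(image) <- c(dim(image), 1L)
  H <- dim(image)[1]; W <- dim(image)[2]
  cx <- boxPx[1]; cy <- boxPx[2]; w <- boxPx[3]; h <- boxPx[4]
  x1 <- max(round(cx - w / 2) + 1L, 1L); x2 <- min(round(cx + w / 2), W)
  y1 <- max(round(cy - h / 2) + 1L, 1L); y2 <- min(round(cy + h / 2), H)
  if (x2 < x1 || y2 < y1) stop("box lies outside the image")
  patch <- image[y1:y2, x1:x2, , drop = FALSE]
  nw <- round((x2 - x1 + 1L) * factor); nh <- round((y2 - y1 + 1L) * factor)
  if (nw < 1L || nh < 1L) {
    warning("factor ", factor, " shrinks the object below 1 px; clamping")
    nw <- max(nw, 1L); nh <- max(nh, 1L)
  }
  resized <- .resizeArray(patch, nh, nw)
  if (length(dim(resized)) == 2L) dim(resized) <- c(nh, nw, 1L)
  ## paste centered at the original center, clip at bounds
  px1 <- round(cx - nw / 2) + 1L; py1 <- round(cy - nh / 2) + 1L
  sx1 <- max(1L, 1L - px1 + 1L); sy1 <- max(1L, 1L - py1 + 1L)
  dx1 <- max(px1, 1L); dy1 <- max(py1, 1L)
  dx2 <- min(px1 + nw - 1L, W); dy2 <- min(py1 + nh - 1L, H)
  out <- image
  if (factor < 1) {
    ## fill the vacated original footprint from adjacent context first
    pre <- image
    for (yy in y1:y2) for (xx in x1:x2) {
      src <- .nearestOutside(yy, xx, y1, y2, x1, x2, H, W)
      out[yy, xx, ] <- pre[src[1], src[2], ]
    }
  }
  if (dx2 >= dx1 && dy2 >= dy1)
    out[dy1:dy2, dx1:dx2, ] <- resized[sy1 + 0:(dy2 - dy1), sx1 + 0:(dx2 - dx1), , drop = FALSE]
  xlo <- max(cx - nw / 2, 0); xhi <- min(cx + nw / 2, W)
  ylo <- max(cy - nh / 2, 0); yhi <- min(cy + nh / 2, H)
  if (mat) dim(out) <- dim(out)[1:2]
  ## center preserved exactly unless the enlarged box was clipped at a bound
  list(image = out, boxPx = c((xlo + xhi) / 2, (ylo + yhi) / 2, xhi - xlo, yhi - ylo))
}

#' Match a dataset's object scales to a target mean scale
#'
#' Every object whose relative scale exceeds \code{judgeThreshold} is
#' rescaled by the single dataset-level factor
#' \code{a = targetS / sSource}, where \code{sSource} is the source
#' dataset's mean relative scale; annotations are rewritten accordingly.
#' Object counts and class labels are conserved; box centers are preserved
#' up to boundary clipping. Overlapping objects are processed in decreasing
#' area order so the smallest objects are re-pasted last.
#'
#' @param samples list of samples \code{list(image =, boxes =)} (normalized
#'   center-form box data.frames).
#' @param targetS reference dataset mean relative scale (e.g. from
#'   \code{\link{datasetScaleStats}} on the reference).
#' @param judgeThreshold objects above this relative scale are adjusted;
#'   defaults to \code{targetS}.
#' @return list with \code{samples} (adjusted), \code{factor}, \code{sSource}
#'   and \code{nAdjusted}.
#' @export
matchDataset <- function(samples, targetS, judgeThreshold = targetS) {
  if (!length(samples)) stop("empty dataset")
  sSource <- datasetScaleStats(samples)@s
  a <- targetS / sSource
  nAdj <- 0L
  out <- lapply(samples, function(s) {
    b <- s$boxes
    if (is.null(b) || !nrow(b)) return(s)
    H <- dim(s$image)[1]; W <- dim(s$image)[2]
    scl <- relativeScale(b$w, b$h)
    ord <- order(-(b$w * b$h))
    img <- s$image
    for (i in ord) {
      if (scl[i] <= judgeThreshold) next
      res <- rescaleObject(img, c(b$cx[i] * W, b$cy[i] * H, b$w[i] * W, b$h[i] * H), a)
      img <- res$image
      b$w[i] <- res$boxPx[3] / W
      b$h[i] <- res$boxPx[4] / H
      b$cx[i] <- res$boxPx[1] / W
      b$cy[i] <- res$boxPx[2] / H
      nAdj <<- nAdj + 1L
    }
    list(image = img, boxes = b)
  })
  list(samples = out, factor = a, sSource = sSource, nAdjusted = nAdj)
}
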