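## Detection decoding and evaluation: confidence decoding + non-maximum
## suppression, greedy confidence-ordered matching of detections to truths,
## precision / recall / average precision by all-point interpolation of the
## precision envelope, and dataset-level evaluation (mAP50, mAP95 under both
## the literal single-threshold and the averaged 0.50:0.95 conventions).

.boxIoU <- function(a, b) {
  ## a, b: matrices with columns x1, y1, x2, y2
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    iw <- pmin(a[i, 3], b[, 3]) - pmax(a[i, 1], b[, 1])
    ih <- pmin(a[i, 4], b[, 4]) - pmax(a[i, 2], b[, 2])
    inter <- pmax(iw, 0) * pmax(ih, 0)
    ua <- (a[i, 3] - a[i, 1]) * (a[i, 4] - a[i, 2]) +
      (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
    out[i, ] <- inter / pmax(ua, 1e-12)
  }
  out
}

#' Decode raw head outputs into scored boxes
#'
#' Applies the sigmoid decode (center offset in (-0.5, 1.5), width/height up
#' to 4x anchor), scales to pixels, thresholds on confidence and applies
#' greedy non-maximum suppression.
#'
#' @param predictions one image's predictions: list of three (h, w, 3*no)
#'   raw arrays.
#' @param config \linkS4class{ModelConfig}.
#' @param confThr confidence threshold (use a low value such as 0.001 when
#'   computing average precision; 0.25 for visualization).
#' @param nmsThr IoU threshold of non-maximum suppression.
#' @param maxDet cap on detections per image.
#' @return data.frame with columns x1, y1, x2, y2 (px), score, class.
#' @export
decodeDetections <- function(predictions, config, confThr = 0.001,
                             nmsThr = 0.45, maxDet = 1000L) {
  nc <- config@numClasses
  no <- nc + 5L
  strides <- c(8L, 16L, 32L)
  rows <- list()
  for (l in 1:3) {
    p <- predictions[[l]]
    gh <- dim(p)[1]; gw <- dim(p)[2]
    for (a in 1:3) {
      off <- (a - 1) * no
      zobj <- p[, , off + 5L]
      conf <- sigmoid(zobj)
      if (nc > 1) {
        clsP <- sigmoid(p[, , off + 5L + seq_len(nc), drop = FALSE])
        best <- apply(clsP, c(1, 2), which.max)
        conf <- conf * apply(clsP, c(1, 2), max)
      } else best <- matrix(0L, gh, gw)
      keep <- which(conf >= confThr, arr.ind = TRUE)
      if (!nrow(keep)) next
      aw <- config@anchors[a, 1, l]; ah <- config@anchors[a, 2, l]
      for (r in seq_len(nrow(keep))) {
        gj <- keep[r, 1]; gi <- keep[r, 2]
        z <- p[gj, gi, off + 1:4]
        s <- sigmoid(z)
        cx <- (s[1] * 2 - 0.5 + gi - 1) * strides[l]
        cy <- (s[2] * 2 - 0.5 + gj - 1) * strides[l]
        w <- (s[3] * 2)^2 * aw
        h <- (s[4] * 2)^2 * ah
        rows[[length(rows) + 1L]] <-
          c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2,
            conf[gj, gi], best[gj, gi])
      }
    }
  }
  if (!length(rows))
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), score = numeric(0), class = integer(0)))
  d <- as.data.frame(do.call(rbind, rows))
  names(d) <- c("x1", "y1", "x2", "y2", "score", "class")
  d <- d[order(-d$score), , drop = FALSE]
  if (nrow(d) > 30000L) d <- d[seq_len(30000L), , drop = FALSE]
  keep <- nmsKeep(as.matrix(d[, 1:4]), d$score, nmsThr)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) > maxDet) d <- d[seq_len(maxDet), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Greedy non-maximum suppression
#'
#' @param boxes matrix with columns x1, y1, x2, y2, ordered or unordered.
#' @param scores confidence scores.
#' @param iouThr suppression threshold.
#' @return integer indices of kept boxes, in decreasing score order.
#' @export
nmsKeep <- function(boxes, scores, iouThr = 0.45) {
  ord <- order(-scores)
  keep <- integer(0)
  alive <- rep(TRUE, length(ord))
  for (ii in seq_along(ord)) {
    if (!alive[ii]) next
    i <- ord[ii]
    keep <- c(keep, i)
    if (ii == length(ord)) break
    rest <- ord[(ii + 1):length(ord)]
    restAlive <- alive[(ii + 1):length(ord)]
    if (!any(restAlive)) next
    iou <- .boxIoU(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])[1, ]
    alive[(ii + 1):length(ord)] <- restAlive & (iou <= iouThr)
  }
  keep
}

#' Match detections to ground truths
#'
#' Greedy one-to-one matching in descending confidence order: each detection
#' claims the highest-IoU unmatched truth whose IoU reaches the threshold.
#'
#' @param detections data.frame with x1, y1, x2, y2, score.
#' @param truths matrix/data.frame with x1, y1, x2, y2.
#' @param iouThr matching threshold.
#' @return list with counts \code{tp}, \code{fp}, \code{fn}, the logical
#'   vector \code{isTP} over detections (confidence order) and
#'   \code{precision}, \code{recall} at these counts.
#' @export
matchDetections <- function(detections, truths, iouThr = 0.5) {
  nT <- if (is.null(truths)) 0L else nrow(truths)
  nD <- nrow(detections)
  isTP <- logical(nD)
  if (nD && nT) {
    ord <- order(-detections$score)
    used <- logical(nT)
    iou <- .boxIoU(as.matrix(detections[, c("x1", "y1", "x2", "y2")]),
                   as.matrix(truths[, c("x1", "y1", "x2", "y2"), drop = FALSE]))
    for (i in ord) {
      cand <- which(!used & iou[i, ] >= iouThr)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        used[j] <- TRUE
        isTP[i] <- TRUE
      }
    }
  }
  tp <- sum(isTP); fp <- nD - tp; fn <- nT - tp
  list(tp = tp, fp = fp, fn = fn, isTP = isTP,
       precision = if (nD) tp / nD else NA_real_,
       recall = if (nT) tp / nT else NA_real_)
}

#' Average precision from precision/recall samples
#'
#' All-point interpolation: the area under the monotone (non-increasing)
#' precision envelope as a function of recall.
#'
#' @param precision,recall numeric vectors of PR samples (recall ascending).
#' @return AP in [0, 1].
#' @examples
#' averagePrecision(c(1.0, 0.5), c(0.5, 1.0))  # 0.75
#' @export
averagePrecision <- function(precision, recall) {
  stopifnot(length(precision) == length(recall))
  if (!length(precision)) return(0)
  ord <- order(recall)
  r <- c(0, recall[ord], 1)
  p <- c(0, precision[ord], 0)
  ## precision envelope from the right
  for (i in rev(seq_len(length(p) - 1))) p[i] <- max(p[i], p[i + 1])
  sum(diff(r) * p[-1])
}

## PR curve + AP at one IoU threshold from scored per-image detections.
.apAtIoU <- function(dets, truths, iouThr) {
  nTot <- sum(vapply(truths, function(t) if (is.null(t)) 0L else nrow(t), integer(1)))
  flags <- list(); scores <- list()
  for (i in seq_along(dets)) {
    d <- dets[[i]]
    if (!nrow(d)) next
    m <- matchDetections(d, truths[[i]], iouThr)
    flags[[length(flags) + 1L]] <- m$isTP
    scores[[length(scores) + 1L]] <- d$score
  }
  if (!length(flags) || nTot == 0)
    return(list(ap = 0, precision = numeric(0), recall = numeric(0)))
  tpf <- unlist(flags); sc <- unlist(scores)
  ord <- order(-sc)
  tpc <- cumsum(tpf[ord]); fpc <- cumsum(!tpf[ord])
  prec <- tpc / (tpc + fpc)
  rec <- tpc / nTot
  list(ap = averagePrecision(prec, rec), precision = prec, recall = rec)
}

#' Evaluate a detector over a dataset
#'
#' Runs the model in inference mode over every sample, decodes and scores
#' detections and reports counts at the reporting confidence threshold plus
#' average-precision summaries. \code{map95} follows the averaged
#' IoU 0.50:0.05:0.95 convention; the literal single-threshold IoU = 0.95
#' value is also reported as \code{map95Literal} (for tiny objects it is
#' near zero by construction; see the vignette).
#'
#' @param model a \code{Detector}.
#' @param dataset list of samples, each \code{list(image =, boxes =)} with a
#'   normalized-coordinate box data.frame.
#' @param iouThr IoU used for the TP/FP/FN counts and mAP50.
#' @param confThr reporting threshold for the precision/recall counts.
#' @param nmsThr suppression threshold.
#' @return list: \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}, \code{map50}, \code{map95}, \code{map95Literal},
#'   \code{pr} (curve samples at \code{iouThr}).
#' @export
evaluateDetector <- function(model, dataset, iouThr = 0.5, confThr = 0.25,
                             nmsThr = 0.45) {
  nTot <- sum(vapply(dataset, function(s) nrow(s$boxes), integer(1)))
  if (nTot == 0) warning("dataset has no ground-truth objects; recall undefined")
  dets <- vector("list", length(dataset))
  truths <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    p <- detectorForward(model, list(s$image), training = FALSE)
    dets[[i]] <- decodeDetections(lapply(p, `[[`, 1L), model$config,
                                  confThr = 0.001, nmsThr = nmsThr)
    truths[[i]] <- .boxesToXYXY(s$boxes, dim(s$image)[1:2])
  }
  r50 <- .apAtIoU(dets, truths, iouThr)
  thrs <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thrs, function(t) .apAtIoU(dets, truths, t)$ap, numeric(1))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(dets)) {
    d <- dets[[i]][dets[[i]]$score >= confThr, , drop = FALSE]
    m <- matchDetections(d, truths[[i]], iouThr)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn) tp / (tp + fn) else NA_real_,
       map50 = r50$ap, map95 = mean(aps), map95Literal = aps[length(aps)],
       pr = list(precision = r50$precision, recall = r50$recall))
}

## normalized center-form data.frame -> pixel corner matrix
.boxesToXYXY <- function(boxes, hw) {
  if (is.null(boxes) || !nrow(boxes))
    return(matrix(numeric(0), 0, 4, dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  H <- hw[1]; W <- hw[2]
  cbind(x1 = (boxes$cx - boxes$w / 2) * W, y1 = (boxes$cy - boxes$h / 2) * H,
        x2 = (boxes$cx + boxes$w / 2) * W, y2 = (boxes$cy + boxes$h / 2) * H)
}
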