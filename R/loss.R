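## Detection loss: binary cross-entropy objectness (and classification when
## more than one class), complete-IoU box regression, v6.1-style anchor
## assignment (wh-ratio gate, centre cell plus two nearest neighbour cells).
## The breakdown L = L_confidence + L_classification + L_box holds exactly.

.lossDefaults <- function() list(
  box = 0.05, obj = 1.0, cls = 0.5,
  balance = c(4.0, 1.0, 0.4),   # per-level objectness weights (P3, P4, P5)
  anchorT = 4.0                 # wh-ratio matching gate
)

## Stable BCE-with-logits and its derivative wrt the logit.
.bceLogit <- function(z, t) pmax(z, 0) - z * t + log1p(exp(-abs(z)))
.bceLogitGrad <- function(z, t) sigmoid(z) - t

#' Complete IoU between two center-form boxes, with gradient
#'
#' Both boxes are (x, y, w, h) in any common unit. The aspect-ratio
#' trade-off coefficient is treated as a constant during differentiation
#' (the usual realization). The gradient is with respect to the first box.
#'
#' @param p,t numeric(4) center-form boxes (prediction, target).
#' @return list with \code{ciou} and \code{grad} (numeric(4)).
#' @export
ciouWithGrad <- function(p, t) {
  if (any(!is.finite(c(p, t))))
    return(list(ciou = NaN, grad = rep(NaN, 4), alpha = NaN))
  eps <- 1e-9
  x <- p[1]; y <- p[2]; w <- max(p[3], eps); h <- max(p[4], eps)
  tx <- t[1]; ty <- t[2]; tw <- max(t[3], eps); th <- max(t[4], eps)
  x1 <- x - w / 2; x2 <- x + w / 2; y1 <- y - h / 2; y2 <- y + h / 2
  tx1 <- tx - tw / 2; tx2 <- tx + tw / 2; ty1 <- ty - th / 2; ty2 <- ty + th / 2
  iw <- min(x2, tx2) - max(x1, tx1)
  ih <- min(y2, ty2) - max(y1, ty1)
  I <- max(iw, 0) * max(ih, 0)
  U <- w * h + tw * th - I + eps
  iou <- I / U
  cw <- max(x2, tx2) - min(x1, tx1)
  ch <- max(y2, ty2) - min(y1, ty1)
  c2 <- cw^2 + ch^2 + eps
  rho2 <- (x - tx)^2 + (y - ty)^2
  dAt <- atan(tw / th) - atan(w / h)
  v <- (4 / pi^2) * dAt^2
  alpha <- v / (1 - iou + v + eps)
  ciou <- iou - rho2 / c2 - alpha * v

  ## gradients
  dI <- numeric(4)
  if (iw > 0 && ih > 0) {
    diw_dx <- (x2 <= tx2) - (x1 >= tx1)
    diw_dw <- 0.5 * (x2 <= tx2) + 0.5 * (x1 >= tx1)
    dih_dy <- (y2 <= ty2) - (y1 >= ty1)
    dih_dh <- 0.5 * (y2 <= ty2) + 0.5 * (y1 >= ty1)
    dI <- c(ih * diw_dx, iw * dih_dy, ih * diw_dw, iw * dih_dh)
  }
  dU <- c(-dI[1], -dI[2], h - dI[3], w - dI[4])
  diou <- (dI * U - I * dU) / U^2
  dcw <- c((x2 > tx2) - (x1 < tx1), 0, 0.5 * (x2 > tx2) + 0.5 * (x1 < tx1), 0)
  dch <- c(0, (y2 > ty2) - (y1 < ty1), 0, 0.5 * (y2 > ty2) + 0.5 * (y1 < ty1))
  dc2 <- 2 * cw * dcw + 2 * ch * dch
  drho2 <- c(2 * (x - tx), 2 * (y - ty), 0, 0)
  dpen <- (drho2 * c2 - rho2 * dc2) / c2^2
  dv <- c(0, 0,
          (8 / pi^2) * dAt * (-h / (w^2 + h^2)),
          (8 / pi^2) * dAt * (w / (w^2 + h^2)))
  list(ciou = ciou, grad = diou - dpen - alpha * dv, alpha = alpha)
}

## Assign targets to (level, anchor, cell) triples. Returns one data.frame
## per level with 0-based cell indices and grid-unit target geometry.
.buildTargets <- function(targets, gridHW, anchorsGrid, anchorT) {
  nl <- length(gridHW)
  out <- vector("list", nl)
  for (l in seq_len(nl)) {
    gh <- gridHW[[l]][1]; gw <- gridHW[[l]][2]
    rows <- list()
    for (b in seq_along(targets)) {
      tb <- targets[[b]]
      if (is.null(tb) || !nrow(tb)) next
      gx <- tb$cx * gw; gy <- tb$cy * gh
      gwd <- tb$w * gw; ghd <- tb$h * gh
      for (a in 1:3) {
        aw <- anchorsGrid[[l]][a, 1]; ah <- anchorsGrid[[l]][a, 2]
        r1 <- gwd / aw; r2 <- ghd / ah
        ok <- pmax(r1, 1 / r1, r2, 1 / r2) < anchorT
        if (!any(ok)) next
        for (ti in which(ok)) {
          cells <- list(c(floor(gx[ti]), floor(gy[ti])))
          fx <- gx[ti] %% 1; fy <- gy[ti] %% 1
          if (fx < 0.5 && gx[ti] > 1) cells <- c(cells, list(c(floor(gx[ti]) - 1, floor(gy[ti]))))
          if (fx >= 0.5 && gx[ti] < gw - 1) cells <- c(cells, list(c(floor(gx[ti]) + 1, floor(gy[ti]))))
          if (fy < 0.5 && gy[ti] > 1) cells <- c(cells, list(c(floor(gx[ti]), floor(gy[ti]) - 1)))
          if (fy >= 0.5 && gy[ti] < gh - 1) cells <- c(cells, list(c(floor(gx[ti]), floor(gy[ti]) + 1)))
          for (cl in cells) {
            gi <- max(min(cl[1], gw - 1), 0); gj <- max(min(cl[2], gh - 1), 0)
            rows[[length(rows) + 1L]] <- c(b, a, gi, gj,
                                           gx[ti] - gi, gy[ti] - gj,
                                           gwd[ti], ghd[ti], tb$class[ti])
          }
        }
      }
    }
    out[[l]] <- if (length(rows))
      as.data.frame(do.call(rbind, rows)) else
      as.data.frame(matrix(numeric(0), 0, 9))
    names(out[[l]]) <- c("b", "a", "gi", "gj", "tx", "ty", "tw", "th", "cls")
  }
  out
}

#' Detection loss with exact additive breakdown
#'
#' Computes the total objective over a batch of raw head outputs: a
#' complete-IoU box regression term at assigned anchor/cell positions, a
#' binary cross-entropy confidence (objectness) term over every position
#' with IoU-valued soft targets at assignments, and a binary cross-entropy
#' classification term (identically zero for a single-class model). The
#' three weighted terms sum exactly to the total.
#'
#' @param predictions output of \code{\link{detectorForward}}: three levels
#'   of per-image raw prediction arrays.
#' @param targets list (batch) of data.frames with columns \code{class},
#'   \code{cx}, \code{cy}, \code{w}, \code{h} (normalized); \code{NULL} or
#'   zero-row frames mean no objects.
#' @param config the model's \linkS4class{ModelConfig} (anchors, classes).
#' @param inputHW integer(2), the (H, W) the images were fed at.
#' @param gains list overriding term gains / balances, see defaults in the
#'   vignette.
#' @param withGrad if TRUE, also returns \code{grad}: per-level, per-image
#'   gradient arrays of the total loss with respect to raw predictions.
#' @return list with \code{total}, \code{box}, \code{confidence},
#'   \code{classification}, \code{nMatched} and optionally \code{grad}.
#' @export
computeLoss <- function(predictions, targets, config, inputHW,
                        gains = list(), withGrad = FALSE) {
  g <- utils::modifyList(.lossDefaults(), gains)
  nc <- config@numClasses
  no <- nc + 5L
  strides <- c(8L, 16L, 32L)
  B <- length(predictions[[1]])
  gridHW <- lapply(predictions, function(lv) dim(lv[[1]])[1:2])
  anchorsGrid <- lapply(1:3, function(l) config@anchors[, , l] / strides[l])
  tl <- .buildTargets(targets, gridHW, anchorsGrid, g$anchorT)

  lbox <- 0; lobj <- 0; lcls <- 0; nMatchedTot <- 0L
  grad <- if (withGrad)
    lapply(predictions, function(lv) lapply(lv, function(a) array(0, dim(a)))) else NULL

  for (l in 1:3) {
    gh <- gridHW[[l]][1]; gw <- gridHW[[l]][2]
    numel <- gh * gw * 3 * B
    tobj <- lapply(seq_len(B), function(b) array(0, c(gh, gw, 3)))
    m <- tl[[l]]
    nM <- nrow(m)
    boxGrads <- NULL
    if (nM) {
      nMatchedTot <- nMatchedTot + nM
      cious <- numeric(nM)
      boxGrads <- vector("list", nM)
      for (r in seq_len(nM)) {
        b <- m$b[r]; a <- m$a[r]; gi <- m$gi[r]; gj <- m$gj[r]
        zi <- predictions[[l]][[b]][gj + 1, gi + 1, (a - 1) * no + 1:4]
        s <- sigmoid(zi)
        aw <- anchorsGrid[[l]][a, 1]; ah <- anchorsGrid[[l]][a, 2]
        pb <- c(s[1] * 2 - 0.5, s[2] * 2 - 0.5, (s[3] * 2)^2 * aw, (s[4] * 2)^2 * ah)
        cg <- ciouWithGrad(pb, c(m$tx[r], m$ty[r], m$tw[r], m$th[r]))
        cious[r] <- cg$ciou
        tobj[[b]][gj + 1, gi + 1, a] <- max(cg$ciou, 0)
        if (withGrad) {
          ## pxy = 2*sigmoid(z) - 0.5 ; pwh = (2*sigmoid(z))^2 * anchor
          dpdz <- c(2 * s[1] * (1 - s[1]), 2 * s[2] * (1 - s[2]),
                    8 * s[3] * aw * s[3] * (1 - s[3]),
                    8 * s[4] * ah * s[4] * (1 - s[4]))
          boxGrads[[r]] <- -cg$grad * dpdz   # d(1 - ciou)/dz
        }
      }
      lbox <- lbox + mean(1 - cious)
      if (withGrad) for (r in seq_len(nM)) {
        b <- m$b[r]; a <- m$a[r]; gi <- m$gi[r]; gj <- m$gj[r]
        idx <- (a - 1) * no + 1:4
        grad[[l]][[b]][gj + 1, gi + 1, idx] <-
          grad[[l]][[b]][gj + 1, gi + 1, idx] + g$box * boxGrads[[r]] / nM
      }
      if (nc > 1) {
        clsSum <- 0
        for (r in seq_len(nM)) {
          b <- m$b[r]; a <- m$a[r]; gi <- m$gi[r]; gj <- m$gj[r]
          zc <- predictions[[l]][[b]][gj + 1, gi + 1, (a - 1) * no + 5 + seq_len(nc)]
          tc <- as.numeric(seq_len(nc) == (m$cls[r] + 1))
          clsSum <- clsSum + sum(.bceLogit(zc, tc))
          if (withGrad) {
            idx <- (a - 1) * no + 5 + seq_len(nc)
            grad[[l]][[b]][gj + 1, gi + 1, idx] <-
              grad[[l]][[b]][gj + 1, gi + 1, idx] +
              g$cls * .bceLogitGrad(zc, tc) / (nM * nc)
          }
        }
        lcls <- lcls + clsSum / (nM * nc)
      }
    }
    objIdx <- rep((0:2) * no + 5L, each = 1L)
    lvlObj <- 0
    for (b in seq_len(B)) {
      zobj <- predictions[[l]][[b]][, , objIdx, drop = FALSE]
      lvlObj <- lvlObj + sum(.bceLogit(zobj, tobj[[b]]))
      if (withGrad)
        grad[[l]][[b]][, , objIdx] <- grad[[l]][[b]][, , objIdx] +
          g$obj * g$balance[l] * .bceLogitGrad(zobj, tobj[[b]]) / numel
    }
    lobj <- lobj + g$balance[l] * lvlObj / numel
  }

  out <- list(box = g$box * lbox, confidence = g$obj * lobj,
              classification = g$cls * lcls, nMatched = nMatchedTot)
  out$total <- out$box + out$confidence + out$classification
  if (withGrad) out$grad <- grad
  out
}
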