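## Independent oracles used across the suite. These deliberately avoid the
## package's own accounting/evaluation code paths.

## Enumerate learnable entries of a runtime-instantiated block by walking
## its actual parameter arrays (layer-by-layer enumeration oracle).
enumerateBlockParameters <- function(block, convention = "train") {
  e <- teadetect:::.newRuntimeBlock(block)
  lys <- teadetect:::.rtLayers(list(e))
  total <- 0
  for (ly in lys) {
    total <- total + length(ly$W)
    if (convention == "train") {
      if (ly$norm) total <- total + length(ly$g) + length(ly$be)
      if (ly$hasBias) total <- total + length(ly$b)
    } else {
      if (ly$norm || ly$hasBias) total <- total + ly$cOut
    }
  }
  total
}

## Exhaustive maximum-cardinality matching of detections to truths at an
## IoU threshold (for instances with <= 8 boxes).
bruteForceMaxMatches <- function(detBoxes, truthBoxes, iouThr) {
  nD <- nrow(detBoxes); nT <- nrow(truthBoxes)
  if (!nD || !nT) return(0L)
  iou <- teadetect:::.boxIoU(as.matrix(detBoxes), as.matrix(truthBoxes))
  best <- 0L
  recurse <- function(d, usedT, count) {
    if (count + (nD - d + 1L) <= best) return()
    if (d > nD) { best <<- max(best, count); return() }
    for (t in seq_len(nT)) {
      if (!usedT[t] && iou[d, t] >= iouThr) {
        usedT[t] <- TRUE
        recurse(d + 1L, usedT, count + 1L)
        usedT[t] <- FALSE
      }
    }
    recurse(d + 1L, usedT, count)
  }
  recurse(1L, logical(nT), 0L)
  best
}

## Independent COCO-style evaluator: own matching loop, 101-point
## interpolated average precision.
cocoStyleAP <- function(dets, truths, iouThr) {
  nTot <- sum(vapply(truths, nrow, integer(1)))
  scores <- c(); istp <- c()
  for (i in seq_along(dets)) {
    d <- dets[[i]]
    if (!nrow(d)) next
    tr <- truths[[i]]
    ord <- order(-d$score)
    taken <- logical(nrow(tr))
    flag <- logical(nrow(d))
    for (j in ord) {
      if (!nrow(tr)) break
      ious <- vapply(seq_len(nrow(tr)), function(t) {
        ix <- max(0, min(d$x2[j], tr[t, 3]) - max(d$x1[j], tr[t, 1]))
        iy <- max(0, min(d$y2[j], tr[t, 4]) - max(d$y1[j], tr[t, 2]))
        inter <- ix * iy
        inter / ((d$x2[j] - d$x1[j]) * (d$y2[j] - d$y1[j]) +
                   (tr[t, 3] - tr[t, 1]) * (tr[t, 4] - tr[t, 2]) - inter)
      }, numeric(1))
      ious[taken] <- -1
      t <- which.max(ious)
      if (length(t) && ious[t] >= iouThr) { taken[t] <- TRUE; flag[j] <- TRUE }
    }
    scores <- c(scores, d$score); istp <- c(istp, flag)
  }
  if (!length(scores) || nTot == 0) return(0)
  ord <- order(-scores)
  tp <- cumsum(istp[ord]); fp <- cumsum(!istp[ord])
  prec <- tp / (tp + fp); rec <- tp / nTot
  ## 101-point interpolation
  mean(vapply(seq(0, 1, by = 0.01), function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1)))
}

## Small aligned scene for fast tests.
tinySceneConfig <- function(...) {
  sceneConfig(imageSize = c(96, 128), countRange = c(15, 25), ...)
}

## Small letterboxed training set from synthetic scenes.
makeTrainSet <- function(n, meanScale = 0.07, imgpx = 96, seedBase = 0) {
  lapply(seq_len(n), function(i) {
    g <- generateScene(sceneConfig(imageSize = c(192, 192),
                                   countRange = c(12, 20),
                                   meanScale = meanScale),
                       seed = seedBase + i)
    letterbox(list(image = g$triplet@rgb, boxes = annBoxes(g$annotations)),
              c(imgpx, imgpx))
  })
}
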