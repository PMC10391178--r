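## Runtime detector: instantiates the blueprint of a ModelConfig as mutable
## layer environments and executes forward/backward over the node DAG.

.newRuntimeBlock <- function(block) {
  e <- new.env(parent = emptyenv())
  e$kind <- block$kind
  e$block <- block
  mkconv <- function(a, act = TRUE)
    newConvLayer(a$cIn, a$cOut, a$k, a$s, norm = a$norm, act = act, bias = a$bias)
  atoms <- block$layers
  if (block$kind %in% c("ConvBNAct", "Focus")) {
    e$conv <- mkconv(atoms[[1]])
  } else if (block$kind %in% c("CSP1_n", "CSP2", "C3_DSConv")) {
    e$shortcut <- block$kind == "CSP1_n"
    e$cv1 <- mkconv(atoms[[1]]); e$cv2 <- mkconv(atoms[[2]])
    e$n <- block$n
    e$b1 <- list(); e$b2 <- list()
    for (i in seq_len(block$n)) {
      e$b1[[i]] <- mkconv(atoms[[2 + 2 * i - 1]])
      e$b2[[i]] <- mkconv(atoms[[2 + 2 * i]])
    }
    e$cv3 <- mkconv(atoms[[length(atoms)]])
  } else if (block$kind %in% c("SPP", "SPPF")) {
    e$cv1 <- mkconv(atoms[[1]])
    e$poolK <- vapply(Filter(function(a) a$op == "pool", atoms), `[[`, integer(1), "k")
    e$serial <- block$kind == "SPPF"
    e$cv2 <- mkconv(atoms[[length(atoms)]])
  } else if (block$kind == "Detect") {
    e$conv <- mkconv(atoms[[1]], act = FALSE)
  }
  e
}

.rtLayers <- function(rt) {
  out <- list()
  for (e in rt) {
    for (nm in c("conv", "cv1", "cv2", "cv3"))
      if (!is.null(e[[nm]])) out <- c(out, list(e[[nm]]))
    if (!is.null(e$b1)) out <- c(out, e$b1, e$b2)
  }
  out
}

#' Build a runtime detector from a configuration
#'
#' Instantiates every block of the blueprint with freshly initialized
#' weights (He-scaled convolution kernels, unit-scale normalization). The
#' forward contract maps an (inChannels, H, W) image to three detection maps
#' at strides 8/16/32, each with 3 * (numClasses + 5) channels. Seed the R
#' random number generator before calling for reproducible initialization.
#'
#' @param config a \linkS4class{ModelConfig} (see \code{\link{modelPreset}}).
#' @return an object of class \code{Detector}.
#' @examples
#' set.seed(1)
#' m <- buildDetector(modelPreset("baseline", imgSize = 64))
#' p <- detectorForward(m, list(array(0, c(64, 64, 3))))
#' vapply(p, function(lv) dim(lv[[1]])[1], numeric(1))  # 8 4 2
#' @export
buildDetector <- function(config) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  nodes <- buildBlueprint(config)
  rt <- lapply(nodes, function(nd) .newRuntimeBlock(nd$block))
  headIds <- which(vapply(nodes, function(nd) nd$role == "head", logical(1)))
  strides <- vapply(nodes[headIds], `[[`, integer(1), "stride")
  m <- structure(list(config = config, nodes = nodes, rt = rt,
                      headIds = headIds, strides = strides),
                 class = "Detector")
  .initDetectBias(m)
  m
}

## Prior-aware detection head bias: start objectness near the expected
## object frequency so early training is stable.
.initDetectBias <- function(model) {
  nc <- model$config@numClasses
  no <- nc + 5L
  img <- model$config@imgSize
  for (i in seq_along(model$headIds)) {
    ly <- model$rt[[model$headIds[i]]]$conv
    b <- ly$b
    for (a in 0:2) {
      b[a * no + 5L] <- log(8 / (img / model$strides[i])^2)
      if (nc > 1) b[a * no + 5L + seq_len(nc)] <- log(0.6 / (nc - 0.99))
      else b[a * no + 6L] <- 0
    }
    ly$b <- b
  }
  invisible(model)
}

.blockForward <- function(e, ins, training) {
  switch(e$kind,
    ConvBNAct = convLayerForward(e$conv, ins, training),
    Focus = {
      if (training) e$c_inDims <- lapply(ins, dim)
      convLayerForward(e$conv, lapply(ins, focusSlice), training)
    },
    CSP1_n = , CSP2 = , C3_DSConv = {
      a <- convLayerForward(e$cv1, ins, training)
      bb <- convLayerForward(e$cv2, ins, training)
      z <- a
      if (training) e$c_zs <- vector("list", e$n)
      for (i in seq_len(e$n)) {
        if (training) e$c_zs[[i]] <- z
        z1 <- convLayerForward(e$b1[[i]], z, training)
        z2 <- convLayerForward(e$b2[[i]], z1, training)
        z <- if (e$shortcut) Map(`+`, z, z2) else z2
      }
      convLayerForward(e$cv3, Map(catChannels, z, bb), training)
    },
    SPP = , SPPF = {
      cc <- convLayerForward(e$cv1, ins, training)
      pools <- vector("list", length(e$poolK))
      if (training) e$c_amax <- vector("list", length(e$poolK))
      src <- cc
      for (j in seq_along(e$poolK)) {
        res <- lapply(if (e$serial) src else cc, .c_maxpool, k = e$poolK[j])
        pools[[j]] <- lapply(res, `[[`, "y")
        if (training) e$c_amax[[j]] <- lapply(res, `[[`, "argmax")
        if (e$serial) src <- pools[[j]]
      }
      cat4 <- Map(function(...) catChannels(...), cc,
                  pools[[1]], pools[[2]], pools[[3]])
      convLayerForward(e$cv2, cat4, training)
    },
    Detect = convLayerForward(e$conv, ins, training),
    Upsample = lapply(ins, .c_upsample2),
    Concat = ins,     # handled by the executor (multi-input)
    Add = ins,
    stop("unknown block kind ", e$kind))
}

.blockBackward <- function(e, dys) {
  switch(e$kind,
    ConvBNAct = convLayerBackward(e$conv, dys),
    Focus = {
      dsl <- convLayerBackward(e$conv, dys)
      Map(focusSliceBackward, dsl, e$c_inDims)
    },
    CSP1_n = , CSP2 = , C3_DSConv = {
      chZ <- e$cv3$cIn %/% 2L
      dcat <- convLayerBackward(e$cv3, dys)
      dz <- lapply(dcat, function(d) d[, , seq_len(chZ), drop = FALSE])
      dbb <- lapply(dcat, function(d) d[, , chZ + seq_len(dim(d)[3] - chZ), drop = FALSE])
      for (i in rev(seq_len(e$n))) {
        dz1 <- convLayerBackward(e$b2[[i]], dz)
        dz0 <- convLayerBackward(e$b1[[i]], dz1)
        dz <- if (e$shortcut) Map(`+`, dz, dz0) else dz0
      }
      dx1 <- convLayerBackward(e$cv1, dz)
      dx2 <- convLayerBackward(e$cv2, dbb)
      Map(`+`, dx1, dx2)
    },
    SPP = , SPPF = {
      ch <- e$cv1$cOut
      dcat <- convLayerBackward(e$cv2, dys)
      parts <- lapply(dcat, function(d) splitChannels(d, rep(ch, 4L)))
      dcc <- lapply(parts, `[[`, 1L)
      dpool <- lapply(1:3, function(j) lapply(parts, `[[`, j + 1L))
      if (e$serial) {
        dcur <- dpool[[3]]
        for (j in 3:1) {
          dprev <- Map(.c_maxpool_bwd, dcur, e$c_amax[[j]])
          dcur <- if (j > 1) Map(`+`, dpool[[j - 1]], dprev) else dprev
        }
        dcc <- Map(`+`, dcc, dcur)
      } else {
        for (j in 1:3)
          dcc <- Map(`+`, dcc, Map(.c_maxpool_bwd, dpool[[j]], e$c_amax[[j]]))
      }
      convLayerBackward(e$cv1, dcc)
    },
    Detect = convLayerBackward(e$conv, dys),
    Upsample = lapply(dys, .c_upsample2_bwd),
    stop("no backward for block kind ", e$kind))
}

#' Run the detector forward
#'
#' @param model a \code{Detector}.
#' @param xs batch: list of (H, W, inChannels) arrays in [0, 1]; H and W
#'   must be divisible by 32.
#' @param training logical; in training mode batch statistics are used for
#'   normalization and caches are retained for \code{detectorBackward}.
#' @return list of three detection levels (strides 8, 16, 32), each a list
#'   over the batch of (H/stride, W/stride, 3 * (numClasses + 5)) arrays of
#'   raw (pre-sigmoid) predictions.
#' @export
detectorForward <- function(model, xs, training = FALSE) {
  stopifnot(is.list(xs))
  for (x in xs) {
    d <- dim(x)
    if (d[1] %% 32L || d[2] %% 32L) stop("input spatial size must be divisible by 32")
    if (d[3] != model$config@inChannels)
      stop("input has ", d[3], " channels; model expects ", model$config@inChannels)
  }
  outs <- vector("list", length(model$nodes))
  for (nd in model$nodes) {
    e <- model$rt[[nd$id]]
    if (nd$block$kind %in% c("Concat", "Add")) {
      srcs <- lapply(nd$from, function(f) if (f == 0L) xs else outs[[f]])
      outs[[nd$id]] <- if (nd$block$kind == "Concat")
        do.call(Map, c(list(catChannels), srcs))
      else Reduce(function(u, v) Map(`+`, u, v), srcs)
      if (training) e$c_chs <- vapply(srcs, function(s) dim(s[[1]])[3], integer(1))
    } else {
      ins <- if (nd$from[1] == 0L) xs else outs[[nd$from[1]]]
      outs[[nd$id]] <- .blockForward(e, ins, training)
    }
  }
  outs[model$headIds]
}

#' Backpropagate head gradients through the detector
#'
#' Accumulates parameter gradients in every layer (call
#' \code{\link{detectorZeroGrad}} between steps) and returns the gradient
#' with respect to the input batch.
#'
#' @param model a \code{Detector} after a \code{detectorForward} call with
#'   \code{training = TRUE}.
#' @param dHeads list of three levels of per-image gradient arrays matching
#'   the forward output shapes.
#' @return list of input-gradient arrays.
#' @export
detectorBackward <- function(model, dHeads) {
  nnod <- length(model$nodes)
  gacc <- vector("list", nnod)
  dxs <- NULL
  for (i in seq_along(model$headIds)) gacc[[model$headIds[i]]] <- dHeads[[i]]
  for (id in rev(seq_len(nnod))) {
    if (is.null(gacc[[id]])) next
    nd <- model$nodes[[id]]
    e <- model$rt[[id]]
    if (nd$block$kind == "Concat") {
      splits <- lapply(gacc[[id]], splitChannels, sizes = e$c_chs)
      for (j in seq_along(nd$from)) {
        f <- nd$from[j]
        dpart <- lapply(splits, `[[`, j)
        if (f == 0L) dxs <- if (is.null(dxs)) dpart else Map(`+`, dxs, dpart)
        else gacc[[f]] <- if (is.null(gacc[[f]])) dpart else Map(`+`, gacc[[f]], dpart)
      }
    } else if (nd$block$kind == "Add") {
      for (f in nd$from) {
        if (f == 0L) dxs <- if (is.null(dxs)) gacc[[id]] else Map(`+`, dxs, gacc[[id]])
        else gacc[[f]] <- if (is.null(gacc[[f]])) gacc[[id]] else Map(`+`, gacc[[f]], gacc[[id]])
      }
    } else {
      din <- .blockBackward(e, gacc[[id]])
      f <- nd$from[1]
      if (f == 0L) dxs <- if (is.null(dxs)) din else Map(`+`, dxs, din)
      else gacc[[f]] <- if (is.null(gacc[[f]])) din else Map(`+`, gacc[[f]], din)
    }
    gacc[[id]] <- NULL
  }
  dxs
}

#' @rdname detectorZeroGrad
#' @export
detectorLayers <- function(model) .rtLayers(model$rt)

#' Reset accumulated gradients and caches
#'
#' @param model a \code{Detector}.
#' @return the model, invisibly.
#' @export
detectorZeroGrad <- function(model) {
  for (ly in detectorLayers(model)) layerZeroGrad(ly)
  invisible(model)
}

#' Extract or restore all learnable state
#'
#' \code{detectorWeights} returns a nested list of every parameter array
#' (including normalization running statistics); \code{setDetectorWeights}
#' restores it, checking shape compatibility layer by layer, so a checkpoint
#' from a mismatched architecture (e.g. a 3-channel stem into a 4-channel
#' model) is rejected with an explicit error.
#'
#' @param model a \code{Detector}.
#' @param weights a list previously returned by \code{detectorWeights}.
#' @return \code{detectorWeights}: a list; \code{setDetectorWeights}: the
#'   model, invisibly.
#' @export
detectorWeights <- function(model) {
  lapply(detectorLayers(model), function(ly) {
    out <- lapply(.layerParamNames(ly), function(nm) ly[[nm]])
    names(out) <- .layerParamNames(ly)
    out
  })
}

#' @rdname detectorWeights
#' @export
setDetectorWeights <- function(model, weights) {
  lys <- detectorLayers(model)
  if (length(lys) != length(weights))
    stop("checkpoint has ", length(weights), " layers; model has ", length(lys))
  for (i in seq_along(lys)) {
    for (nm in names(weights[[i]])) {
      cur <- lys[[i]][[nm]]
      new <- weights[[i]][[nm]]
      if (!identical(dim(cur), dim(new)) || length(cur) != length(new))
        stop("shape mismatch restoring layer ", i, " parameter '", nm, "'")
      lys[[i]][[nm]] <- new
    }
  }
  invisible(model)
}

#' Save / load a checkpoint with its embedded configuration
#'
#' @param model a \code{Detector}.
#' @param path file path.
#' @return \code{loadCheckpoint} returns a rebuilt \code{Detector}.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(config = model$config, weights = detectorWeights(model)), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  m <- buildDetector(ck$config)
  setDetectorWeights(m, ck$weights)
  m
}

#' @export
print.Detector <- function(x, ...) {
  s <- modelSummary(x$config)
  cat(sprintf("<Detector> %s stem, stages %s, %s neck | %s parameters\n",
              x$config@stem, paste(x$config@stageRepeats, collapse = ","),
              x$config@neck, format(s$parameters, big.mark = ",")))
  invisible(x)
}
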