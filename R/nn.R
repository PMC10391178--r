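## Minimal CPU runtime for the detector family: convolution via im2col + GEMM
## (compiled patch extraction, BLAS multiply), batch normalization, SiLU,
## max pooling, nearest upsampling, space-to-depth slicing. Every layer
## supports an exact backward pass; batches are lists of (H, W, C) arrays.

sigmoid <- function(x) 1 / (1 + exp(-x))

.silu <- function(x) x * sigmoid(x)
.siluGrad <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }

.autoPad <- function(k) if (k %% 2L == 1L) (k - 1L) %/% 2L else k %/% 2L - 1L

## A convolution layer (optionally normalized and activated) as a mutable
## environment. Weights are (k*k*cIn) x cOut matrices in im2col column order.
newConvLayer <- function(cIn, cOut, k = 1L, s = 1L, norm = TRUE, act = TRUE,
                         bias = !norm) {
  e <- new.env(parent = emptyenv())
  e$cIn <- cIn; e$cOut <- cOut; e$k <- as.integer(k); e$s <- as.integer(s)
  e$p <- .autoPad(as.integer(k)); e$norm <- norm; e$act <- act; e$hasBias <- bias
  fan <- k * k * cIn
  e$W <- matrix(stats::rnorm(fan * cOut, sd = sqrt(2 / fan)), fan, cOut)
  e$b <- if (bias) numeric(cOut) else NULL
  if (norm) {
    e$g <- rep(1, cOut); e$be <- numeric(cOut)
    e$rm <- numeric(cOut); e$rv <- rep(1, cOut)
  }
  e$eps <- 1e-5; e$momentum <- 0.1
  e
}

## Forward over a batch (list of (H,W,C) arrays). In training mode caches
## what the backward pass needs.
convLayerForward <- function(ly, xs, training = FALSE) {
  B <- length(xs)
  ps <- vector("list", B); zs <- vector("list", B); dims <- vector("list", B)
  for (i in seq_len(B)) {
    x <- xs[[i]]
    P <- .c_im2col(x, ly$k, ly$s, ly$p)
    Z <- P %*% ly$W
    if (ly$hasBias) Z <- sweep(Z, 2, ly$b, "+")
    d <- dim(x)
    ho <- (d[1] + 2 * ly$p - ly$k) %/% ly$s + 1
    wo <- (d[2] + 2 * ly$p - ly$k) %/% ly$s + 1
    ps[[i]] <- P; zs[[i]] <- Z; dims[[i]] <- c(d, ho, wo)
  }
  if (ly$norm) {
    n <- sum(vapply(zs, nrow, numeric(1)))
    if (training) {
      mu <- Reduce(`+`, lapply(zs, colSums)) / n
      va <- Reduce(`+`, lapply(zs, function(z) colSums(sweep(z, 2, mu)^2))) / n
      ly$rm <- (1 - ly$momentum) * ly$rm + ly$momentum * mu
      ly$rv <- (1 - ly$momentum) * ly$rv + ly$momentum * va * n / max(n - 1, 1)
    } else {
      mu <- ly$rm; va <- ly$rv
    }
    sd_ <- sqrt(va + ly$eps)
    xh <- lapply(zs, function(z) sweep(sweep(z, 2, mu), 2, sd_, "/"))
    out <- lapply(xh, function(h) sweep(sweep(h, 2, ly$g, "*"), 2, ly$be, "+"))
    if (training) { ly$c_mu <- mu; ly$c_sd <- sd_; ly$c_xh <- xh; ly$c_n <- n }
  } else out <- zs
  if (ly$act) {
    if (training) ly$c_pre <- out
    out <- lapply(out, .silu)
  }
  if (training) { ly$c_P <- ps; ly$c_dims <- dims }
  lapply(seq_len(B), function(i) {
    d <- dims[[i]]
    array(out[[i]], c(d[4], d[5], ly$cOut))
  })
}

## Backward over a batch; accumulates parameter gradients into the layer and
## returns input gradients.
convLayerBackward <- function(ly, dys) {
  B <- length(dys)
  dzs <- lapply(seq_len(B), function(i) {
    d <- ly$c_dims[[i]]
    matrix(dys[[i]], d[4] * d[5], ly$cOut)
  })
  if (ly$act) {
    dzs <- lapply(seq_len(B), function(i) dzs[[i]] * .siluGrad(ly$c_pre[[i]]))
  }
  if (ly$norm) {
    ## dz = (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) / sd,
    ## dxhat = dy * gamma, means taken over all batch elements per channel.
    n <- ly$c_n; g <- ly$g; sd_ <- ly$c_sd
    dg <- Reduce(`+`, lapply(seq_len(B), function(i) colSums(dzs[[i]] * ly$c_xh[[i]])))
    dbe <- Reduce(`+`, lapply(dzs, colSums))
    ly$d_g <- (if (is.null(ly$d_g)) 0 else ly$d_g) + dg
    ly$d_be <- (if (is.null(ly$d_be)) 0 else ly$d_be) + dbe
    m1 <- g * dbe / n   # mean(dxhat) * g-scaled
    m2 <- g * dg / n    # mean(dxhat * xhat) * g-scaled
    dzs <- lapply(seq_len(B), function(i) {
      dxh <- sweep(dzs[[i]], 2, g, "*")
      dxh <- sweep(dxh, 2, m1, "-")
      dxh <- dxh - sweep(ly$c_xh[[i]], 2, m2, "*")
      sweep(dxh, 2, sd_, "/")
    })
  }
  dW <- 0
  dxs <- vector("list", B)
  for (i in seq_len(B)) {
    dW <- dW + crossprod(ly$c_P[[i]], dzs[[i]])
    dP <- tcrossprod(dzs[[i]], ly$W)
    d <- ly$c_dims[[i]]
    dxs[[i]] <- .c_col2im(dP, d[1], d[2], d[3], ly$k, ly$s, ly$p)
  }
  ly$d_W <- (if (is.null(ly$d_W)) 0 else ly$d_W) + dW
  if (ly$hasBias)
    ly$d_b <- (if (is.null(ly$d_b)) 0 else ly$d_b) + Reduce(`+`, lapply(dzs, colSums))
  dxs
}

## Space-to-depth slice of the Focus stem: 2x2 neighbourhoods to channels.
## Odd spatial sizes are rejected (deterministic shape contract).
focusSlice <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L)
    stop("Focus stem requires even spatial dimensions, got ", d[1], "x", d[2])
  oy <- seq(1L, d[1], 2L); ey <- seq(2L, d[1], 2L)
  ox <- seq(1L, d[2], 2L); ex <- seq(2L, d[2], 2L)
  out <- array(0, c(d[1] / 2, d[2] / 2, 4 * d[3]))
  out[, , seq_len(d[3])] <- x[oy, ox, , drop = FALSE]
  out[, , d[3] + seq_len(d[3])] <- x[ey, ox, , drop = FALSE]
  out[, , 2 * d[3] + seq_len(d[3])] <- x[oy, ex, , drop = FALSE]
  out[, , 3 * d[3] + seq_len(d[3])] <- x[ey, ex, , drop = FALSE]
  out
}

focusSliceBackward <- function(dy, inDim) {
  C <- inDim[3]
  dx <- array(0, inDim)
  oy <- seq(1L, inDim[1], 2L); ey <- seq(2L, inDim[1], 2L)
  ox <- seq(1L, inDim[2], 2L); ex <- seq(2L, inDim[2], 2L)
  dx[oy, ox, ] <- dy[, , seq_len(C), drop = FALSE]
  dx[ey, ox, ] <- dy[, , C + seq_len(C), drop = FALSE]
  dx[oy, ex, ] <- dy[, , 2 * C + seq_len(C), drop = FALSE]
  dx[ey, ex, ] <- dy[, , 3 * C + seq_len(C), drop = FALSE]
  dx
}

catChannels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(cs)))
  at <- 0L
  for (x in xs) { cc <- dim(x)[3]; out[, , at + seq_len(cc)] <- x; at <- at + cc }
  out
}

splitChannels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(cc) { y <- x[, , at + seq_len(cc), drop = FALSE]; at <<- at + cc; y })
}

## Parameter bookkeeping shared by the optimizer and checkpoints.
.layerParamNames <- function(ly) {
  nm <- "W"
  if (ly$hasBias) nm <- c(nm, "b")
  if (ly$norm) nm <- c(nm, "g", "be", "rm", "rv")
  nm
}

layerZeroGrad <- function(ly) {
  ly$d_W <- NULL; ly$d_b <- NULL; ly$d_g <- NULL; ly$d_be <- NULL
  ly$c_P <- NULL; ly$c_dims <- NULL; ly$c_pre <- NULL; ly$c_xh <- NULL
  invisible(ly)
}
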