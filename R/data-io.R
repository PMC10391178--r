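## Aligned-triplet and annotation input/output: PNG (8-bit) and TIFF
## (16-bit infrared) images, COCO-style JSON and YOLO-style text labels,
## field-of-view cropping with label re-projection and small-box filtering.
##
## Conventions: pixel coordinates are 0-based with half-open boxes
## [x, x + w); normalized coordinates divide by image width/height.

#' Construct an annotation set
#'
#' @param boxes data.frame with columns class, cx, cy, w, h (normalized
#'   center form).
#' @param imageSize integer(2), (H, W).
#' @param imageId identifier.
#' @return a \linkS4class{BoxAnnotationSet}.
#' @export
boxAnnotationSet <- function(boxes, imageSize, imageId = "") {
  new("BoxAnnotationSet",
      boxes = as.data.frame(boxes)[, c("class", "cx", "cy", "w", "h")],
      imageId = as.character(imageId), imageSize = as.integer(imageSize))
}

#' @rdname boxAnnotationSet
#' @param object a \code{BoxAnnotationSet}.
#' @export
setMethod("show", "BoxAnnotationSet", function(object) {
  cat(sprintf("<BoxAnnotationSet> %d objects on %dx%d image '%s'\n",
              nrow(object@boxes), object@imageSize[1], object@imageSize[2],
              object@imageId))
})

#' Accessors for annotation sets
#' @param x a \code{BoxAnnotationSet}.
#' @return \code{annBoxes}: the normalized box data.frame; \code{annImageSize}:
#'   integer(2) (H, W).
#' @export
annBoxes <- function(x) x@boxes

#' @rdname annBoxes
#' @export
annImageSize <- function(x) x@imageSize

.readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: ", ext)
}

.writeImageFile <- function(x, path, bits = 8L) {
  ext <- tolower(tools::file_ext(path))
  x <- pmin(pmax(x, 0), 1)
  ## quantize to the declared code values so the round trip is exact
  x <- round(x * (2^bits - 1)) / (2^bits - 1)
  if (ext == "png") {
    if (bits != 8L) stop("PNG output is written at 8 bits; use TIFF for 16")
    png::writePNG(x, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Load one aligned modality triplet
#'
#' Reads the three modality images, checks spatial alignment and bit-depth
#' plausibility, and returns a \linkS4class{ModalityTriplet} with values in
#' [0, 1] and declared bit depths (RGB 8/channel, infrared 16, depth 8).
#' A mismatching modality is named in the error. With \code{strict = FALSE}
#' an 8-bit file supplied for the infrared slot is promoted losslessly
#' instead of rejected.
#'
#' @param rgbPath,irPath,depthPath image files (PNG; TIFF for 16-bit IR).
#' @param frameId frame identifier (defaults to the RGB file stem).
#' @param strict reject (TRUE) or promote (FALSE) an 8-bit infrared file.
#' @return a \linkS4class{ModalityTriplet}.
#' @export
loadTriplet <- function(rgbPath, irPath, depthPath,
                        frameId = tools::file_path_sans_ext(basename(rgbPath)),
                        strict = TRUE) {
  rgb <- .readImageFile(rgbPath)
  ir <- .readImageFile(irPath)
  depth <- .readImageFile(depthPath)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("modality 'rgb': expected a 3-channel image in ", rgbPath)
  rgb <- rgb[, , 1:3, drop = FALSE]
  if (length(dim(ir)) == 3L) ir <- ir[, , 1]
  if (length(dim(depth)) == 3L) depth <- depth[, , 1]
  hw <- dim(rgb)[1:2]
  if (!identical(dim(ir), hw))
    stop("modality 'ir': size ", paste(dim(ir), collapse = "x"),
         " does not match rgb ", paste(hw, collapse = "x"))
  if (!identical(dim(depth), hw))
    stop("modality 'depth': size ", paste(dim(depth), collapse = "x"),
         " does not match rgb ", paste(hw, collapse = "x"))
  irBits <- if (tolower(tools::file_ext(irPath)) %in% c("tif", "tiff")) 16L else 8L
  if (irBits == 8L) {
    if (strict) stop("modality 'ir': expected a 16-bit source, got an 8-bit file; ",
                     "use strict = FALSE to promote losslessly")
    irBits <- 16L   # values already in [0, 1]; promotion is the identity
  }
  new("ModalityTriplet", rgb = rgb, ir = ir, depth = depth,
      bitDepths = c(rgb = 8L, ir = irBits, depth = 8L),
      frameId = frameId, aligned = TRUE)
}

#' Write a modality triplet
#'
#' RGB and depth are written as 8-bit PNG, infrared as 16-bit TIFF
#' (lossless for the 16-bit source scale).
#'
#' @param triplet a \linkS4class{ModalityTriplet}.
#' @param dir output directory.
#' @param stem file stem; writes \code{<stem>_rgb.png}, \code{<stem>_ir.tif},
#'   \code{<stem>_depth.png}.
#' @return named character vector of paths, invisibly.
#' @export
writeTriplet <- function(triplet, dir, stem = triplet@frameId) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rgb = file.path(dir, paste0(stem, "_rgb.png")),
             ir = file.path(dir, paste0(stem, "_ir.tif")),
             depth = file.path(dir, paste0(stem, "_depth.png")))
  .writeImageFile(triplet@rgb, paths["rgb"], 8L)
  .writeImageFile(triplet@ir, paths["ir"], 16L)
  .writeImageFile(triplet@depth, paths["depth"], 8L)
  invisible(paths)
}

setMethod("show", "ModalityTriplet", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("<ModalityTriplet> '%s' %dx%d (rgb %d-bit, ir %d-bit, depth %d-bit)%s\n",
              object@frameId, d[1], d[2], object@bitDepths["rgb"],
              object@bitDepths["ir"], object@bitDepths["depth"],
              if (object@aligned) ", aligned" else ""))
})

#' Crop the shared field of view
#'
#' Removes rows outside the target height, split evenly between top and
#' bottom (an odd remainder goes to the bottom), and re-projects the
#' annotations: surviving boxes keep their pixel-space centers up to the
#' crop offset, boxes straddling the cut are clipped, and boxes left with
#' under one square pixel are dropped.
#'
#' @param triplet a \linkS4class{ModalityTriplet}.
#' @param annotations a \linkS4class{BoxAnnotationSet} or NULL.
#' @param targetH target height in px (e.g. 360 for 512 x 424 sensor frames).
#' @return list(triplet =, annotations =).
#' @export
cropFov <- function(triplet, annotations = NULL, targetH) {
  H <- dim(triplet@rgb)[1]; W <- dim(triplet@rgb)[2]
  if (targetH > H) stop("targetH (", targetH, ") exceeds image height (", H, ")")
  drop <- H - targetH
  top <- drop %/% 2L
  rows <- top + seq_len(targetH)
  out <- new("ModalityTriplet",
             rgb = triplet@rgb[rows, , , drop = FALSE],
             ir = triplet@ir[rows, , drop = FALSE],
             depth = triplet@depth[rows, , drop = FALSE],
             bitDepths = triplet@bitDepths, frameId = triplet@frameId,
             aligned = triplet@aligned)
  annOut <- NULL
  if (!is.null(annotations)) {
    b <- annotations@boxes
    if (nrow(b)) {
      y1 <- pmax(b$cy * H - b$h * H / 2 - top, 0)
      y2 <- pmin(b$cy * H + b$h * H / 2 - top, targetH)
      x1 <- b$cx * W - b$w * W / 2
      x2 <- b$cx * W + b$w * W / 2
      keep <- (y2 - y1) * (x2 - x1) >= 1 & y2 > y1
      b <- data.frame(class = b$class[keep],
                      cx = b$cx[keep],
                      cy = (y1 + y2)[keep] / 2 / targetH,
                      w = b$w[keep],
                      h = (y2 - y1)[keep] / targetH)
    }
    annOut <- boxAnnotationSet(b, c(targetH, W), annotations@imageId)
  }
  list(triplet = out, annotations = annOut)
}

#' Filter out tiny annotations
#'
#' Keeps objects strictly larger than \code{minSidePx} in both pixel
#' dimensions (the annotation policy keeps objects larger than 2 x 2 px).
#'
#' @param annotations a \linkS4class{BoxAnnotationSet}.
#' @param minSidePx minimum exclusive side length (default 2).
#' @return filtered \linkS4class{BoxAnnotationSet}.
#' @export
filterAnnotations <- function(annotations, minSidePx = 2) {
  stopifnot(minSidePx >= 1)
  b <- annotations@boxes
  if (nrow(b)) {
    H <- annotations@imageSize[1]; W <- annotations@imageSize[2]
    keep <- (b$w * W > minSidePx) & (b$h * H > minSidePx)
    b <- b[keep, , drop = FALSE]
  }
  boxAnnotationSet(b, annotations@imageSize, annotations@imageId)
}

#' Read / write annotations (COCO JSON or YOLO text)
#'
#' COCO boxes are stored as absolute top-left (x, y, w, h); YOLO rows are
#' \code{class cx cy w h} normalized. Conversions are exact up to the
#' stated coordinate quantization of the text format.
#'
#' @param path file path.
#' @param format \code{"coco_json"} or \code{"yolo_txt"}.
#' @param imageSize (H, W); required for \code{yolo_txt} (the format does
#'   not store it) and used to validate \code{coco_json}.
#' @param imageId image identifier (yolo_txt only).
#' @return a \linkS4class{BoxAnnotationSet}.
#' @export
readLabels <- function(path, format = c("coco_json", "yolo_txt"),
                       imageSize = NULL, imageId = "") {
  format <- match.arg(format)
  if (format == "coco_json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    img <- doc$images
    if (is.null(img) || !nrow(img)) stop("COCO file has no images entry")
    H <- img$height[1]; W <- img$width[1]
    ann <- doc$annotations
    if (is.null(ann) || !NROW(ann)) {
      b <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
    } else {
      bb <- do.call(rbind, ann$bbox)
      bad <- which(bb[, 3] <= 0 | bb[, 4] <= 0)
      if (length(bad))
        stop("malformed COCO record: nonpositive box size at annotation index ", bad[1])
      b <- data.frame(class = ann$category_id - 1L,
                      cx = (bb[, 1] + bb[, 3] / 2) / W,
                      cy = (bb[, 2] + bb[, 4] / 2) / H,
                      w = bb[, 3] / W, h = bb[, 4] / H)
    }
    boxAnnotationSet(b, c(H, W), as.character(img$id[1]))
  } else {
    if (is.null(imageSize)) stop("imageSize is required for yolo_txt")
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      b <- data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
    } else {
      parts <- lapply(seq_along(lines), function(i) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
        if (length(v) != 5L || anyNA(v))
          stop("malformed YOLO record at line ", i, " of ", path)
        if (v[4] <= 0 || v[5] <= 0)
          stop("malformed YOLO record: nonpositive size at line ", i, " of ", path)
        v
      })
      m <- do.call(rbind, parts)
      b <- data.frame(class = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                      w = m[, 4], h = m[, 5])
    }
    boxAnnotationSet(b, imageSize, imageId)
  }
}

#' @rdname readLabels
#' @param annotations a \linkS4class{BoxAnnotationSet} to write.
#' @export
writeLabels <- function(annotations, path, format = c("coco_json", "yolo_txt")) {
  format <- match.arg(format)
  b <- annotations@boxes
  H <- annotations@imageSize[1]; W <- annotations@imageSize[2]
  if (nrow(b) && any(b$w <= 0 | b$h <= 0)) {
    bad <- which(b$w <= 0 | b$h <= 0)[1]
    stop("annotation ", bad, " has nonpositive size")
  }
  if (format == "coco_json") {
    ann <- if (nrow(b)) list(
      id = seq_len(nrow(b)),
      image_id = rep(1L, nrow(b)),
      category_id = as.integer(b$class) + 1L,
      bbox = lapply(seq_len(nrow(b)), function(i)
        c((b$cx[i] - b$w[i] / 2) * W, (b$cy[i] - b$h[i] / 2) * H,
          b$w[i] * W, b$h[i] * H)),
      area = b$w * W * b$h * H,
      iscrowd = rep(0L, nrow(b))
    ) else list()
    doc <- list(
      images = data.frame(id = 1L, file_name = annotations@imageId,
                          height = H, width = W),
      annotations = if (length(ann))
        data.frame(id = ann$id, image_id = ann$image_id,
                   category_id = ann$category_id,
                   bbox = I(ann$bbox), area = ann$area, iscrowd = ann$iscrowd)
        else data.frame(),
      categories = data.frame(id = 1L, name = "shoot"))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- if (nrow(b))
      sprintf("%d %.6f %.6f %.6f %.6f", as.integer(b$class), b$cx, b$cy, b$w, b$h)
      else character(0)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' Plain-text table mapping frame ids to the three image paths and the
#' label path (tab-separated, one frame per row).
#'
#' @param path manifest file.
#' @return data.frame with columns frame, rgb, ir, depth, labels.
#' @export
readManifest <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname readManifest
#' @param manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
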