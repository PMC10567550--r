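#' Read a binary mask image
#'
#' PNG or TIFF; any nonzero value (any channel) is foreground.
#'
#' @param path image file.
#' @return binary integer matrix.
#' @export
readMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE))
                    stop("reading TIFF masks requires the 'tiff' package")
                  tiff::readTIFF(path)
                },
                stop("unsupported mask format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), max)
  (img > 0) * 1L
}

#' Write a binary mask as PNG
#'
#' @param mask binary matrix (nonzero = foreground).
#' @param path output PNG.
#' @export
writeMask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

# Zhang-Suen morphological thinning to a 1-px skeleton. No installed R
# package provides 2-D skeletonization, so it is implemented here.
skeletonize <- function(mask) {
  img <- (mask > 0) * 1L
  pad <- matrix(0L, nrow(img) + 2L, ncol(img) + 2L)
  pad[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)] <- img
  nr <- nrow(pad); nc <- ncol(pad)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- (1 + max(0, dr)):(nr + min(0, dr))
    cs <- (1 + max(0, dc)):(nc + min(0, dc))
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(pad, 1, 0);  p3 <- shift(pad, 1, -1)
      p4 <- shift(pad, 0, -1); p5 <- shift(pad, -1, -1)
      p6 <- shift(pad, -1, 0); p7 <- shift(pad, -1, 1)
      p8 <- shift(pad, 0, 1);  p9 <- shift(pad, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nr, nc)
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      if (step == 1) {
        c1 <- p2 * p4 * p6
        c2 <- p4 * p6 * p8
      } else {
        c1 <- p2 * p4 * p8
        c2 <- p2 * p6 * p8
      }
      del <- pad == 1L & B >= 2L & B <= 6L & A == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        pad[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nrow(img) + 1L), 2:(ncol(img) + 1L), drop = FALSE]
}

#' Total skeleton length of a fiber mask
#'
#' The mask is thinned to a 1-px skeleton and the length is the sum over
#' adjacency steps between skeleton pixels: orthogonal step = 1 px,
#' diagonal step = sqrt(2) px, times the pixel size. A diagonal step is
#' not counted when the two pixels already share an orthogonal skeleton
#' neighbour (avoids double-counting around corners).
#'
#' @param mask binary matrix (values 0/1).
#' @param pxSize pixel size (um/px; default 1).
#' @return total length in um (0 for an empty mask).
#' @export
totalLength <- function(mask, pxSize = 1) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  if (!any(mask == 1)) return(0)
  sk <- skeletonize(mask)
  nr <- nrow(sk); nc <- ncol(sk)
  at <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc & {
    v <- rep(FALSE, length(r))
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v[ok] <- sk[cbind(r[ok], c[ok])] == 1L
    v
  }
  px <- which(sk == 1L, arr.ind = TRUE)
  total <- 0
  # orthogonal steps: right and down neighbours (each pair counted once)
  total <- total + sum(at(px[, 1], px[, 2] + 1))
  total <- total + sum(at(px[, 1] + 1, px[, 2]))
  # diagonal steps: down-right and down-left, skipped when the two pixels
  # share an orthogonal skeleton neighbour
  dr <- at(px[, 1] + 1, px[, 2] + 1) &
    !(at(px[, 1], px[, 2] + 1) | at(px[, 1] + 1, px[, 2]))
  dl <- at(px[, 1] + 1, px[, 2] - 1) &
    !(at(px[, 1], px[, 2] - 1) | at(px[, 1] + 1, px[, 2]))
  total <- total + sqrt(2) * (sum(dr) + sum(dl))
  total * pxSize
}

#' Gliding-box lacunarity of a binary mask
#'
#' For each box size r an r x r window slides at stride 1; the box mass is
#' the foreground count and `Lambda(r) = var(mass) / mean(mass)^2 + 1`
#' (population variance, the standard gliding-box definition). 1 for
#' homogeneous patterns; larger for gappier ones.
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @param boxSizes box edge lengths (default c(2, 4, 8, 16), capped at the
#'   smaller image dimension).
#' @return list(boxSizes, lacunarity per box size, mean).
#' @export
lacunarity <- function(mask, boxSizes = c(2L, 4L, 8L, 16L)) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  if (!any(mask == 1)) stop("all-zero mask: mean box mass is 0")
  boxSizes <- boxSizes[boxSizes <= min(dim(mask))]
  if (!length(boxSizes)) stop("no box size fits inside the mask")
  # integral image: exact integer window sums
  I <- apply(apply(mask, 2L, cumsum), 1L, cumsum)
  I <- t(I)
  Ipad <- matrix(0, nrow(mask) + 1L, ncol(mask) + 1L)
  Ipad[-1, -1] <- I
  lam <- vapply(boxSizes, function(r) {
    nr <- nrow(mask) - r + 1L
    nc <- ncol(mask) - r + 1L
    rs <- seq_len(nr); cs <- seq_len(nc)
    mass <- Ipad[rs + r, cs + r, drop = FALSE] -
      Ipad[rs, cs + r, drop = FALSE] -
      Ipad[rs + r, cs, drop = FALSE] + Ipad[rs, cs, drop = FALSE]
    mu <- mean(mass)
    v <- mean((mass - mu)^2)
    v / mu^2 + 1
  }, numeric(1))
  list(boxSizes = boxSizes, lacunarity = stats::setNames(lam, boxSizes),
       mean = mean(lam))
}

#' Actin network metrics for one mask
#'
#' @param mask binary matrix.
#' @param pxSize pixel size (um/px).
#' @param boxSizes lacunarity box sizes.
#' @return list(total_length_um, lacunarity, mean_lacunarity).
#' @export
actinMetrics <- function(mask, pxSize = 1, boxSizes = c(2L, 4L, 8L, 16L)) {
  lac <- lacunarity(mask, boxSizes)
  list(total_length_um = totalLength(mask, pxSize),
       lacunarity = lac$lacunarity,
       mean_lacunarity = lac$mean)
}
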