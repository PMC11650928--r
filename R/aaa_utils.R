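# Internal numerical / RNG / image-array helpers shared across modules.
# Images are numeric arrays H x W x 3 in [0, 1]; masks are H x W in {0, 1}.
# Pixel coordinates are 0-based and refer to pixel centers: x rightward,
# y downward, so array element [y + 1, x + 1, ] is the pixel at (x, y).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded package functions do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed and a key path
#'
#' Hierarchical seed splitting: all package randomness flows from one master
#' seed through string keys, so every stage is independently reproducible.
#' Result is a positive integer < 2^31 - 1.
#' @noRd
derive_seed <- function(seed, ...) {
  keys <- paste(c(format(as.integer(seed)), vapply(list(...), as.character,
                                                  character(1))),
                collapse = "/")
  h <- digest::digest(keys, algo = "xxhash32", serialize = FALSE)
  (strtoi(substr(h, 1, 7), base = 16L) %% 2147483546L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_image <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L))
    stopf("expected an H x W x 3 image array")
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## ---- PNG I/O -------------------------------------------------------------

#' Read an RGB image from a PNG file
#'
#' @param path PNG file path.
#' @return Numeric array `H x W x 3` with intensities in `[0, 1]`;
#'   grayscale files are expanded to three channels, alpha is dropped.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] >= 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  x[, , 1:3, drop = FALSE]
}

#' Write an RGB image to a PNG file
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param path Output path.
#' @export
write_image <- function(img, path) {
  assert_image(img)
  png::writePNG(clip01(img), path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' @param path PNG path; any nonzero intensity counts as foreground.
#' @return `H x W` matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (!is.matrix(x)) x <- x[, , 1]
  (x > 0.5) * 1
}

#' Write a binary mask as a single-channel PNG (0 background, 255 shark)
#'
#' @param mask `H x W` matrix; nonzero is foreground.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

## ---- resampling ----------------------------------------------------------

#' Bilinear sample of an image at fractional pixel-center coordinates
#'
#' Out-of-bounds samples read as 0. `xs`, `ys` are 0-based pixel-center
#' coordinates of equal length; returns a length(xs) x C matrix.
#' @noRd
sample_bilinear <- function(img, xs, ys) {
  d <- dim(img); H <- d[1]; W <- d[2]; C <- if (length(d) == 3L) d[3] else 1L
  if (length(d) == 2L) img <- array(img, c(H, W, 1L))
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  # per-corner integer coords; out-of-range corners contribute 0
  val <- matrix(0, length(xs), C)
  corner <- function(xi, yi, w) {
    ok <- xi >= 0 & xi <= (W - 1) & yi >= 0 & yi <= (H - 1) & w > 0
    if (!any(ok)) return(invisible(NULL))
    idx <- cbind(yi[ok] + 1L, xi[ok] + 1L)
    for (c in seq_len(C)) {
      pl <- img[, , c]
      val[ok, c] <<- val[ok, c] + w[ok] * pl[idx]
    }
    invisible(NULL)
  }
  corner(x0,      y0,      (1 - fx) * (1 - fy))
  corner(x0 + 1,  y0,      fx       * (1 - fy))
  corner(x0,      y0 + 1,  (1 - fx) * fy)
  corner(x0 + 1,  y0 + 1,  fx       * fy)
  val
}

# cos/sin with exact values at multiples of pi/2 so that 90-degree
# geometry is a bit-exact pixel remap rather than a near-identity blend
snap_trig <- function(angle) {
  c0 <- cos(angle); s0 <- sin(angle)
  if (abs(c0 - round(c0)) < 1e-9) c0 <- round(c0)
  if (abs(s0 - round(s0)) < 1e-9) s0 <- round(s0)
  c(c0, s0)
}

#' Rotate an image about a center point (clockwise-positive, y down)
#'
#' Bilinear interpolation; out-of-frame regions are filled with `fill`.
#' @noRd
rotate_image <- function(img, angle, fill = 0) {
  d <- dim(img); H <- d[1]; W <- d[2]
  cs <- snap_trig(angle); cth <- cs[1]; sth <- cs[2]
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  g <- expand.grid(x = 0:(W - 1), y = 0:(H - 1))
  dx <- g$x - cx; dy <- g$y - cy
  # inverse map: output pixel <- input coords (rotate by -angle)
  xs <- cx + cth * dx + sth * dy
  ys <- cy - sth * dx + cth * dy
  v <- sample_bilinear(img, xs, ys)
  if (fill != 0) {
    out <- xs < 0 | xs > (W - 1) | ys < 0 | ys > (H - 1)
    v[out, ] <- fill
  }
  if (length(d) == 3L) {
    out <- array(0, d)
    for (c in seq_len(d[3])) out[, , c] <- matrix(v[, c], H, W, byrow = TRUE)
    out
  } else {
    matrix(v[, 1], H, W, byrow = TRUE)
  }
}

#' Exact rotation by a multiple of 90 degrees (pixel permutation)
#'
#' `k` quarter turns clockwise in display coordinates (y down).
#' @noRd
rot90k <- function(img, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(img)
  one <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE] # 90 cw
  f <- function(m) { for (i in seq_len(k)) m <- one(m); m }
  if (length(dim(img)) == 3L) {
    pls <- lapply(seq_len(dim(img)[3]), function(c) f(img[, , c]))
    array(unlist(pls), c(dim(pls[[1]]), dim(img)[3]))
  } else f(img)
}

#' Separable Gaussian blur (sigma in pixels; sigma = 0 is identity)
#' @noRd
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); k <- k / sum(k)
  blur1 <- function(m) {
    # replicate-pad rows then convolve along rows, then columns
    padr <- m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
    m2 <- apply(padr, 2, function(col) stats::filter(col, k, sides = 2))
    m2 <- m2[(r + 1):(r + nrow(m)), , drop = FALSE]
    padc <- m2[, c(rep(1, r), seq_len(ncol(m2)), rep(ncol(m2), r)),
               drop = FALSE]
    m3 <- t(apply(padc, 1, function(row) stats::filter(row, k, sides = 2)))
    m3[, (r + 1):(r + ncol(m2)), drop = FALSE]
  }
  if (length(dim(img)) == 3L) {
    out <- img
    for (c in seq_len(dim(img)[3])) out[, , c] <- blur1(img[, , c])
    out
  } else blur1(img)
}

## ---- convolution (frozen backbone forward pass) ---------------------------

#' 2-D convolution with "same" zero padding, stride, bias and optional ReLU
#'
#' `w` is a k x k x Cin x Cout array (k odd). Input `x` is H x W x Cin.
#' Implemented as k*k shifted-slice matrix products: fast enough in base R
#' for the small frozen test backbone.
#' @noRd
conv2d <- function(x, w, b, stride = 1L, relu = TRUE) {
  dx <- dim(x); H <- dx[1]; W <- dx[2]; Cin <- dx[3]
  dw <- dim(w); k <- dw[1]; Cout <- dw[4]
  stopifnot(dw[3] == Cin, k %% 2 == 1)
  p <- (k - 1L) / 2L
  xp <- array(0, c(H + 2L * p, W + 2L * p, Cin))
  xp[p + seq_len(H), p + seq_len(W), ] <- x
  ys <- seq(1L, H, by = stride); xs <- seq(1L, W, by = stride)
  Ho <- length(ys); Wo <- length(xs)
  acc <- matrix(rep(b, each = Ho * Wo), Ho * Wo, Cout)
  wm <- matrix(w, k * k * Cin, Cout)  # rows ordered (dy, dx, cin)
  for (dxk in seq_len(k)) for (dyk in seq_len(k)) {
    sl <- xp[ys + dyk - 1L, xs + dxk - 1L, , drop = FALSE]
    rows <- ((dxk - 1L) * k + (dyk - 1L)) * Cin + seq_len(Cin)
    acc <- acc + matrix(sl, Ho * Wo, Cin) %*% wm[rows, , drop = FALSE]
  }
  if (relu) acc[acc < 0] <- 0
  array(acc, c(Ho, Wo, Cout))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## ---- misc ----------------------------------------------------------------

#' Resize a square image with bilinear interpolation
#' @noRd
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img); H <- d[1]; W <- d[2]
  if (H == out_h && W == out_w) return(img)
  # align pixel centers: output center u maps to input (u+0.5)*W/out - 0.5
  xs <- ( (0:(out_w - 1)) + 0.5 ) * W / out_w - 0.5
  ys <- ( (0:(out_h - 1)) + 0.5 ) * H / out_h - 0.5
  xs <- pmin(pmax(xs, 0), W - 1); ys <- pmin(pmax(ys, 0), H - 1)
  g <- expand.grid(x = xs, y = ys)
  v <- sample_bilinear(img, g$x, g$y)
  if (length(d) == 3L) {
    out <- array(0, c(out_h, out_w, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- matrix(v[, c], out_h, out_w,
                                                 byrow = TRUE)
    out
  } else matrix(v[, 1], out_h, out_w, byrow = TRUE)
}

PATCH_TYPES <- c("head", "pec", "FDF", "FDB")
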