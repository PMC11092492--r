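# Glyph sources: pools of 28x28 grayscale digit images. Two backends:
#  * "synthetic": parametric stroke-rendered digits (segment skeletons with
#    random affine jitter, stroke width 2-4 px, additive pixel noise), so the
#    package builds and tests without any external download;
#  * "mnist": handwritten digits read from IDX files.
# Operator glyphs are composed from the digit "1": minus is a "1" rotated 90
# degrees, plus is the pixel-wise maximum of a vertical and a rotated "1".

GLYPH_SIZE <- 28L

# Segment endpoints (row, col) of a seven-segment-style skeleton; digit "1"
# is a single centered vertical stroke so that rotations give clean operator
# strokes.
.seg_pts <- list(
  A = c(5, 9, 5, 19), B = c(5, 19, 14, 19), C = c(14, 19, 23, 19),
  D = c(23, 9, 23, 19), E = c(14, 9, 23, 9), F = c(5, 9, 14, 9),
  G = c(14, 9, 14, 19), V = c(5, 14, 23, 14)
)
.digit_segs <- list(
  "0" = c("A", "B", "C", "D", "E", "F"), "1" = "V",
  "2" = c("A", "B", "G", "E", "D"), "3" = c("A", "B", "G", "C", "D"),
  "4" = c("F", "G", "B", "C"), "5" = c("A", "F", "G", "C", "D"),
  "6" = c("A", "F", "G", "E", "D", "C"), "7" = c("A", "B", "C"),
  "8" = c("A", "B", "C", "D", "E", "F", "G"),
  "9" = c("A", "B", "C", "D", "F", "G")
)

# distance from every pixel to a segment, vectorised over the 28x28 grid
.seg_dist <- function(py, px, y1, x1, y2, x2) {
  vy <- y2 - y1; vx <- x2 - x1
  len2 <- vy^2 + vx^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((py - y1) * vy + (px - x1) * vx) / len2))
  sqrt((py - (y1 + t * vy))^2 + (px - (x1 + t * vx))^2)
}

# One jittered rendering of a digit. Uses the current RNG stream.
render_synthetic_digit <- function(digit) {
  segs <- .digit_segs[[as.character(digit)]]
  cy <- 14; cx <- 14
  theta <- runif(1, -0.1, 0.1)
  scale <- runif(1, 0.9, 1.08)
  dy <- runif(1, -1.5, 1.5); dx <- runif(1, -1.5, 1.5)
  width <- runif(1, 2.4, 3.2)
  g <- expand.grid(y = 1:GLYPH_SIZE, x = 1:GLYPH_SIZE)
  img <- matrix(0, GLYPH_SIZE, GLYPH_SIZE)
  co <- cos(theta); si <- sin(theta)
  for (s in segs) {
    p <- .seg_pts[[s]]
    y <- c(p[1], p[3]) - cy; x <- c(p[2], p[4]) - cx
    yr <- scale * (co * y - si * x) + cy + dy
    xr <- scale * (si * y + co * x) + cx + dx
    d <- .seg_dist(g$y, g$x, yr[1], xr[1], yr[2], xr[2])
    val <- pmin(1, pmax(0, (width / 2 + 0.5 - d) * 1.5))
    img <- pmax(img, matrix(val, GLYPH_SIZE, GLYPH_SIZE))
  }
  img <- img + matrix(rnorm(GLYPH_SIZE^2, 0, 0.02), GLYPH_SIZE, GLYPH_SIZE)
  matrix(pmin(pmax(img, 0), 1), GLYPH_SIZE, GLYPH_SIZE)
}

#' Create a pool of digit glyphs
#'
#' Builds a [glyph] source: per-digit pools of 28x28 grayscale images in
#' \[0, 1\]. The synthetic backend renders parametric stroke digits; the MNIST
#' backend reads IDX image/label files. Use separate sources (different seeds
#' or MNIST splits) for the train and test halves of a stimulus set so that
#' glyph variants never leak across the split.
#'
#' @param backend `"synthetic"` or `"mnist"`.
#' @param split label stored on the source, `"train"` or `"test"`.
#' @param seed integer seed for the synthetic renderer.
#' @param n_glyphs pool size per digit (synthetic backend).
#' @param images,labels paths to IDX files (MNIST backend).
#' @param max_per_digit cap on pool size per digit (MNIST backend).
#' @return An object of class `glyph_source` with fields `backend`, `split`
#'   and `pools` (a named list, digits `"0"`..`"9"`).
#' @export
glyph_source <- function(backend = c("synthetic", "mnist"),
                         split = c("train", "test"),
                         seed = 1L, n_glyphs = 40L,
                         images = NULL, labels = NULL,
                         max_per_digit = Inf) {
  backend <- match.arg(backend)
  split <- match.arg(split)
  if (backend == "synthetic") {
    pools <- withr::with_seed(as.integer(seed), {
      lapply(setNames(0:9, as.character(0:9)), function(d)
        lapply(seq_len(n_glyphs), function(i) render_synthetic_digit(d)))
    })
  } else {
    if (is.null(images) || is.null(labels))
      abort("mnist backend needs `images` and `labels` IDX paths")
    imgs <- read_idx(images)
    labs <- as.integer(read_idx(labels))
    pools <- lapply(setNames(0:9, as.character(0:9)), function(d) {
      idx <- which(labs == d)
      if (length(idx) == 0) abort(paste0("no MNIST glyphs for digit ", d))
      idx <- utils::head(idx, max_per_digit)
      lapply(idx, function(i) imgs[i, , ] / 255)
    })
  }
  structure(list(backend = backend, split = split, pools = pools),
            class = "glyph_source")
}

#' @export
print.glyph_source <- function(x, ...) {
  cat("<glyph_source> backend:", x$backend, " split:", x$split,
      " pool sizes:", paste(range(lengths(x$pools)), collapse = "-"), "\n")
  invisible(x)
}

rot90ccw <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

#' Draw one 28x28 glyph from a source
#'
#' Digits are drawn uniformly from the source pool; `"minus"` is a digit-1
#' glyph rotated 90 degrees, `"plus"` the pixel-wise maximum of a vertical
#' and a rotated digit-1 glyph, and `"blank"` an all-zero image. Sampling
#' uses the current RNG stream, so rendering is a pure function of
#' (symbol, source, seed).
#'
#' @param symbol one of `"0"`..`"9"` (or integers 0..9), `"plus"`, `"minus"`,
#'   `"blank"`.
#' @param source a [glyph_source()].
#' @return a 28x28 matrix with values in \[0, 1\].
#' @export
render_glyph <- function(symbol, source) {
  symbol <- as.character(symbol)
  pick <- function(d) {
    pool <- source$pools[[d]]
    if (is.null(pool) || length(pool) == 0)
      abort(paste0("glyph pool for symbol '", d, "' is empty"))
    pool[[sample.int(length(pool), 1)]]
  }
  switch(symbol,
    blank = matrix(0, GLYPH_SIZE, GLYPH_SIZE),
    minus = rot90ccw(pick("1")),
    plus = pmax(pick("1"), rot90ccw(pick("1"))),
    pick(symbol)
  )
}

#' Read an IDX array file (MNIST format)
#'
#' Parses the big-endian IDX container used by the MNIST distribution
#' (magic `0x00000803` for image tensors, `0x00000801` for label vectors).
#'
#' @param path file path.
#' @return an integer array with the dimensions declared in the header
#'   (first dimension indexes items).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (is.na(magic) || bitwAnd(magic, -256L) != 0x0800L)
    abort(paste0("not an IDX file (bad magic): ", path))
  ndim <- bitwAnd(magic, 0xffL)
  dims <- readBin(con, "integer", n = ndim, size = 4, endian = "big")
  n <- prod(dims)
  raw <- readBin(con, "integer", n = n, size = 1, signed = FALSE)
  if (length(raw) < n) abort(paste0("truncated IDX file: ", path))
  if (ndim == 1) return(as.integer(raw))
  # row-major on disk -> fill last dim fastest
  array(raw, dim = rev(dims)) |> aperm(rev(seq_len(ndim)))
}
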