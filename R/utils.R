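#' @useDynLib dtcwtseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats kmeans median rnorm runif sd quantile fft
NULL

# stop() with a consistent prefix so pipeline stages can be identified
.fail <- function(...) stop(..., call. = FALSE)

.check_matrix <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    .fail(name, " must be a numeric matrix")
  if (!all(is.finite(x)))
    .fail(name, " contains non-finite values")
  invisible(x)
}

# Run expr with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage seeds (small
#' string hash, reduced modulo 2^31 - 1 so the result is a valid integer
#' seed). Used throughout the package so that every pipeline stage is
#' reproducible from the master seed alone.
#'
#' @param master integer master seed.
#' @param stage stage name (any string).
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(as.character(stage)))
    h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# circular index helper (1-based)
.wrap1 <- function(i, n) ((i - 1L) %% n) + 1L

# Symmetric-reflection padding of a matrix to target dimensions (pad at the
# bottom/right; reflection without repeating the edge sample).
.pad_reflect <- function(x, nr, nc) {
  r <- nrow(x); c <- ncol(x)
  if (nr < r || nc < c) .fail("padding target smaller than input")
  if (nr > r) {
    extra <- nr - r
    if (extra > r - 1) .fail("image too small to pad for requested depth")
    x <- rbind(x, x[seq(r - 1, by = -1, length.out = extra), , drop = FALSE])
  }
  if (nc > c) {
    extra <- nc - c
    if (extra > c - 1) .fail("image too small to pad for requested depth")
    x <- cbind(x, x[, seq(c - 1, by = -1, length.out = extra), drop = FALSE])
  }
  x
}

# nearest-neighbour integer upsampling by a factor, then crop to (nr, nc)
.upsample_nn <- function(x, factor, nr, nc) {
  y <- x[rep(seq_len(nrow(x)), each = factor),
         rep(seq_len(ncol(x)), each = factor), drop = FALSE]
  y[seq_len(nr), seq_len(nc), drop = FALSE]
}

# circular shift up-left by `off` pixels in both dimensions
.circ_shift <- function(m, off) {
  if (off == 0L) return(m)
  m[.wrap1(seq_len(nrow(m)) + off, nrow(m)),
    .wrap1(seq_len(ncol(m)) + off, ncol(m)), drop = FALSE]
}

# Bilinear upsampling by an integer factor with a constant alignment
# shift: coarse sample k is treated as sitting at fine coordinate
# fac*k - fac/2 - shift (circular indexing on the fine grid).
.upsample_bilinear <- function(x, fac, nr, nc, shift = 0) {
  if (fac == 1L && shift == 0) return(x[seq_len(nr), seq_len(nc), drop = FALSE])
  u <- (seq_len(nr) + shift) / fac + 0.5
  v <- (seq_len(nc) + shift) / fac + 0.5
  interp1 <- function(coord, n) {
    k0 <- floor(coord)
    w <- coord - k0
    list(lo = .wrap1(k0, n), hi = .wrap1(k0 + 1, n), w = w)
  }
  iu <- interp1(u, nrow(x)); iv <- interp1(v, ncol(x))
  top <- x[iu$lo, iv$lo, drop = FALSE] * (1 - iv$w)[col(matrix(0, nr, nc))] +
         x[iu$lo, iv$hi, drop = FALSE] * iv$w[col(matrix(0, nr, nc))]
  bot <- x[iu$hi, iv$lo, drop = FALSE] * (1 - iv$w)[col(matrix(0, nr, nc))] +
         x[iu$hi, iv$hi, drop = FALSE] * iv$w[col(matrix(0, nr, nc))]
  top * (1 - iu$w) + bot * iu$w
}

# local box mean with reflected borders, odd window
.box_mean <- function(x, window) {
  if (window %% 2 != 1 || window < 1) .fail("window must be odd and >= 1")
  if (window == 1) return(x)
  h <- (window - 1) / 2
  n <- nrow(x); m <- ncol(x)
  ridx <- c(seq(h + 1, 2, by = -1), seq_len(n), seq(n - 1, n - h, by = -1))
  cidx <- c(seq(h + 1, 2, by = -1), seq_len(m), seq(m - 1, m - h, by = -1))
  xe <- x[ridx, cidx, drop = FALSE]
  cs <- apply(xe, 2, cumsum)
  cs <- rbind(0, cs)
  rowsum_mat <- cs[(window + 1):(n + window), , drop = FALSE] -
    cs[1:n, , drop = FALSE]
  cs2 <- t(apply(rowsum_mat, 1, cumsum))
  cs2 <- cbind(0, cs2)
  out <- cs2[, (window + 1):(m + window), drop = FALSE] -
    cs2[, 1:m, drop = FALSE]
  out / (window * window)
}
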