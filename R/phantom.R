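# Synthetic brain-like phantom slices with ground-truth masks.
#
# A phantom is built from concentric structure: a bright skull ring
# enclosing a smooth tissue region, with 1-3 tumour blobs of distinct mean
# intensity strictly inside the tissue. Tumour shapes are thresholded
# Gaussian-smoothed random fields intersected with ellipses, which gives
# irregular but connected blobs with clear boundaries. Class layout:
#   0 = background, 1 = tissue, 2..(n_classes-2) = tumour classes,
#   n_classes-1 = skull ring (the brightest class by construction).

#' Phantom specification
#'
#' @param height,width image size in pixels (>= 32).
#' @param n_classes number of label classes, >= 2. With `n_classes = 2` the
#'   phantom is background + tissue only (no skull, no tumours); with 3 it
#'   gains the skull ring; tumour classes appear from 4 upward.
#' @param tumor_count_range integer interval `c(lo, hi)` for the number of
#'   tumour blobs drawn per tumour class.
#' @param class_means per-class mean intensities in `[0, 1]`, one per class,
#'   pairwise distinct. Default spreads classes over `[0, 0.9]` with the
#'   skull brightest.
#' @param class_texture_sd per-class within-class intensity SD (recycled).
#' @param tumor_smooth SD (pixels) of the Gaussian smoothing that shapes
#'   tumour blobs; larger values give rounder tumours.
#' @param seed integer RNG seed; phantoms are bit-reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L, n_classes = 4L,
                         tumor_count_range = c(1L, 3L),
                         class_means = NULL,
                         class_texture_sd = 0.02,
                         tumor_smooth = 3,
                         seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  n_classes <- as.integer(n_classes)
  if (height < 32L || width < 32L) .fail("phantom must be at least 32x32")
  if (n_classes < 2L) .fail("n_classes must be >= 2")
  if (is.null(class_means)) {
    # background dark, tissue mid, tumours spread between, skull brightest
    class_means <- switch(as.character(min(n_classes, 3L)),
      "2" = c(0.05, 0.45),
      "3" = c(0.05, 0.45, 0.95))
    if (n_classes > 3L)
      class_means <- c(0.05, 0.4,
                       seq(0.7, 0.85, length.out = n_classes - 3L), 0.95)
  }
  if (length(class_means) != n_classes)
    .fail("class_means must have one entry per class (",
          n_classes, "), got ", length(class_means))
  if (any(class_means < 0 | class_means > 1))
    .fail("class_means must lie in [0, 1]")
  if (anyDuplicated(class_means))
    .fail("class_means must be pairwise distinct")
  class_texture_sd <- rep_len(class_texture_sd, n_classes)
  if (any(class_texture_sd < 0)) .fail("class_texture_sd must be >= 0")
  tumor_count_range <- as.integer(tumor_count_range)
  if (length(tumor_count_range) != 2L ||
      any(tumor_count_range < 0L) ||
      tumor_count_range[1] > tumor_count_range[2])
    .fail("tumor_count_range must be a non-decreasing pair of counts >= 0")
  structure(list(height = height, width = width, n_classes = n_classes,
                 tumor_count_range = tumor_count_range,
                 class_means = class_means,
                 class_texture_sd = class_texture_sd,
                 tumor_smooth = tumor_smooth, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Gaussian-smoothed white noise field (circular smoothing)
.smooth_field <- function(h, w, sdpix) {
  x <- matrix(rnorm(h * w), h, w)
  if (sdpix <= 0) return(x)
  half <- max(1L, ceiling(3 * sdpix))
  k <- exp(-0.5 * (seq(-half, half) / sdpix)^2)
  k <- k / sum(k)
  x <- .cconv_cols(x, k)
  t(.cconv_cols(t(x), k))
}

# connected-component labelling, 4-connectivity (two-pass, base R)
.connected_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  stack <- integer(h * w)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    top <- 1L; stack[1] <- start; lab[start] <- nxt
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- ((p - 1L) %% h) + 1L; cc <- ((p - 1L) %/% h) + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < h) p + 1L,
                  if (cc > 1L) p - h, if (cc < w) p + h)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt; top <- top + 1L; stack[top] <- q
        }
      }
    }
  }
  list(labels = lab, n = nxt)
}

#' Generate a synthetic brain phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (clean intensity matrix in `[0,1]`) and
#'   `truth` (integer label matrix, values `0..n_classes-1`).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) .fail("spec must be a phantom_spec")
  with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  h <- spec$height; w <- spec$width; K <- spec$n_classes
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- 0.42 * h; rx <- 0.42 * w
  rr <- matrix(rep(seq_len(h), w), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  # mildly irregular head outline
  ang <- atan2(rr - cy, cc - cx)
  wob <- 1 + 0.03 * sin(2 * ang + runif(1, 0, 2 * pi)) +
             0.02 * sin(3 * ang + runif(1, 0, 2 * pi))
  d <- sqrt(((rr - cy) / ry)^2 + ((cc - cx) / rx)^2) / wob

  truth <- matrix(0L, h, w)
  if (K == 2L) {
    truth[d <= 1] <- 1L
  } else {
    skull_id <- K - 1L
    ring <- 0.12
    truth[d <= 1] <- skull_id
    truth[d <= 1 - ring] <- 1L
    # tumour blobs strictly inside the tissue
    tissue_margin <- d <= (1 - ring) * 0.82
    n_tumor_classes <- K - 3L
    if (n_tumor_classes > 0L) for (k in seq_len(n_tumor_classes)) {
      cls <- 1L + k
      n_blob <- if (spec$tumor_count_range[1] == spec$tumor_count_range[2])
        spec$tumor_count_range[1]
      else sample(spec$tumor_count_range[1]:spec$tumor_count_range[2], 1L)
      placed <- 0L; tries <- 0L
      while (placed < n_blob && tries < 200L) {
        tries <- tries + 1L
        cand <- .tumor_blob(h, w, spec$tumor_smooth, tissue_margin)
        if (is.null(cand)) next
        # reject overlap with already-placed tumours
        if (any(truth[cand] > 1L)) next
        truth[cand] <- cls
        placed <- placed + 1L
      }
      if (placed < n_blob)
        .fail("could not place ", n_blob, " tumour blobs; enlarge the ",
              "phantom or reduce tumor_count_range")
    }
  }
  image <- matrix(spec$class_means[truth + 1L], h, w) +
    matrix(spec$class_texture_sd[truth + 1L], h, w) * rnorm(h * w)
  image[image < 0] <- 0; image[image > 1] <- 1
  list(image = image, truth = truth)
}

# one connected irregular blob inside `allowed`; NULL on failure
.tumor_blob <- function(h, w, smooth_sd, allowed) {
  idx <- which(allowed)
  ctr <- idx[sample.int(length(idx), 1L)]
  br <- ((ctr - 1L) %% h) + 1L; bc <- ((ctr - 1L) %/% h) + 1L
  a <- runif(1, 0.05, 0.11) * min(h, w)
  b <- runif(1, 0.05, 0.11) * min(h, w)
  th <- runif(1, 0, pi)
  rr <- matrix(rep(seq_len(h), w), h, w) - br
  cc <- matrix(rep(seq_len(w), each = h), h, w) - bc
  u <- cos(th) * cc + sin(th) * rr
  v <- -sin(th) * cc + cos(th) * rr
  ell <- (u / a)^2 + (v / b)^2 <= 1
  f <- .smooth_field(h, w, smooth_sd)
  blob <- ell & (f > quantile(f[ell], 0.25)) & allowed
  if (!any(blob)) return(NULL)
  # keep the largest connected component containing mass
  comp <- .connected_components(blob)
  if (comp$n == 0L) return(NULL)
  sizes <- tabulate(comp$labels[comp$labels > 0L], comp$n)
  best <- which.max(sizes)
  if (sizes[best] < 12L) return(NULL)
  comp$labels == best
}

#' Add Gaussian white noise to an image
#'
#' The output is intentionally NOT clipped to `[0, 1]`: the denoiser's
#' noise model assumes true Gaussian statistics.
#'
#' @param image numeric matrix.
#' @param sigma noise standard deviation in intensity units, >= 0.
#' @param seed integer seed; the corruption is reproducible.
#' @return numeric matrix, `image + N(0, sigma^2)` i.i.d. per pixel.
#' @export
add_noise <- function(image, sigma, seed = 1L) {
  .check_matrix(image)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    .fail("sigma must be a single finite value >= 0")
  if (sigma == 0) return(image)
  with_seed(seed, image + sigma * matrix(rnorm(length(image)), nrow(image)))
}

#' Generate a dataset of noisy phantom samples
#'
#' Per-sample seeds are derived deterministically from the master seed, so
#' a dataset is reproducible as a whole while its samples differ.
#'
#' @param n number of samples, >= 1.
#' @param spec a [phantom_spec()]; its own seed field is ignored in favour
#'   of the derived per-sample seeds.
#' @param sigma Gaussian noise SD applied to each clean image.
#' @param seed master seed.
#' @return list of `n` samples, each a list with `clean`, `noisy`, `truth`
#'   and `sigma`.
#' @export
make_dataset <- function(n, spec, sigma, seed = 1L) {
  if (n < 1L) .fail("n must be >= 1")
  lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, paste0("sample", i))
    sp <- spec
    sp$seed <- si
    ph <- generate_phantom(sp)
    list(clean = ph$image,
         noisy = add_noise(ph$image, sigma, derive_seed(si, "noise")),
         truth = ph$truth, sigma = sigma)
  })
}
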