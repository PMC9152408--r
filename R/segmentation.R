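# Initial MAP segmentation: per-class diagonal-Gaussian likelihood on the
# wavelet features plus a Potts label-smoothness prior, minimized by
# iterated conditional modes (ICM).
#
# The labelling energy is
#   E(f) = sum_s [ -log N(x_s; mu_{f_s}, diag(var_{f_s})) - log P(f_s) ]
#        + beta * #{4-neighbour pairs with differing labels},
# i.e. the sum of a characteristic (data) energy and a marker (smoothness)
# energy. ICM performs raster-order coordinate descent on E; each sweep is
# non-increasing in E and the procedure is deterministic (ties break to
# the lowest class id).

#' Fit per-class Gaussian parameters from labelled features
#'
#' Maximum-likelihood mean and per-channel variance per class, with class
#' priors given by label frequencies. Every class present in
#' `0..n_classes-1` must own at least one pixel.
#'
#' @param features a [extract_features()] result.
#' @param init_labels integer label matrix (`0`-based class ids) matching
#'   the feature shape, e.g. the clustering labels or ground truth.
#' @param beta Potts smoothness weight, >= 0.
#' @param var_floor lower bound applied to the per-channel variances.
#' @return object of class `seg_model` with `class_means` (K x D),
#'   `class_vars` (K x D), `class_priors` (length K), `beta`, `n_classes`.
#' @export
fit_segmentation_model <- function(features, init_labels, beta = 1,
                                   var_floor = 1e-6) {
  if (!inherits(features, "dtcwt_features")) .fail("not a dtcwt_features")
  lab <- as.vector(init_labels)
  if (length(lab) != nrow(features$vectors))
    .fail("init_labels shape does not match features")
  if (beta < 0) .fail("beta must be >= 0")
  K <- max(lab) + 1L
  X <- features$vectors
  D <- ncol(X)
  mu <- matrix(0, K, D); va <- matrix(0, K, D); pr <- numeric(K)
  for (k in 0:(K - 1L)) {
    rows <- lab == k
    if (!any(rows)) .fail("class ", k, " has no pixels in init_labels")
    Xi <- X[rows, , drop = FALSE]
    mu[k + 1L, ] <- colMeans(Xi)
    va[k + 1L, ] <- pmax(colMeans(Xi^2) - colMeans(Xi)^2, var_floor)
    pr[k + 1L] <- mean(rows)
  }
  structure(list(class_means = mu, class_vars = va, class_priors = pr,
                 beta = beta, n_classes = K),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat("MAP segmentation model: ", x$n_classes, " classes, ",
      ncol(x$class_means), " feature channels, beta = ", x$beta, "\n",
      sep = "")
  cat("  class priors:", signif(x$class_priors, 3), "\n")
  invisible(x)
}

#' Per-pixel per-class data (characteristic) energy
#'
#' Negative log of the diagonal-Gaussian class likelihood minus the log
#' prior; the evidence term is constant over classes and omitted.
#'
#' @param features a [extract_features()] result.
#' @param model a [fit_segmentation_model()] result.
#' @return numeric matrix, one row per pixel (column-major), one column
#'   per class.
#' @export
data_energy <- function(features, model) {
  if (!inherits(model, "seg_model")) .fail("not a seg_model")
  X <- features$vectors
  K <- model$n_classes
  E <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    mu <- model$class_means[k, ]; va <- model$class_vars[k, ]
    q <- sweep(X, 2, mu)
    E[, k] <- 0.5 * ncol(X) * log(2 * pi) + 0.5 * sum(log(va)) +
      0.5 * (q^2 %*% (1 / va)) - log(model$class_priors[k])
  }
  E
}

#' Potts marker (smoothness) energy of a label map
#'
#' `beta` times the number of 4-neighbour pixel pairs with differing
#' labels.
#'
#' @param labels integer label matrix.
#' @param beta smoothness weight.
#' @return scalar energy.
#' @export
marker_energy <- function(labels, beta = 1) {
  h <- nrow(labels); w <- ncol(labels)
  disagree <- sum(labels[-h, , drop = FALSE] != labels[-1, , drop = FALSE]) +
    sum(labels[, -w, drop = FALSE] != labels[, -1, drop = FALSE])
  beta * disagree
}

#' MAP segmentation by iterated conditional modes
#'
#' Initializes at the per-pixel argmin of the data energy and performs
#' raster-order ICM sweeps until no pixel changes or `max_sweeps` is
#' reached. With `beta = 0` the result is exactly the per-pixel argmin.
#' The total energy trace (recorded after every sweep) is attached as
#' attribute `"energy_trace"` and is non-increasing.
#'
#' @param features a [extract_features()] result.
#' @param model a [fit_segmentation_model()] result (its `beta` is used).
#' @param max_sweeps sweep cap, default 10.
#' @param block_side optional tile side; when given, the image is split
#'   into `block_side`-sized tiles segmented independently and stitched
#'   (the per-block product form of the segmentation objective). Default
#'   `NULL` treats the whole lattice as one block.
#' @return integer label matrix (`0`-based), with attributes
#'   `energy_trace` and `sweeps`.
#' @export
segment_icm <- function(features, model, max_sweeps = 10L,
                        block_side = NULL) {
  E <- data_energy(features, model)
  h <- features$shape[1]; w <- features$shape[2]
  if (!is.null(block_side)) {
    out <- matrix(0L, h, w)
    for (r0 in seq(1, h, by = block_side)) for (c0 in seq(1, w, by = block_side)) {
      r1 <- min(r0 + block_side - 1L, h); c1 <- min(c0 + block_side - 1L, w)
      sub <- outer(r0:r1, (c0:c1 - 1L) * h, "+")
      Es <- E[as.vector(sub), , drop = FALSE]
      init <- matrix(max.col(-Es, ties.method = "first") - 1L,
                     r1 - r0 + 1L, c1 - c0 + 1L)
      res <- .icm_sweeps(Es, init, model$beta, as.integer(max_sweeps))
      out[r0:r1, c0:c1] <- res$labels
    }
    return(out)
  }
  init <- matrix(max.col(-E, ties.method = "first") - 1L, h, w)
  res <- .icm_sweeps(E, init, model$beta, as.integer(max_sweeps))
  structure(res$labels, energy_trace = res$energy_trace,
            sweeps = res$sweeps)
}

#' Fraction of pixels whose labels disagree
#'
#' The empirical mis-segmentation rate. No label matching is applied;
#' align labels first with [match_labels()] when the two maps use
#' arbitrary label ids.
#'
#' @param pred,truth integer label matrices of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
missegmentation_rate <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    .fail("pred and truth must have the same shape")
  mean(pred != truth)
}

#' Best bijective label matching
#'
#' Relabels `pred` so that its classes align with `truth` as well as
#' possible (maximum total overlap over one-to-one assignments; exhaustive
#' over permutations for up to 8 classes, greedy beyond).
#'
#' @param pred,truth integer label matrices of equal shape.
#' @return relabelled copy of `pred`.
#' @export
match_labels <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    .fail("pred and truth must have the same shape")
  pl <- sort(unique(as.vector(pred)))
  tl <- sort(unique(as.vector(truth)))
  K <- max(length(pl), length(tl))
  overlap <- matrix(0, length(pl), K)
  for (i in seq_along(pl)) for (j in seq_along(tl))
    overlap[i, j] <- sum(pred == pl[i] & truth == tl[j])
  tl_ext <- c(tl, setdiff(seq(0L, K * 2L), tl))[seq_len(K)]
  if (length(pl) <= 8L) {
    perms <- .permutations(K)
    best <- perms[which.max(apply(perms, 1, function(p)
      sum(overlap[cbind(seq_along(pl), p[seq_along(pl)])]))), ]
  } else {
    best <- integer(length(pl))
    taken <- rep(FALSE, K)
    for (i in order(-apply(overlap, 1, max))) {
      j <- order(-overlap[i, ])
      j <- j[!taken[j]][1]
      best[i] <- j; taken[j] <- TRUE
    }
  }
  out <- pred
  for (i in seq_along(pl)) out[pred == pl[i]] <- tl_ext[best[i]]
  out
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}
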