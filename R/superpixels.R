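# Grid-seeded local k-means superpixels (SLIC-style) used as the focus
# regions of the refinement agent. Deterministic: no randomness involved.

#' SLIC-style superpixels
#'
#' Segments an intensity image into roughly `n_superpixels` compact
#' regions by local k-means in (row, col, intensity) space: seeds on a
#' regular grid, assignment restricted to a 2S window around each centre
#' (S the grid step), followed by a connectivity cleanup that merges
#' stray fragments into an adjacent region.
#'
#' @param image numeric matrix.
#' @param n_superpixels target region count, default 64.
#' @param compactness intensity scale relative to the spatial scale;
#'   smaller values let regions follow intensity edges more freely.
#' @param iterations k-means iterations, default 5.
#' @return integer matrix of region ids `0..n-1` (row-major compact ids).
#' @export
slic_superpixels <- function(image, n_superpixels = 64L, compactness = 0.1,
                             iterations = 5L) {
  .check_matrix(image)
  h <- nrow(image); w <- ncol(image)
  n_superpixels <- max(1L, as.integer(n_superpixels))
  S <- sqrt(h * w / n_superpixels)
  gr <- pmin(pmax(round(seq(S / 2, h - S / 2, by = S)), 1), h)
  gc <- pmin(pmax(round(seq(S / 2, w - S / 2, by = S)), 1), w)
  if (length(gr) == 0) gr <- round(h / 2)
  if (length(gc) == 0) gc <- round(w / 2)
  centers <- expand.grid(r = gr, c = gc)
  centers$int <- image[cbind(centers$r, centers$c)]
  K <- nrow(centers)
  rr <- matrix(rep(seq_len(h), w), h, w)
  cc <- matrix(rep(seq_len(w), each = h), h, w)
  lab <- matrix(1L, h, w)
  dist <- matrix(Inf, h, w)
  for (it in seq_len(iterations)) {
    dist[] <- Inf
    for (k in seq_len(K)) {
      r0 <- max(1L, floor(centers$r[k] - 2 * S)); r1 <- min(h, ceiling(centers$r[k] + 2 * S))
      c0 <- max(1L, floor(centers$c[k] - 2 * S)); c1 <- min(w, ceiling(centers$c[k] + 2 * S))
      d <- ((rr[r0:r1, c0:c1] - centers$r[k])^2 +
            (cc[r0:r1, c0:c1] - centers$c[k])^2) / S^2 +
           ((image[r0:r1, c0:c1] - centers$int[k]) / compactness)^2
      win_d <- dist[r0:r1, c0:c1]
      upd <- d < win_d
      win_l <- lab[r0:r1, c0:c1]
      win_l[upd] <- k
      win_d[upd] <- d[upd]
      lab[r0:r1, c0:c1] <- win_l
      dist[r0:r1, c0:c1] <- win_d
    }
    for (k in seq_len(K)) {
      m <- lab == k
      if (!any(m)) next
      centers$r[k] <- mean(rr[m]); centers$c[k] <- mean(cc[m])
      centers$int[k] <- mean(image[m])
    }
  }
  lab <- .enforce_connectivity(lab)
  ids <- sort(unique(as.vector(lab)))
  matrix(match(lab, ids) - 1L, h, w)
}

# merge connected fragments so each region id is a single 4-connected
# component: every component except the largest of its id is merged into
# the neighbouring component it touches first (raster order)
.enforce_connectivity <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  comp <- matrix(0L, h, w)
  nxt <- 0L
  stack <- integer(h * w)
  comp_of_lab <- list()
  for (start in seq_len(h * w)) {
    if (comp[start] != 0L) next
    nxt <- nxt + 1L
    top <- 1L; stack[1] <- start; comp[start] <- nxt
    val <- lab[start]
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- ((p - 1L) %% h) + 1L; cc <- ((p - 1L) %/% h) + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < h) p + 1L,
                  if (cc > 1L) p - h, if (cc < w) p + h)) {
        if (comp[q] == 0L && lab[q] == val) {
          comp[q] <- nxt; top <- top + 1L; stack[top] <- q
        }
      }
    }
  }
  sizes <- tabulate(comp, nxt)
  keep <- rep(FALSE, nxt)
  for (id in unique(as.vector(lab))) {
    comps <- unique(comp[lab == id])
    keep[comps[which.max(sizes[comps])]] <- TRUE
  }
  out <- lab
  for (ci in which(!keep)) {
    px <- which(comp == ci)
    # first neighbouring pixel outside the fragment decides the new id
    newid <- NA_integer_
    for (p in px) {
      r <- ((p - 1L) %% h) + 1L; cc <- ((p - 1L) %/% h) + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < h) p + 1L,
                  if (cc > 1L) p - h, if (cc < w) p + h)) {
        if (comp[q] != ci && keep[comp[q]]) { newid <- out[q]; break }
      }
      if (!is.na(newid)) break
    }
    if (!is.na(newid)) out[px] <- newid
  }
  out
}
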