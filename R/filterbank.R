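#' Hard-wired centre-surround filter bank with pooled summation channels
#'
#' The first hidden layer of the deep model is fixed (not learned). It has
#' two hard-wired components, both generic visuospatial machinery:
#'
#' 1. *Location-specific filters*: difference-of-Gaussians kernels at a
#'    range of receptive-field sizes, one on-centre and one off-centre
#'    detector anchored at every position of a regular tiling. Each kernel
#'    is balanced (weights sum to zero), so a uniform field elicits no
#'    response; responses are driven by local luminance discontinuities —
#'    object borders and object-sized blobs at the matching scale. This
#'    mimics retinal ganglion / LGN receptive fields, which span a range of
#'    sizes and develop independently of visual experience.
#' 2. *Pooled summation units*: for every spatial-frequency channel (one
#'    per filter scale), a small population of units that monotonically
#'    pool the channel's total rectified activity with logarithmically
#'    spaced thresholds (a thermometer intensity code with Weber–Fechner
#'    compression). These units carry compressed aggregate signals —
#'    cumulative area and contour energy per spatial scale — and cannot by
#'    themselves encode numerosity; they provide the normalisation signal
#'    that upstream layers can combine with the spatial filters.
#'
#' @param side Image side in pixels.
#' @param scales Centre Gaussian widths (pixels) of the filter scales; the
#'   surround width is `surround_ratio` times the centre width.
#' @param stride Tiling stride of kernel anchors (shared across scales).
#' @param surround_ratio Surround:centre width ratio.
#' @param max_radius Kernel half-widths are `ceiling(3 * sigma_c)` capped
#'   at this value.
#' @param pool_levels Thermometer units per channel.
#' @param pool_tau Softness (in log-activity units) of the thermometer
#'   thresholds.
#' @param pool_max Channel activity mapped to the top threshold.
#' @return A `filter_bank`: `W` (kernels x pixels weight matrix), `meta`
#'   (tibble: kernel, row, col, polarity, scale), `blocks` (kernel indices
#'   per scale channel), pooling parameters, `side`, `n_features`.
#'   Positive kernel parts are L1-normalised to 1, so rectified responses
#'   lie in `[0, 1]`.
#' @export
build_filterbank <- function(side = 30L, scales = c(0.5, 1, 2, 3.5),
                             stride = 2L, surround_ratio = 2,
                             max_radius = 14L, pool_levels = 24L,
                             pool_tau = 0.18, pool_max = 120) {
  if (stride < 1L || stride > side) {
    abort("invalid tiling stride", class = "numerosense_config")
  }
  offs_for <- function(radius) (-radius):radius
  g <- function(s, offs) {
    k <- exp(-outer(offs^2, offs^2, "+") / (2 * s^2))
    k / sum(k)
  }
  anchors <- seq(1L, side, by = stride)
  Ws <- list(); metas <- list(); blocks <- list()
  k <- 0L
  for (si in seq_along(scales)) {
    sigma_c <- scales[si]
    sigma_s <- surround_ratio * sigma_c
    radius <- min(as.integer(max_radius), max(2L, as.integer(ceiling(3 * sigma_c))))
    if (2L * radius + 1L > side) {
      abort("kernel larger than image", class = "numerosense_config")
    }
    offs <- offs_for(radius)
    dog <- g(sigma_c, offs) - g(sigma_s, offs)
    first_k <- k + 1L
    for (ac in anchors) for (ar in anchors) {
      rows <- ar + offs; cols <- ac + offs
      keep_r <- rows >= 1 & rows <= side
      keep_c <- cols >= 1 & cols <= side
      patch <- dog[keep_r, keep_c, drop = FALSE]
      # rebalance after edge cropping: scale negatives so the kernel sums to
      # 0, then normalise the positive part to unit L1
      pos <- sum(patch[patch > 0]); neg <- -sum(patch[patch < 0])
      patch[patch < 0] <- patch[patch < 0] * pos / neg
      patch <- patch / pos
      idx <- outer(rows[keep_r], (cols[keep_c] - 1L) * side, "+")
      for (pol in c(1, -1)) {
        k <- k + 1L
        w <- numeric(side * side)
        w[as.vector(idx)] <- pol * as.vector(patch)
        Ws[[k]] <- w
        metas[[k]] <- tibble::tibble(kernel = k, row = ar, col = ac,
                                     polarity = if (pol > 0) "on" else "off",
                                     scale = sigma_c)
      }
    }
    blocks[[si]] <- first_k:k
  }
  structure(list(W = do.call(rbind, Ws), meta = dplyr::bind_rows(metas),
                 blocks = blocks, side = side, stride = stride,
                 scales = scales, surround_ratio = surround_ratio,
                 pool_levels = as.integer(pool_levels), pool_tau = pool_tau,
                 pool_max = pool_max,
                 n_features = k + length(scales) * as.integer(pool_levels)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf(
    "<filter_bank  %d kernels (%d scales, on+off, stride %d) + %d pooled units>\n",
    nrow(x$W), length(x$scales), x$stride,
    length(x$scales) * x$pool_levels))
  invisible(x)
}

# thermometer-coded, baseline-subtracted pooled channel activity
pool_features <- function(resp, bank) {
  th <- seq(0.1, log1p(bank$pool_max), length.out = bank$pool_levels)
  base <- sigmoid(-th / bank$pool_tau)
  out <- lapply(bank$blocks, function(ix) {
    S <- log1p(rowSums(resp[, ix, drop = FALSE]))
    u <- sigmoid(outer(S, th, "-") / bank$pool_tau)
    sweep(u, 2, base)
  })
  do.call(cbind, out)
}

#' Propagate images through the filter bank
#'
#' Linear filtering followed by half-wave rectification (firing-rate
#' semantics: responses are non-negative and bounded by 1), then the pooled
#' summation channels appended. A blank image yields all-zero features.
#'
#' @param x A `num_img`, a binary pixel matrix, a `num_corpus`, or a list of
#'   `num_img`.
#' @param bank A [build_filterbank()] result.
#' @return For a single image, a numeric feature vector of length
#'   `bank$n_features` (kernel responses followed by pooled units); for a
#'   collection, an images x features matrix.
#' @export
propagate <- function(x, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  if (inherits(x, "num_corpus")) x <- x$images
  single <- inherits(x, "num_img") || (is.matrix(x) && !is.list(x))
  imgs <- if (single) list(x) else x
  px <- vapply(imgs, function(im) {
    m <- if (inherits(im, "num_img")) im$pixels else im
    if (nrow(m) != bank$side || ncol(m) != bank$side) {
      abort("image geometry does not match the filter bank",
            class = "numerosense_config")
    }
    as.numeric(m)
  }, numeric(bank$side^2))
  resp <- pmax(crossprod(px, t(bank$W)), 0)
  feats <- cbind(resp, pool_features(resp, bank))
  if (single) feats[1, ] else feats
}
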