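#' Stimulus images for numerosity experiments
#'
#' Binary raster images of object sets with exact control over numerosity
#' (object count), cumulative area (total "on" pixels), contour length and
#' per-item size. Objects are axis-aligned rectangles placed with at least
#' one pixel of separation in every direction, so the requested numerosity
#' always equals the number of 4-connected components.
#'
#' @name stimuli
NULL

# largest permitted item side (keeps items well inside the receptive-field
# range of the filter bank, as in bounded-dot-size displays)
.MAX_ITEM_DIM <- 8L
# within-image multiplicative item-size jitter (log-sd)
.ITEM_JITTER <- 0.25

# areas realisable as w*h with both dims <= max_dim
feasible_item_areas <- function(side = 30L, max_dim = .MAX_ITEM_DIM,
                                square = FALSE) {
  d <- min(max_dim, side - 2L)
  if (square) return(seq_len(d)^2)
  sort(unique(as.vector(outer(seq_len(d), seq_len(d)))))
}

# factor pair (h, w) for a feasible area, preferring compact aspect ratios
sample_dims <- function(area, side = 30L, max_dim = .MAX_ITEM_DIM,
                        square = FALSE) {
  d <- min(max_dim, side - 2L)
  ws <- seq_len(min(d, area))
  ws <- ws[area %% ws == 0 & area / ws <= d]
  if (square) ws <- ws[ws == area / ws]
  if (length(ws) == 0) {
    abort(sprintf("item area %d has no feasible rectangle (max side %d)", area, d),
          class = "numerosense_infeasible")
  }
  w <- ws[which.min(abs(log(ws^2 / area)) + runif(length(ws)) * 0.2)]
  c(as.integer(area / w), as.integer(w))
}

# split `total` into `n` feasible item areas: near-equal parts with
# multiplicative jitter, repaired onto the feasible set with the sum exact
sample_item_areas <- function(n, total, side = 30L, square = FALSE,
                              max_tries = 40L) {
  feas <- feasible_item_areas(side, square = square)
  if (n == 1) {
    if (!total %in% feas) {
      abort(sprintf("area %d infeasible for a single item", total),
            class = "numerosense_infeasible")
    }
    return(total)
  }
  if (total < n || total > n * max(feas)) {
    abort(sprintf("cannot split area %d into %d feasible items", total, n),
          class = "numerosense_infeasible")
  }
  for (try in seq_len(max_tries)) {
    raw <- exp(log(total / n) + rnorm(n, 0, .ITEM_JITTER))
    parts <- pmin(max(feas), pmax(1L, round(raw * total / sum(raw))))
    for (rep in seq_len(300L)) {
      bad <- !(parts %in% feas)
      if (any(bad)) {
        parts[bad] <- vapply(parts[bad],
                             function(p) max(feas[feas <= p]), numeric(1))
      }
      d <- total - sum(parts)
      if (d == 0 && !any(!(parts %in% feas))) break
      i <- sample.int(n, 1)
      if (d > 0) {
        cand <- feas[feas > parts[i] & feas <= parts[i] + max(1, d)]
        if (length(cand)) parts[i] <- max(cand)
      } else if (d < 0) {
        cand <- feas[feas < parts[i] & feas >= parts[i] + min(-1, d)]
        if (length(cand)) parts[i] <- min(cand)
      }
    }
    if (sum(parts) == total && all(parts %in% feas)) return(as.integer(parts))
  }
  abort(sprintf("could not compose area %d into %d feasible items", total, n),
        class = "numerosense_infeasible")
}

# cumulative-area levels usable for a given numerosity: every object needs
# >= 1 pixel, and mean item area is capped so items stay within the bounded
# size range (mean <= 32 pixels, i.e. level <= 32 n)
feasible_area_levels <- function(n, levels) {
  levels[levels >= n & levels <= 32L * n]
}

# place rectangles (rows of dims = c(h, w)) on a side x side grid with >= 1 px
# separation (including diagonals); returns pixel matrix or NULL on failure
place_rects <- function(dims, side, retries = 1000L) {
  px <- matrix(0L, side, side)
  blocked <- matrix(FALSE, side, side)
  ord <- order(-dims[, 1] * dims[, 2])
  for (i in ord) {
    h <- dims[i, 1]; w <- dims[i, 2]
    if (h > side || w > side) return(NULL)
    placed <- FALSE
    for (try in seq_len(retries)) {
      r0 <- sample.int(side - h + 1L, 1L)
      c0 <- sample.int(side - w + 1L, 1L)
      if (!any(blocked[r0:(r0 + h - 1L), c0:(c0 + w - 1L)])) {
        px[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 1L
        blocked[max(1L, r0 - 1L):min(side, r0 + h), max(1L, c0 - 1L):min(side, c0 + w)] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  px
}

#' Contour length of a binary image
#'
#' Number of "on" pixels with at least one "off" 4-neighbour (pixels on the
#' grid border count their out-of-grid neighbours as off).
#'
#' @param pixels Binary integer matrix (or a `num_img`).
#' @return Integer contour length.
#' @export
contour_length <- function(pixels) {
  if (inherits(pixels, "num_img")) pixels <- pixels$pixels
  m <- pixels != 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  boundary <- core & !(pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
                         pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)])
  sum(boundary)
}

#' Count objects in a binary image
#'
#' Ground-truth counting oracle: the number of 4-connected components of
#' "on" pixels (diagonal contact does not join objects).
#'
#' @param image A `num_img` or a binary integer matrix.
#' @return Integer object count.
#' @export
count_objects <- function(image) {
  px <- if (inherits(image, "num_img")) image$pixels else image
  storage.mode(px) <- "integer"
  cpp_count_components(px)
}

new_stimulus_image <- function(pixels, item_areas, seed_tag = NA_character_) {
  storage.mode(pixels) <- "integer"
  structure(
    list(
      pixels = pixels,
      n = cpp_count_components(pixels),
      area = sum(pixels),
      contour = contour_length(pixels),
      item_areas = as.integer(sort(item_areas)),
      seed_tag = seed_tag
    ),
    class = "num_img"
  )
}

#' @export
print.num_img <- function(x, ...) {
  cat(sprintf("<num_img %dx%d  N=%d  area=%d  contour=%d>\n",
              nrow(x$pixels), ncol(x$pixels), x$n, x$area, x$contour))
  invisible(x)
}

#' Generate a binary object-set image
#'
#' Places `n` disjoint axis-aligned rectangles on a square grid. Cumulative
#' area (total on-pixels) can be fixed exactly or left free, in which case
#' per-item side lengths are sampled uniformly from `dim_range`.
#'
#' @param n Number of objects (positive integer).
#' @param area_target Total on-pixel count to hit exactly, or `"free"`.
#' @param shape_family `"rect"` (free aspect ratio) or `"square"`.
#' @param side Image side length in pixels.
#' @param dim_range Integer range of item side lengths used when
#'   `area_target = "free"`.
#' @param retries Placement attempts per item before the layout is restarted.
#' @param restarts Full-layout restarts before a placement-failure error.
#' @param seed_tag Optional identifier recorded in the image metadata.
#' @return A `num_img`: list with `pixels`, `n`, `area`, `contour`,
#'   `item_areas`, `seed_tag`.
#' @export
#' @examples
#' img <- generate_image(8, area_target = 64)
#' img$n; img$area
generate_image <- function(n, area_target = "free",
                           shape_family = c("rect", "square"),
                           side = 30L, dim_range = c(1L, 4L),
                           retries = 1000L, restarts = 25L,
                           seed_tag = NA_character_) {
  shape_family <- match.arg(shape_family)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a positive integer", class = "numerosense_precondition")
  }
  n <- as.integer(n)
  fixed_area <- !identical(area_target, "free")
  if (fixed_area) {
    area_target <- as.integer(area_target)
    if (area_target < n) {
      abort(sprintf("area %d < numerosity %d: each object needs >= 1 pixel", area_target, n),
            class = "numerosense_infeasible")
    }
  }
  for (att in seq_len(restarts)) {
    if (fixed_area) {
      areas <- sample_item_areas(n, area_target, side, square = shape_family == "square")
      dims <- t(vapply(areas, sample_dims, integer(2),
                       side = side, square = shape_family == "square"))
    } else {
      h <- sample(dim_range[1]:dim_range[2], n, replace = TRUE)
      w <- if (shape_family == "square") h else sample(dim_range[1]:dim_range[2], n, replace = TRUE)
      dims <- cbind(h, w)
      areas <- h * w
    }
    px <- place_rects(dims, side, retries)
    if (!is.null(px)) {
      img <- new_stimulus_image(px, areas, seed_tag)
      if (img$n == n && (!fixed_area || img$area == area_target)) return(img)
    }
  }
  abort(sprintf("placement failure: could not place %d objects%s on a %dx%d grid",
                n, if (fixed_area) sprintf(" with total area %d", area_target) else "",
                side, side),
        class = "numerosense_placement_failure")
}

#' Corpus specification
#'
#' Describes a reproducible training corpus: image count, numerosity range,
#' grid size, cumulative-area levels, shape family and master seed. Within
#' the corpus, numerosity and cumulative area are sampled independently
#' (uniform over levels), so total area is not predictive of numerosity.
#'
#' @param image_count Number of images.
#' @param numerosity_range Integer range of numerosities, within `[1, 32]`.
#' @param image_side Grid side in pixels.
#' @param area_levels Cumulative-area levels sampled per image.
#' @param shape_family `"rect"` or `"square"`.
#' @param seed Integer seed; the corpus is bit-reproducible from these settings.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(image_count, numerosity_range = c(1L, 32L),
                        image_side = 30L, area_levels = c(32L, 64L, 128L, 256L),
                        shape_family = "rect", seed = 1L) {
  stopifnot(image_count > 0,
            numerosity_range[1] >= 1, numerosity_range[2] <= 32,
            numerosity_range[1] <= numerosity_range[2])
  structure(list(image_count = as.integer(image_count),
                 numerosity_range = as.integer(numerosity_range),
                 image_side = as.integer(image_side),
                 area_levels = as.integer(area_levels),
                 shape_family = shape_family,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate an image corpus
#'
#' @param spec A [corpus_spec()].
#' @return A `num_corpus`: list with `images` (list of `num_img`), `meta`
#'   (tibble of per-image ground truth) and the originating `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    ns <- sample(spec$numerosity_range[1]:spec$numerosity_range[2],
                 spec$image_count, replace = TRUE)
    imgs <- vector("list", spec$image_count)
    for (i in seq_len(spec$image_count)) {
      lv <- feasible_area_levels(ns[i], spec$area_levels)
      if (length(lv) == 0) {
        abort(sprintf("image %d: no area level feasible for numerosity %d", i, ns[i]),
              class = "numerosense_infeasible")
      }
      a <- if (length(lv) == 1) lv else sample(lv, 1)
      imgs[[i]] <- tryCatch(
        generate_image(ns[i], area_target = a, shape_family = spec$shape_family,
                       side = spec$image_side,
                       seed_tag = sprintf("corpus%d_img%d", spec$seed, i)),
        error = function(e) {
          abort(sprintf("corpus generation failed at image %d (N=%d, A=%d): %s",
                        i, ns[i], a, conditionMessage(e)),
                class = "numerosense_placement_failure")
        })
    }
    structure(list(images = imgs, meta = corpus_meta(imgs), spec = spec),
              class = "num_corpus")
  })
}

corpus_meta <- function(images) {
  tibble::tibble(
    id = seq_along(images),
    n = vapply(images, function(x) x$n, integer(1)),
    area = vapply(images, function(x) x$area, integer(1)),
    contour = vapply(images, function(x) x$contour, integer(1)),
    mean_item_area = vapply(images, function(x) mean(x$item_areas), numeric(1)),
    seed_tag = vapply(images, function(x) x$seed_tag, character(1))
  )
}

#' @export
print.num_corpus <- function(x, ...) {
  cat(sprintf("<num_corpus  %d images  %dx%d  N in [%d, %d]>\n",
              length(x$images), x$spec$image_side, x$spec$image_side,
              min(x$meta$n), max(x$meta$n)))
  invisible(x)
}

# ---- comparison pairs -------------------------------------------------------

new_stimulus_pair <- function(left, right, congruency) {
  if (left$n == right$n) {
    abort("equal numerosities are not a valid comparison pair",
          class = "numerosense_precondition")
  }
  structure(
    list(left = left, right = right,
         ratio = min(left$n, right$n) / max(left$n, right$n),
         correct_side = if (left$n > right$n) "left" else "right",
         congruency = congruency),
    class = "num_pair"
  )
}

#' @export
print.num_pair <- function(x, ...) {
  cat(sprintf("<num_pair  %d vs %d  ratio=%.3f  correct=%s  %s>\n",
              x$left$n, x$right$n, x$ratio, x$correct_side, x$congruency))
  invisible(x)
}

#' Pair metadata as a tibble
#'
#' @param pairs List of `num_pair` objects.
#' @return Tibble with one row per pair: numerosities, continuous properties
#'   of each side, ratio, correct side and congruency label.
#' @export
pairs_meta <- function(pairs) {
  purrr::map_dfr(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    tibble::tibble(
      pair = i,
      n_left = p$left$n, n_right = p$right$n,
      area_left = p$left$area, area_right = p$right$area,
      contour_left = p$left$contour, contour_right = p$right$contour,
      item_left = mean(p$left$item_areas), item_right = mean(p$right$item_areas),
      ratio = p$ratio, correct_side = p$correct_side, congruency = p$congruency
    )
  })
}

#' Default comparison ratios
#'
#' The numerical ratios spanned by the comparison task, as `p:q` integer
#' pairs (`1:2` through `6:7`).
#' @return List of integer vectors `c(p, q)`.
#' @export
default_ratios <- function() {
  list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 6L), c(6L, 7L))
}

#' Generate uncontrolled comparison pairs
#'
#' Pairs of corpus-style images (independent cumulative-area levels) at the
#' given numerical ratios. Continuous properties are left uncontrolled, as in
#' the unsupervised training regime.
#'
#' @param n_per_ratio Pairs per ratio.
#' @param ratios List of `c(p, q)` integer ratios (`p < q`).
#' @param numerosity_max Largest numerosity used.
#' @param area_levels Cumulative-area levels sampled independently per image.
#' @param side Grid side.
#' @param seed Optional seed.
#' @return List of `num_pair` objects.
#' @export
generate_comparison_pairs <- function(n_per_ratio, ratios = default_ratios(),
                                      numerosity_max = 32L,
                                      area_levels = c(32L, 64L, 128L, 256L),
                                      side = 30L, seed = NULL) {
  with_seed(seed, {
    pairs <- list()
    for (r in ratios) {
      p <- r[1]; q <- r[2]
      stopifnot(p >= 1, q > p)
      kmax <- floor(numerosity_max / q)
      if (kmax < 1) abort("ratio not expressible within numerosity range",
                          class = "numerosense_precondition")
      for (j in seq_len(n_per_ratio)) {
        k <- sample.int(kmax, 1)
        ns <- c(k * p, k * q)
        flip <- runif(1) < 0.5
        if (flip) ns <- rev(ns)
        imgs <- lapply(ns, function(nn) {
          lv <- feasible_area_levels(nn, area_levels)
          generate_image(nn, area_target = if (length(lv) == 1) lv else sample(lv, 1),
                         side = side)
        })
        pairs[[length(pairs) + 1]] <- new_stimulus_pair(imgs[[1]], imgs[[2]],
                                                        "uncontrolled")
      }
    }
    pairs
  })
}

#' Generate congruency-controlled comparison pairs
#'
#' Pairs are built by the same generator as the training corpus (near-equal
#' item partitions at fixed cumulative-area levels); only the assignment of
#' area levels relative to numerosity is manipulated. In a congruent pair,
#' cumulative area, contour length and mean item size all covary with
#' numerosity (the more-numerous image also has more pixels, more contour
#' and larger items); in an incongruent pair all three continuous
#' properties are anti-correlated with numerosity. Every emitted pair is
#' verified by recomputing the three properties from the pixels.
#'
#' @param ratio Integer ratio `c(p, q)` with `p < q`.
#' @param congruency `"congruent"` or `"incongruent"`.
#' @param count Number of pairs.
#' @param numerosity_max Largest numerosity of the more-numerous image.
#' @param area_levels Cumulative-area levels available to the constructor.
#' @param side Grid side.
#' @param seed Optional seed.
#' @param max_tries Construction attempts per pair before an infeasibility
#'   error.
#' @return List of `num_pair` objects.
#' @export
generate_congruency_pairs <- function(ratio, congruency = c("congruent", "incongruent"),
                                      count, numerosity_max = 32L,
                                      area_levels = c(32L, 64L, 128L, 256L),
                                      side = 30L, seed = NULL,
                                      max_tries = 1000L) {
  congruency <- match.arg(congruency)
  p <- ratio[1]; q <- ratio[2]
  if (p == q) abort("equal numerosities are not a valid comparison ratio",
                    class = "numerosense_precondition")
  if (p > q) { tmp <- p; p <- q; q <- tmp }
  stopifnot(count >= 1)
  kmax <- floor(numerosity_max / q)
  if (kmax < 1) abort("ratio not expressible within numerosity range",
                      class = "numerosense_precondition")
  # (n_small, A_small, n_large, A_large) choices whose *intended* property
  # signs match the condition; realised signs are re-verified from pixels
  combos <- list()
  for (k in seq_len(kmax)) {
    n_s <- k * p; n_l <- k * q
    for (a_s in feasible_area_levels(n_s, area_levels)) {
      for (a_l in feasible_area_levels(n_l, area_levels)) {
        ok <- if (congruency == "congruent") {
          a_l * n_s > a_s * n_l  # larger mean item size => larger A, C too
        } else {
          a_l < a_s && a_l * n_s < a_s * n_l && a_l * n_l < a_s * n_s
        }
        if (ok) combos[[length(combos) + 1]] <- c(n_s, a_s, n_l, a_l)
      }
    }
  }
  if (length(combos) == 0) {
    abort(sprintf("no %s area-level assignment exists at ratio %d:%d (area/item-size constraints unsatisfiable)",
                  congruency, p, q),
          class = "numerosense_infeasible")
  }
  with_seed(seed, {
    pairs <- vector("list", count)
    for (j in seq_len(count)) {
      pr <- NULL
      for (try in seq_len(max_tries)) {
        cmb <- combos[[sample.int(length(combos), 1)]]
        img_small <- generate_image(cmb[1], area_target = cmb[2], side = side)
        img_large <- generate_image(cmb[3], area_target = cmb[4], side = side)
        if (congruency_holds(img_small, img_large, congruency)) {
          flip <- runif(1) < 0.5
          pr <- if (flip) new_stimulus_pair(img_large, img_small, congruency)
                else new_stimulus_pair(img_small, img_large, congruency)
          break
        }
      }
      if (is.null(pr)) {
        abort(sprintf("could not construct %s pair at ratio %d:%d (property sign constraints unsatisfiable)",
                      congruency, p, q),
              class = "numerosense_infeasible")
      }
      pairs[[j]] <- pr
    }
    pairs
  })
}

# verify the sign constraints from pixel-derived properties
congruency_holds <- function(img_small, img_large, congruency) {
  d_area <- img_large$area - img_small$area
  d_contour <- img_large$contour - img_small$contour
  d_item <- mean(img_large$item_areas) - mean(img_small$item_areas)
  if (congruency == "congruent") {
    d_area > 0 && d_contour > 0 && d_item > 0
  } else {
    d_area < 0 && d_contour < 0 && d_item < 0
  }
}

# ---- persistence ------------------------------------------------------------

#' Write a corpus to disk (PNG images plus TSV metadata sidecar)
#'
#' @param corpus A `num_corpus`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_stimuli <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(corpus$images)) {
    png::writePNG(corpus$images[[i]]$pixels + 0,
                  file.path(dir, sprintf("img%05d.png", i)))
  }
  meta <- corpus$meta
  meta$item_areas <- vapply(corpus$images,
                            function(x) paste(x$item_areas, collapse = ","),
                            character(1))
  utils::write.table(meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a corpus written by [write_stimuli()]
#'
#' @param dir Directory containing the PNGs and `metadata.tsv`.
#' @return A `num_corpus` (without the originating spec).
#' @export
read_stimuli <- function(dir) {
  meta <- utils::read.table(file.path(dir, "metadata.tsv"),
                            sep = "\t", header = TRUE,
                            colClasses = c(item_areas = "character",
                                           seed_tag = "character"))
  imgs <- lapply(seq_len(nrow(meta)), function(i) {
    px <- png::readPNG(file.path(dir, sprintf("img%05d.png", i)))
    if (length(dim(px)) == 3) px <- px[, , 1]
    new_stimulus_image(matrix(as.integer(px > 0.5), nrow(px), ncol(px)),
                       as.integer(strsplit(meta$item_areas[i], ",")[[1]]),
                       meta$seed_tag[i])
  })
  structure(list(images = imgs, meta = corpus_meta(imgs), spec = NULL),
            class = "num_corpus")
}
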