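# Independent brute-force oracles used to validate the package's fast paths.
# These are deliberately naive implementations.

# 4-connected component count by breadth-first flood fill in plain R
oracle_count_components <- function(px) {
  px <- px != 0
  nr <- nrow(px); nc <- ncol(px)
  seen <- matrix(FALSE, nr, nc)
  comps <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!px[i, j] || seen[i, j]) next
    comps <- comps + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- cur[1] + d[1]; c <- cur[2] + d[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && px[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  comps
}

# contour length by explicit per-pixel neighbour checks
oracle_contour <- function(px) {
  px <- px != 0
  nr <- nrow(px); nc <- ncol(px)
  total <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!px[i, j]) next
    nb <- c(if (i > 1) px[i - 1, j] else FALSE,
            if (i < nr) px[i + 1, j] else FALSE,
            if (j > 1) px[i, j - 1] else FALSE,
            if (j < nc) px[i, j + 1] else FALSE)
    if (!all(nb)) total <- total + 1L
  }
  total
}

# direct convolution response of one DoG kernel (weight row) to an image
oracle_kernel_response <- function(w_row, px) {
  sum(w_row * as.numeric(px))
}

# build a synthetic factorial probe "corpus" carrying only metadata, for use
# with planted activation matrices
fake_probe <- function(numerosities, areas, reps) {
  design <- expand.grid(n = numerosities, area = areas)
  design <- design[rep(seq_len(nrow(design)), each = reps), ]
  structure(list(images = NULL,
                 meta = tibble::tibble(id = seq_len(nrow(design)),
                                       n = design$n, area = design$area)),
            class = "num_corpus")
}
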