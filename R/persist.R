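#' Persist a network (filter bank, generative layer, read-out) to disk
#'
#' Weights are written as plain tab-separated tables plus a JSON config
#' snapshot, so saved models are portable, diffable text.
#'
#' @param bank,layer,head Network components (`head` may be `NULL`).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_network <- function(bank, layer, head = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", row.names = FALSE, col.names = FALSE)
  wt(bank$W, "filterbank_W.tsv")
  utils::write.table(bank$meta, file.path(dir, "filterbank_meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  wt(layer$W, "generative_W.tsv")
  wt(layer$b_vis, "generative_bvis.tsv")
  wt(layer$b_hid, "generative_bhid.tsv")
  if (!is.null(head)) wt(c(head$b, head$v), "readout_w.tsv")
  cfg <- list(
    filterbank = bank[c("side", "scales", "stride", "surround_ratio",
                        "pool_levels", "pool_tau", "pool_max")],
    generative = list(n_hidden = nrow(layer$W), n_visible = ncol(layer$W),
                      epoch = layer$epoch),
    readout = if (!is.null(head)) head$settings
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load a network saved by [save_network()]
#'
#' @param dir Directory written by [save_network()].
#' @return List with `bank`, `layer` and (if present) `head`.
#' @export
load_network <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  fb <- cfg$filterbank
  bank <- build_filterbank(side = fb$side, scales = fb$scales,
                           stride = fb$stride,
                           surround_ratio = fb$surround_ratio,
                           pool_levels = fb$pool_levels,
                           pool_tau = fb$pool_tau, pool_max = fb$pool_max)
  W <- rd("filterbank_W.tsv"); dimnames(W) <- NULL
  bank$W <- W  # stored weights are authoritative
  layer <- structure(list(
    W = unname(rd("generative_W.tsv")),
    b_vis = as.numeric(rd("generative_bvis.tsv")),
    b_hid = as.numeric(rd("generative_bhid.tsv")),
    epoch = cfg$generative$epoch
  ), class = "generative_layer")
  out <- list(bank = bank, layer = layer)
  if (file.exists(file.path(dir, "readout_w.tsv"))) {
    wv <- as.numeric(rd("readout_w.tsv"))
    out$head <- structure(list(v = wv[-1], b = wv[1],
                               train_index = NA,
                               n_hidden = length(wv) - 1L,
                               settings = cfg$readout),
                          class = "readout_head")
  }
  out
}
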