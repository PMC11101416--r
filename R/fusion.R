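#' Split a latent block into contiguous column chunks
#'
#' Divides a latent tibble of width `w` into `w / chunk_width` contiguous
#' column chunks, preserving column order. The width must be divisible by
#' `chunk_width`; choose compatible latent sizes otherwise.
#'
#' @param block latent tibble (`sample_id` + latent columns), as from
#'   [encode()].
#' @param chunk_width target chunk width, typically the minimum latent width
#'   across assays.
#' @return list of numeric matrices, each `n_samples x chunk_width`.
#' @export
split_latent <- function(block, chunk_width) {
  check_omics(block, "block")
  V <- omics_values(block)
  w <- ncol(V)
  if (w %% chunk_width != 0) {
    abort(sprintf("latent width %d is not divisible by chunk width %d", w, chunk_width),
          class = "tensoromics_indivisible_latent")
  }
  map(seq_len(w / chunk_width), function(j) {
    V[, ((j - 1) * chunk_width + 1):(j * chunk_width), drop = FALSE]
  })
}

#' Fuse latent blocks into a 3-way tensor by slice-splitting
#'
#' Sets the chunk width `K` to the minimum latent width across blocks, splits
#' every wider block into contiguous chunks of width `K`, and stacks all
#' chunks along a new middle mode. The result is a `samples x slices x K`
#' array; slices are ordered by the input block order, then chunk index, and
#' the mapping is recorded in `slice_map` so the tensor can be unstacked
#' losslessly with [unstack_tensor()].
#'
#' @param blocks named list of latent tibbles sharing the same `sample_id`
#'   sequence.
#' @return a `fused_tensor`: list with `values` (3-way array), `slice_map`
#'   (tibble `slice`, `assay`, `chunk`), `sample_ids`.
#' @examples
#' # four assay blocks of widths 256, 128, 512, 256 fuse to 9 slices of 128
#' @export
stack_tensor <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  ids <- blocks[[1]]$sample_id
  ok <- map_dbl(blocks, ~ sum(.x$sample_id != ids))
  if (any(ok > 0)) {
    abort("all latent blocks must share the same sample IDs in the same order",
          class = "tensoromics_alignment_error")
  }
  widths <- map_int(blocks, ~ length(omics_features(.x)))
  K <- min(widths)
  if (any(widths %% K != 0)) {
    abort(sprintf("latent widths (%s) are not all divisible by the minimum %d",
                  paste(widths, collapse = ", "), K),
          class = "tensoromics_indivisible_latent")
  }
  names(blocks) <- names(blocks) %||% map(blocks, assay_name)
  chunks <- imap(blocks, function(b, nm) {
    cs <- split_latent(b, K)
    map2(cs, seq_along(cs), ~ list(assay = nm, chunk = .y, values = .x))
  })
  chunks <- unlist(chunks, recursive = FALSE)
  J <- length(chunks)
  X <- array(0, dim = c(length(ids), J, K))
  for (j in seq_len(J)) X[, j, ] <- chunks[[j]]$values
  if (!all(is.finite(X))) {
    abort("fused tensor contains non-finite values", class = "tensoromics_schema_error")
  }
  structure(list(values = X,
                 slice_map = tibble(slice = seq_len(J),
                                    assay = unname(map_chr(chunks, "assay")),
                                    chunk = unname(map_int(chunks, "chunk"))),
                 sample_ids = ids),
            class = "fused_tensor")
}

#' @export
print.fused_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fused_tensor> %d samples x %d slices x %d latent features\n",
              d[1], d[2], d[3]))
  print(x$slice_map, n = d[2])
  invisible(x)
}

#' Reassemble per-assay latent blocks from a fused tensor
#'
#' Inverts [stack_tensor()]: concatenates each assay's chunks in order,
#' reproducing every input latent block bit-exactly.
#'
#' @param ft a `fused_tensor`.
#' @return named list of latent tibbles.
#' @export
unstack_tensor <- function(ft) {
  stopifnot(inherits(ft, "fused_tensor"))
  sm <- ft$slice_map
  out <- map(split(sm, factor(sm$assay, levels = unique(sm$assay))), function(g) {
    g <- g[order(g$chunk), , drop = FALSE]
    V <- do.call(cbind, map(g$slice, ~ ft$values[, .x, , drop = TRUE]))
    new_omics_tbl(V, ft$sample_ids, paste0("latent_", seq_len(ncol(V))),
                  g$assay[1])
  })
  out[unique(sm$assay)]
}

#' Persist a fused tensor as text artifacts
#'
#' Writes the tensor entries as a long CSV (`sample, slice, feature, value`)
#' plus a JSON sidecar with the slice map and sample IDs.
#'
#' @param ft a `fused_tensor`.
#' @param path output path stem; `<stem>.csv` and `<stem>.json` are written.
#' @return invisibly, the two paths.
#' @export
write_fused_tensor <- function(ft, path) {
  d <- dim(ft$values)
  long <- tibble(
    sample = rep(ft$sample_ids, times = d[2] * d[3]),
    slice = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    feature = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(ft$values)
  )
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  readr::write_csv(long, csv)
  jsonlite::write_json(list(slice_map = ft$slice_map, sample_ids = ft$sample_ids),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
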