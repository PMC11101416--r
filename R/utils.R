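# internal helpers shared across modules

# An omics table is a tibble whose first column is `sample_id` and whose
# remaining columns are numeric features; the assay name travels in the
# "assay" attribute so tables stay pipeable plain tibbles.

new_omics_tbl <- function(values, sample_ids, feature_names, assay) {
  stopifnot(nrow(values) == length(sample_ids), ncol(values) == length(feature_names))
  out <- as_tibble(as.data.frame(values, stringsAsFactors = FALSE),
                   .name_repair = "minimal")
  names(out) <- feature_names
  out <- bind_cols(tibble(sample_id = sample_ids), out)
  attr(out, "assay") <- assay
  out
}

#' Assay name of an omics table
#' @param m an omics tibble as produced by [generate_cohort()] or [read_omics()]
#' @return the assay label, or `NA` if unset
#' @export
assay_name <- function(m) attr(m, "assay") %||% NA_character_

omics_values <- function(m) {
  v <- as.matrix(m[, setdiff(names(m), "sample_id"), drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- m$sample_id
  v
}

omics_features <- function(m) setdiff(names(m), "sample_id")

check_omics <- function(m, arg = "m") {
  if (!is.data.frame(m) || !"sample_id" %in% names(m)) {
    abort(sprintf("`%s` must be a data frame with a `sample_id` column", arg),
          class = "tensoromics_schema_error")
  }
  invisible(m)
}

check_survival <- function(surv) {
  req <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(req, names(surv))
  if (length(miss)) {
    abort(paste0("clinical table is missing column(s): ", paste(miss, collapse = ", ")),
          class = "tensoromics_schema_error")
  }
  if (any(surv$os_time < 0, na.rm = TRUE)) {
    abort("os_time must be non-negative", class = "tensoromics_schema_error")
  }
  if (!all(surv$os_event %in% c(0, 1))) {
    abort("os_event must be 0/1", class = "tensoromics_schema_error")
  }
  invisible(surv)
}

# derive a stream-specific 31-bit seed from a master seed, so that every
# stochastic stage gets an independent but reproducible stream
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% .Machine$integer.max)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Moore-Penrose pseudo-inverse with a plain solve() fast path
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
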