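#' Read an omics assay table
#'
#' Reads a delimited text file into an omics tibble. The LinkedOmics exports
#' come in both orientations; if `clinical_ids` is supplied the orientation is
#' auto-detected by checking which margin matches the clinical sample IDs, and
#' the matrix is transposed to samples-as-rows if needed.
#'
#' @param path TSV/CSV file with a header row; the first column holds either
#'   sample IDs (samples-as-rows) or feature names (samples-as-columns).
#' @param assay label recorded as the assay name; defaults to the file stem.
#' @param clinical_ids optional character vector of known sample IDs used for
#'   orientation detection.
#' @return an omics tibble (`sample_id` + numeric feature columns).
#' @export
read_omics <- function(path, assay = NULL, clinical_ids = NULL) {
  if (!file.exists(path)) {
    abort(paste0("assay file not found: ", path), class = "tensoromics_path_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  first <- names(raw)[1]
  row_ids <- as.character(raw[[first]])
  if (!is.null(clinical_ids)) {
    hit_rows <- mean(row_ids %in% clinical_ids)
    hit_cols <- mean(names(raw)[-1] %in% clinical_ids)
    if (hit_cols > hit_rows) {
      vals <- t(as.matrix(raw[, -1]))
      out <- new_omics_tbl(vals, rownames(vals), row_ids,
                           assay %||% sub("\\.[^.]+$", "", basename(path)))
      return(out)
    }
  }
  vals <- as.matrix(raw[, -1])
  new_omics_tbl(vals, row_ids, colnames(vals),
                assay %||% sub("\\.[^.]+$", "", basename(path)))
}

#' Read a clinical survival table
#'
#' @param path TSV/CSV with columns `sample_id` (or first column as ID),
#'   `os_time`, `os_event`, and optionally `tumor_purity`.
#' @return a clinical tibble.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("clinical file not found: ", path), class = "tensoromics_path_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  clin <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  if (!"sample_id" %in% names(clin)) names(clin)[1] <- "sample_id"
  clin$sample_id <- as.character(clin$sample_id)
  check_survival(clin)
  clin
}

#' Restrict assays and clinical data to their common samples
#'
#' Intersects the sample IDs of every assay and the clinical table and
#' returns all tables restricted to that intersection in one canonical
#' (lexicographically sorted) order.
#'
#' @param assays named list of omics tibbles.
#' @param clinical clinical tibble.
#' @return list with `assays` and `clinical`, all sharing an identical
#'   `sample_id` sequence.
#' @export
align_samples <- function(assays, clinical) {
  stopifnot(length(assays) >= 1)
  check_survival(clinical)
  common <- Reduce(intersect, c(map(assays, ~ .x$sample_id), list(clinical$sample_id)))
  if (length(common) == 0) {
    abort("no samples are shared by all assays and the clinical table",
          class = "tensoromics_no_common_samples")
  }
  common <- sort(common)
  assays <- map(assays, function(m) {
    a <- assay_name(m)
    out <- m[match(common, m$sample_id), , drop = FALSE]
    attr(out, "assay") <- a
    out
  })
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  list(assays = assays, clinical = clinical)
}

#' Split a cohort into train and test partitions
#'
#' The training set holds `floor(train_fraction * n)` samples. The partition
#' is a deterministic function of the sorted sample-ID set and the seed only,
#' and the same split is applied to every assay and the clinical table.
#'
#' @param assays named list of aligned omics tibbles.
#' @param clinical aligned clinical tibble.
#' @param train_fraction fraction of samples assigned to training (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test`, each a list of `assays` and
#'   `clinical`.
#' @export
split_train_test <- function(assays, clinical, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be strictly between 0 and 1",
          class = "tensoromics_invalid_spec")
  }
  ids <- sort(clinical$sample_id)
  n <- length(ids)
  if (n < 2) abort("need at least 2 samples to split", class = "tensoromics_cannot_split")
  n_train <- floor(train_fraction * n)
  train_ids <- withr::with_seed(seed, sort(sample(ids, n_train)))
  test_ids <- setdiff(ids, train_ids)
  take <- function(keep) {
    list(
      assays = map(assays, function(m) {
        a <- assay_name(m)
        out <- m[m$sample_id %in% keep, , drop = FALSE]
        attr(out, "assay") <- a
        out
      }),
      clinical = clinical[clinical$sample_id %in% keep, , drop = FALSE]
    )
  }
  list(train = take(train_ids), test = take(test_ids))
}

#' Impute missing values by train-fitted feature means
#'
#' Each missing entry is replaced by the mean of the observed entries in its
#' feature column. Means are computed on the training partition (when
#' `params` is `NULL`) and must be reused for the test partition by passing
#' the returned `params`. Zeros are data and are preserved. A feature with no
#' observed training value is dropped from both partitions with a warning.
#'
#' @param m omics tibble.
#' @param policy only `"feature-mean"` is supported.
#' @param params `NULL` to fit on `m`, or the `params` element of a previous
#'   call to reuse train-fitted means.
#' @return list with `data` (imputed omics tibble) and `params` (tibble of
#'   feature means with a `fitted_on` attribute).
#' @export
impute_missing <- function(m, policy = "feature-mean", params = NULL) {
  if (!identical(policy, "feature-mean")) {
    abort("only policy = \"feature-mean\" is supported", class = "tensoromics_invalid_spec")
  }
  check_omics(m)
  V <- omics_values(m)
  if (is.null(params)) {
    mu <- colMeans(V, na.rm = TRUE)
    dropped <- names(mu)[!is.finite(mu)]
    if (length(dropped)) {
      warn(paste0("dropping ", length(dropped),
                  " feature(s) with no observed training value: ",
                  paste(head(dropped, 5), collapse = ", ")))
      mu <- mu[is.finite(mu)]
    }
    params <- tibble(feature = names(mu), mean = unname(mu))
    attr(params, "fitted_on") <- "train"
  }
  keep <- intersect(colnames(V), params$feature)
  V <- V[, keep, drop = FALSE]
  mu <- setNames(params$mean, params$feature)[keep]
  na_idx <- which(is.na(V), arr.ind = TRUE)
  if (nrow(na_idx)) V[na_idx] <- mu[na_idx[, 2]]
  list(data = new_omics_tbl(V, m$sample_id, keep, assay_name(m)), params = params)
}

#' Min-max scale features to the training range
#'
#' Applies `x' = (x - min) / (max - min)` per feature. When `params` is
#' `NULL`, minima and maxima are fitted on `m` (the training partition);
#' passing the returned `params` applies the training scaling to a test
#' partition, where values outside `[0, 1]` are permitted (never clipped).
#' Constant features map to 0.
#'
#' @param m omics tibble with no missing values.
#' @param params `NULL` to fit, or a previously returned `params`.
#' @return list with `data` (scaled omics tibble) and `params` (tibble of
#'   per-feature `min` and `max`, with a `fitted_on` attribute).
#' @export
minmax_scale <- function(m, params = NULL) {
  check_omics(m)
  V <- omics_values(m)
  if (anyNA(V)) abort("minmax_scale requires complete data; impute first",
                      class = "tensoromics_schema_error")
  if (is.null(params)) {
    params <- tibble(feature = colnames(V),
                     min = apply(V, 2, min), max = apply(V, 2, max))
    attr(params, "fitted_on") <- "train"
  }
  stopifnot(identical(params$feature, colnames(V)))
  rng <- params$max - params$min
  scaled <- sweep(V, 2, params$min, "-")
  nz <- rng > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, rng[nz], "/")
  scaled[, !nz] <- 0
  list(data = new_omics_tbl(scaled, m$sample_id, colnames(V), assay_name(m)),
       params = params)
}

#' Pad an assay with zero-valued synthetic features
#'
#' Appends constant-zero columns named `pad_0 .. pad_k` until the assay
#' reaches `target_dim` features, so small assays (such as focal copy-number
#' panels) can be fed to an autoencoder with a wider bottleneck.
#'
#' @param m omics tibble.
#' @param target_dim desired feature count, at least the current count.
#' @return the padded omics tibble.
#' @export
pad_features <- function(m, target_dim) {
  check_omics(m)
  d <- length(omics_features(m))
  if (target_dim < d) {
    abort(sprintf("target_dim (%d) is below the current feature count (%d)",
                  target_dim, d), class = "tensoromics_invalid_target")
  }
  if (target_dim == d) return(m)
  k <- target_dim - d
  pads <- matrix(0, nrow(m), k, dimnames = list(NULL, paste0("pad_", seq_len(k) - 1)))
  new_omics_tbl(cbind(omics_values(m), pads), m$sample_id,
                c(omics_features(m), colnames(pads)), assay_name(m))
}
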