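# Attribution of encoder latent coordinates to input biomarkers.
# Exact Kernel SHAP enumerates coalitions with the Shapley weights
# |S|!(d-|S|-1)!/d!; excluded features are imputed with the background-mean
# vector, so per sample sum(phi) = g(x) - g(baseline) exactly.

as_feature_matrix <- function(x, feature_names = NULL) {
  if (is.data.frame(x)) {
    if ("sample_id" %in% names(x)) return(omics_values(x))
    return(as.matrix(x))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.null(feature_names) && is.null(colnames(x))) colnames(x) <- feature_names
  x
}

new_shap_attribution <- function(assay, feature_names, phi, baseline, method,
                                 latent_index, g_x, g_baseline) {
  structure(list(assay = assay, feature_names = feature_names, phi = phi,
                 baseline = baseline, method = method,
                 latent_index = latent_index, g_x = g_x,
                 g_baseline = g_baseline),
            class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf("<shap_attribution> %s SHAP for latent %d: %d sample(s) x %d feature(s)\n",
              x$method, x$latent_index, nrow(x$phi), ncol(x$phi)))
  invisible(x)
}

shapley_weights <- function(d) {
  # w[s + 1] = s! (d - s - 1)! / d!  for coalition size s = 0 .. d-1
  exp(lfactorial(0:(d - 1)) + lfactorial(d - 1 - 0:(d - 1)) - lfactorial(d))
}

kernel_shap_exact_row <- function(g_masked, masks, d) {
  # g_masked[b]: value with coalition given by bit pattern masks[b, ]
  w <- shapley_weights(d)
  sizes <- rowSums(masks)
  phi <- numeric(d)
  for (i in seq_len(d)) {
    with_i <- masks[, i] == 1
    phi[i] <- sum(w[sizes[with_i]] * g_masked[with_i]) -
      sum(w[sizes[!with_i] + 1] * g_masked[!with_i])
  }
  phi
}

kernel_shap_sampled_row <- function(x_row, baseline, value_fun, d, n_coalitions,
                                    seed) {
  v0 <- value_fun(matrix(0, 1, d))
  v1 <- value_fun(matrix(1, 1, d))
  all_nontrivial <- 2^d - 2
  if (d <= 20 && n_coalitions >= all_nontrivial) {
    Z <- t(vapply(seq_len(all_nontrivial),
                  function(b) as.integer(intToBits(b)[1:d]), integer(d)))
  } else {
    Z <- withr::with_seed(seed, {
      sizes <- sample(seq_len(d - 1), n_coalitions, replace = TRUE,
                      prob = 1 / (seq_len(d - 1) * (d - seq_len(d - 1))))
      t(vapply(sizes, function(s) {
        z <- integer(d); z[sample.int(d, s)] <- 1L; z
      }, integer(d)))
    })
  }
  s <- rowSums(Z)
  w <- (d - 1) / (choose(d, s) * s * (d - s))
  v <- value_fun(Z)
  # solve the SHAP-kernel weighted regression with the efficiency constraint
  # sum(phi) = v(full) - v(empty) eliminated into the last coefficient
  delta <- v1 - v0
  y <- v - v0 - Z[, d] * delta
  A <- sweep(Z[, -d, drop = FALSE], 1, Z[, d], "-")
  WA <- A * w
  beta <- solve(crossprod(WA, A), crossprod(WA, y))
  phi <- c(beta, delta - sum(beta))
  phi
}

#' Kernel SHAP attribution of one latent coordinate
#'
#' Quantifies how much each input feature moves the chosen latent coordinate
#' of a trained encoder, relative to a background population. Excluded
#' features are imputed with the background mean vector. Exact mode
#' enumerates all `2^d` coalitions with the Shapley weights (limited to
#' `d <= 12`); sampled mode solves the SHAP-kernel weighted regression over
#' sampled coalitions (or all of them when the budget allows, which
#' reproduces the exact values).
#'
#' @param model a [train_autoencoder()] result.
#' @param x samples to explain: omics tibble, matrix, or single row vector.
#' @param background background samples (same feature space).
#' @param latent_index which latent coordinate to explain.
#' @param mode `"auto"` (exact when `d <= 12`), `"exact"` or `"sampled"`.
#' @param n_coalitions coalition budget for sampled mode.
#' @param seed seed for coalition sampling.
#' @return a `shap_attribution`: `phi` is a samples x features matrix for the
#'   chosen latent coordinate.
#' @export
kernel_shap_latent <- function(model, x, background, latent_index = 1,
                               mode = c("auto", "exact", "sampled"),
                               n_coalitions = 2048, seed = 1L) {
  mode <- match.arg(mode)
  X <- as_feature_matrix(x, model$feature_names)
  BG <- as_feature_matrix(background, model$feature_names)
  d <- ncol(X)
  stopifnot(ncol(BG) == d, latent_index >= 1,
            latent_index <= model$spec$latent_dim)
  if (mode == "auto") mode <- if (d <= 12) "exact" else "sampled"
  if (mode == "exact" && d > 12) {
    abort(sprintf("exact mode enumerates 2^%d coalitions; use mode = \"sampled\"", d),
          class = "tensoromics_too_many_features")
  }
  baseline <- colMeans(BG)
  g_of <- function(M) encode_matrix(model, M)[, latent_index]
  phi <- matrix(0, nrow(X), d, dimnames = list(rownames(X), colnames(X)))
  if (mode == "exact") {
    masks <- t(vapply(0:(2^d - 1), function(b) as.integer(intToBits(b)[1:d]),
                      integer(d)))
    for (r in seq_len(nrow(X))) {
      M <- sweep(masks, 2, X[r, ], "*") + sweep(1 - masks, 2, baseline, "*")
      phi[r, ] <- kernel_shap_exact_row(g_of(M), masks, d)
    }
  } else {
    for (r in seq_len(nrow(X))) {
      value_fun <- function(Z) {
        M <- sweep(Z, 2, X[r, ], "*") + sweep(1 - Z, 2, baseline, "*")
        g_of(M)
      }
      phi[r, ] <- kernel_shap_sampled_row(X[r, ], baseline, value_fun, d,
                                          n_coalitions,
                                          derive_seed(seed, paste0("ks", r)))
    }
  }
  new_shap_attribution(model$assay, colnames(X) %||% model$feature_names, phi,
                       baseline, "kernel", latent_index,
                       g_of(X), g_of(matrix(baseline, 1)))
}

#' Gradient SHAP attribution of one latent coordinate
#'
#' Approximates each feature's contribution as the displacement from the
#' baseline times the expected encoder gradient along the baseline-to-sample
#' path, averaged over baselines: an integrated-gradients estimate. With
#' `n_steps = 1` and a single baseline this is exactly the single-point form
#' `phi_i = (x_i - x'_i) * dg/dx_i |_{x = x'}`.
#'
#' @param model a [train_autoencoder()] result.
#' @param x samples to explain.
#' @param baselines baseline samples.
#' @param latent_index which latent coordinate to explain.
#' @param n_steps number of path positions (left endpoints `t = (j-1)/n`).
#' @return a `shap_attribution`.
#' @export
gradient_shap_latent <- function(model, x, baselines, latent_index = 1,
                                 n_steps = 50) {
  stopifnot(n_steps >= 1)
  X <- as_feature_matrix(x, model$feature_names)
  BG <- as_feature_matrix(baselines, model$feature_names)
  d <- ncol(X)
  phi <- matrix(0, nrow(X), d, dimnames = list(rownames(X), colnames(X)))
  ts <- (seq_len(n_steps) - 1) / n_steps
  for (r in seq_len(nrow(X))) {
    acc <- matrix(0, 1, d)
    for (m in seq_len(nrow(BG))) {
      pts <- matrix(rep(BG[m, ], n_steps), n_steps, byrow = TRUE) +
        ts %o% (X[r, ] - BG[m, ])
      g <- encoder_input_gradient(model, pts, latent_index)
      acc <- acc + matrix(X[r, ] - BG[m, ], 1) * matrix(colMeans(g), 1)
    }
    phi[r, ] <- acc / nrow(BG)
  }
  g_of <- function(M) encode_matrix(model, M)[, latent_index]
  new_shap_attribution(model$assay, colnames(X) %||% model$feature_names, phi,
                       colMeans(BG), "gradient", latent_index,
                       g_of(X), mean(g_of(BG)))
}

#' Rank biomarkers by SHAP attribution
#'
#' Aggregates per-sample attributions per feature and ranks features by the
#' absolute aggregate, keeping the signed score so direction is preserved
#' (positive = increases the latent value).
#'
#' @param attr a `shap_attribution`.
#' @param k how many features to return.
#' @param aggregate `"mean_abs"` (mean of `|phi|`) or `"mean"` (signed mean).
#' @return tibble `rank`, `feature`, `score` (signed mean phi), `abs_score`
#'   (the ranking key under the chosen aggregate).
#' @export
top_biomarkers <- function(attr, k = 10, aggregate = c("mean_abs", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(attr, "shap_attribution"), k <= ncol(attr$phi))
  signed <- colMeans(attr$phi)
  key <- if (aggregate == "mean_abs") colMeans(abs(attr$phi)) else abs(signed)
  ord <- order(key, decreasing = TRUE)[seq_len(k)]
  tibble(rank = seq_len(k), feature = attr$feature_names[ord],
         score = unname(signed[ord]), abs_score = unname(key[ord]))
}

#' Fold enrichment with a hypergeometric test
#'
#' Computes `FE = (subset_with / subset_size) / (bg_with / bg_size)` and the
#' hypergeometric upper-tail probability of drawing at least `subset_with`
#' annotated genes in a subset of `subset_size` from the background.
#'
#' @param subset_with annotated genes in the subset.
#' @param subset_size subset size.
#' @param bg_with annotated genes in the background.
#' @param bg_size background size.
#' @param term optional term label carried through to the result.
#' @return one-row tibble: `term`, `subset_with`, `subset_size`, `bg_with`,
#'   `bg_size`, `fold_enrichment`, `p_value`.
#' @export
fold_enrichment <- function(subset_with, subset_size, bg_with, bg_size,
                            term = NA_character_) {
  if (bg_with == 0) {
    abort("no background gene carries the term; enrichment undefined",
          class = "tensoromics_undefined_enrichment")
  }
  if (subset_with > subset_size || subset_size > bg_size || subset_with > bg_with) {
    abort("inconsistent counts", class = "tensoromics_invalid_spec")
  }
  fe <- (subset_with / subset_size) / (bg_with / bg_size)
  p <- phyper(subset_with - 1, bg_with, bg_size - bg_with, subset_size,
              lower.tail = FALSE)
  tibble(term = term, subset_with = subset_with, subset_size = subset_size,
         bg_with = bg_with, bg_size = bg_size, fold_enrichment = fe,
         p_value = p)
}

#' Fold enrichment of every term for a gene subset
#'
#' @param subset_genes character vector of selected genes (e.g. top SHAP
#'   biomarkers).
#' @param annotations two-column data frame `gene`, `term` (as read from a
#'   gene-set TSV).
#' @param background_genes the background universe; defaults to all annotated
#'   genes.
#' @return tibble of [fold_enrichment()] rows, one per term present in the
#'   subset, sorted by p-value.
#' @export
fold_enrichment_table <- function(subset_genes, annotations,
                                  background_genes = unique(annotations$gene)) {
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  annotations <- annotations[annotations$gene %in% background_genes, , drop = FALSE]
  subset_genes <- intersect(subset_genes, background_genes)
  terms <- unique(annotations$term[annotations$gene %in% subset_genes])
  out <- map(terms, function(tm) {
    genes_with <- unique(annotations$gene[annotations$term == tm])
    fold_enrichment(length(intersect(subset_genes, genes_with)),
                    length(subset_genes), length(genes_with),
                    length(background_genes), term = tm)
  })
  arrange(bind_rows(out), .data$p_value)
}
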