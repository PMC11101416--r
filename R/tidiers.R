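#' Tidy CP factors into a long tibble
#'
#' @param x a `cp_factors` object.
#' @param ... unused.
#' @return tibble with `mode` (`"samples"`, `"slices"`, `"features"`),
#'   `label`, `component`, `value`, `lambda`.
#' @export
tidy.cp_factors <- function(x, ...) {
  one <- function(M, mode) {
    lbl <- rownames(M) %||% as.character(seq_len(nrow(M)))
    tibble(mode = mode,
           label = rep(lbl, times = ncol(M)),
           component = rep(seq_len(ncol(M)), each = nrow(M)),
           value = as.vector(M),
           lambda = rep(x$lambda, each = nrow(M)))
  }
  bind_rows(one(x$A, "samples"), one(x$B, "slices"), one(x$C, "features"))
}

#' One-row summary of a CP fit
#'
#' @param x a `cp_factors` object.
#' @param ... unused.
#' @return tibble with `rank`, `fit`, `n_iter`, `converged`, `lambda_max`,
#'   `lambda_min`.
#' @export
glance.cp_factors <- function(x, ...) {
  tibble(rank = x$rank, fit = x$fit, n_iter = x$n_iter, converged = x$converged,
         lambda_max = max(x$lambda), lambda_min = min(x$lambda))
}

#' Tidy Kaplan-Meier curves
#'
#' @param x a `survfit_result` from [km_logrank()].
#' @param ... unused.
#' @return the per-group KM step function as a tibble (`group`, `time`,
#'   `survival`, `n_risk`, `n_event`).
#' @export
tidy.survfit_result <- function(x, ...) x$km

#' One-row summary of a survival comparison
#'
#' @param x a `survfit_result`.
#' @param ... unused.
#' @return tibble with `logrank_chisq`, `logrank_p`, `cox_hr`, `cox_ci_low`,
#'   `cox_ci_high`, `n_groups`.
#' @export
glance.survfit_result <- function(x, ...) {
  tibble(logrank_chisq = x$logrank_chisq, logrank_p = x$logrank_p,
         cox_hr = x$cox_hr, cox_ci_low = x$cox_ci[1], cox_ci_high = x$cox_ci[2],
         n_groups = length(x$n_per_group))
}

#' Tidy SHAP attributions into a long tibble
#'
#' @param x a `shap_attribution`.
#' @param ... unused.
#' @return tibble with `sample`, `feature`, `phi`.
#' @export
tidy.shap_attribution <- function(x, ...) {
  tibble(sample = rep(rownames(x$phi) %||% as.character(seq_len(nrow(x$phi))),
                      times = ncol(x$phi)),
         feature = rep(x$feature_names, each = nrow(x$phi)),
         phi = as.vector(x$phi))
}

#' Tidy an autoencoder training history
#'
#' @param x a `trained_autoencoder`.
#' @param ... unused.
#' @return the history tibble (`epoch`, `train_loss`).
#' @export
tidy.trained_autoencoder <- function(x, ...) x$history

#' One-row summary of a trained autoencoder
#'
#' @param x a `trained_autoencoder`.
#' @param ... unused.
#' @return tibble with `assay`, `input_dim`, `latent_dim`, `n_hidden`,
#'   `initial_loss`, `final_loss`.
#' @export
glance.trained_autoencoder <- function(x, ...) {
  tibble(assay = x$assay %||% NA_character_,
         input_dim = x$spec$input_dim, latent_dim = x$spec$latent_dim,
         n_hidden = length(x$spec$hidden_widths),
         initial_loss = x$history$train_loss[1],
         final_loss = tail(x$history$train_loss, 1))
}
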