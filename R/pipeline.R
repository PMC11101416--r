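#' Configure the end-to-end multi-omics pipeline
#'
#' Collects every stage's settings in one object. Data can be given as file
#' paths (`assay_paths`, `clinical_path`) or as in-memory tables (`assays`,
#' `clinical`). All stochastic stages derive their streams from `seed`, so an
#' identical config reproduces all numeric outputs bit-identically.
#'
#' @param assay_paths named character vector of assay TSV/CSV paths.
#' @param clinical_path clinical table path.
#' @param assays,clinical in-memory alternatives to the paths.
#' @param train_fraction training fraction (default 0.7).
#' @param latent_dims named (or scalar) latent size per assay, used as-is.
#' @param latent_candidates optional vector of candidate latent sizes; when
#'   set, [select_latent_size()] picks per assay by CV and `latent_dims` is
#'   ignored.
#' @param cv_folds folds for latent-size selection.
#' @param epochs,learning_rate,batch_size autoencoder training settings.
#' @param max_width first-hidden-layer cap.
#' @param pad_to padding target for assays narrower than their latent size;
#'   default `max(512, 2 * latent)`.
#' @param fusion_order assay order for tensor stacking; default input order.
#' @param cp_rank fixed CP rank, or `NULL` to select by CORCONDIA.
#' @param cp_candidate_ranks ranks scanned when `cp_rank` is `NULL`.
#' @param l1_penalty,cp_max_iter,cp_tol RALS settings.
#' @param corcondia_threshold core-consistency cutoff for rank selection.
#' @param cluster_k number of risk groups (2 or 3).
#' @param cluster_distance `"canberra"` or `"chebyshev"`.
#' @param survival_horizon optional administrative-censoring horizon in days
#'   (e.g. 3000); `NULL` to disable.
#' @param purity_threshold tumor-purity binarization cut.
#' @param purity_models classifiers for [classify_purity()]; `NULL` skips the
#'   purity stage even when purity is present.
#' @param n_explain samples per assay to attribute with SHAP (0 skips the
#'   stage).
#' @param n_background background samples for SHAP.
#' @param shap_coalitions coalition budget for sampled Kernel SHAP.
#' @param gradient_threshold assays with more features than this use Gradient
#'   SHAP instead of Kernel SHAP.
#' @param seed master seed.
#' @param outdir optional directory for artifacts; `NULL` keeps everything in
#'   memory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(assay_paths = NULL, clinical_path = NULL,
                            assays = NULL, clinical = NULL,
                            train_fraction = 0.7,
                            latent_dims = 64, latent_candidates = NULL,
                            cv_folds = 10,
                            epochs = 10, learning_rate = 0.001, batch_size = 128,
                            max_width = 1024, pad_to = NULL,
                            fusion_order = NULL,
                            cp_rank = NULL, cp_candidate_ranks = 1:6,
                            l1_penalty = 0.01, cp_max_iter = 500, cp_tol = 1e-7,
                            corcondia_threshold = 90,
                            cluster_k = 2,
                            cluster_distance = c("canberra", "chebyshev"),
                            survival_horizon = NULL,
                            purity_threshold = 0.7,
                            purity_models = c("logistic", "random_forest"),
                            n_explain = 0, n_background = 20,
                            shap_coalitions = 512, gradient_threshold = 1000,
                            seed = 1L, outdir = NULL) {
  if (is.null(assay_paths) && is.null(assays)) {
    abort("provide assay_paths or in-memory assays", class = "tensoromics_config_error")
  }
  if (is.null(clinical_path) && is.null(clinical)) {
    abort("provide clinical_path or an in-memory clinical table",
          class = "tensoromics_config_error")
  }
  structure(list(
    assay_paths = assay_paths, clinical_path = clinical_path,
    assays = assays, clinical = clinical,
    train_fraction = train_fraction,
    latent_dims = latent_dims, latent_candidates = latent_candidates,
    cv_folds = cv_folds, epochs = epochs, learning_rate = learning_rate,
    batch_size = batch_size, max_width = max_width, pad_to = pad_to,
    fusion_order = fusion_order,
    cp_rank = cp_rank, cp_candidate_ranks = cp_candidate_ranks,
    l1_penalty = l1_penalty, cp_max_iter = cp_max_iter, cp_tol = cp_tol,
    corcondia_threshold = corcondia_threshold,
    cluster_k = cluster_k, cluster_distance = match.arg(cluster_distance),
    survival_horizon = survival_horizon,
    purity_threshold = purity_threshold, purity_models = purity_models,
    n_explain = n_explain, n_background = n_background,
    shap_coalitions = shap_coalitions, gradient_threshold = gradient_threshold,
    seed = as.integer(seed), outdir = outdir
  ), class = "pipeline_config")
}

#' Load a pipeline config from a YAML or JSON file
#'
#' @param path config file; keys mirror the arguments of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path),
                                class = "tensoromics_config_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$assay_paths)) raw$assay_paths <- unlist(raw$assay_paths)
  do.call(pipeline_config, raw)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
          class = "tensoromics_stage_error", parent = e)
  })
}

#' Run the full multi-omics risk-stratification pipeline
#'
#' Executes preprocessing (align, split, impute, scale, pad), per-assay
#' autoencoding, slice-split tensor fusion, CP decomposition with CORCONDIA
#' rank selection, hierarchical risk clustering with Kaplan-Meier / log-rank /
#' Cox evaluation per partition, optional tumor-purity classification, and
#' optional SHAP biomarker attribution. When `cfg$outdir` is set, artifacts
#' (latents, factors, curves, summary JSON) are written there.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_result` list; `$summary` is a plain machine-readable
#'   list (also written as `summary.json` when `outdir` is set).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seed <- cfg$seed

  clinical <- with_stage("load", {
    if (!is.null(cfg$clinical)) cfg$clinical else read_clinical(cfg$clinical_path)
  })
  assays <- with_stage("load", {
    if (!is.null(cfg$assays)) cfg$assays else {
      imap(as.list(cfg$assay_paths),
           ~ read_omics(.x, assay = .y, clinical_ids = clinical$sample_id))
    }
  })

  aligned <- with_stage("align", align_samples(assays, clinical))
  parts <- with_stage("split",
    split_train_test(aligned$assays, aligned$clinical, cfg$train_fraction,
                     seed = derive_seed(seed, "split")))

  assay_names <- names(aligned$assays)
  latent_dims <- cfg$latent_dims
  if (length(latent_dims) == 1 && is.null(names(latent_dims))) {
    latent_dims <- setNames(rep(latent_dims, length(assay_names)), assay_names)
  }

  hyper_for <- function(nm) train_hyper(cfg$learning_rate, cfg$epochs,
                                        cfg$batch_size,
                                        seed = derive_seed(seed, paste0("ae_", nm)))

  prep <- with_stage("preprocess", map(assay_names, function(nm) {
    tr <- parts$train$assays[[nm]]; te <- parts$test$assays[[nm]]
    imp <- impute_missing(tr)
    tr <- imp$data
    te <- impute_missing(te, params = imp$params)$data
    sc <- minmax_scale(tr)
    tr <- sc$data
    te <- minmax_scale(te, params = sc$params)$data
    list(train = tr, test = te)
  }))
  names(prep) <- assay_names

  selected_latent <- list()
  models <- list()
  latents <- with_stage("autoencode", map(assay_names, function(nm) {
    tr <- prep[[nm]]$train; te <- prep[[nm]]$test
    d <- length(omics_features(tr))
    ld <- if (!is.null(cfg$latent_candidates)) {
      as.integer(select_latent_size(tr, cfg$latent_candidates, cfg$cv_folds,
                                    hyper_for(nm), cfg$max_width))
    } else unname(latent_dims[[nm]])
    if (ld >= d) {
      target <- cfg$pad_to %||% max(512, 2 * ld)
      tr <- pad_features(tr, target)
      te <- pad_features(te, target)
      d <- target
    }
    spec <- build_encoder_spec(d, ld, cfg$max_width)
    model <- train_autoencoder(tr, spec, hyper_for(nm))
    selected_latent[[nm]] <<- ld
    models[[nm]] <<- model
    list(train = encode(model, tr), test = encode(model, te))
  }))
  names(latents) <- assay_names

  order_ <- cfg$fusion_order %||% assay_names
  tensors <- with_stage("fuse", list(
    train = stack_tensor(map(setNames(order_, order_), ~ latents[[.x]]$train)),
    test = stack_tensor(map(setNames(order_, order_), ~ latents[[.x]]$test))
  ))

  rcfg <- rals_config(cfg$l1_penalty, cfg$cp_max_iter, cfg$cp_tol,
                      seed = derive_seed(seed, "cp"))
  rank_sel <- with_stage("decompose", {
    if (!is.null(cfg$cp_rank)) {
      list(rank = as.integer(cfg$cp_rank), diagnostics = NULL)
    } else {
      select_rank(tensors$train, cfg$cp_candidate_ranks, rcfg,
                  cfg$corcondia_threshold)
    }
  })
  rank <- rank_sel$rank
  rank_diag <- rank_sel$diagnostics
  cp <- with_stage("decompose", list(
    train = rals_cp(tensors$train, rank, rcfg),
    test = rals_cp(tensors$test, rank, rcfg)
  ))

  stratify_one <- function(f, clin) {
    labels <- hierarchical_clusters(f$A, k = cfg$cluster_k,
                                    distance = cfg$cluster_distance)
    surv <- if (!is.null(cfg$survival_horizon)) {
      truncate_survival(clin, cfg$survival_horizon)
    } else clin
    groups <- assign_risk_labels(labels, surv)
    list(groups = groups, fit = km_logrank(groups, surv))
  }
  strat <- with_stage("stratify", list(
    train = stratify_one(cp$train, parts$train$clinical),
    test = stratify_one(cp$test, parts$test$clinical)
  ))

  purity <- NULL
  has_purity <- "tumor_purity" %in% names(aligned$clinical) &&
    !all(is.na(aligned$clinical$tumor_purity)) && !is.null(cfg$purity_models)
  if (has_purity) {
    purity <- with_stage("classify_purity",
      classify_purity(cp_project(cp$train, tensors$train),
                      cp_project(cp$train, tensors$test),
                      parts$train$clinical$tumor_purity,
                      parts$test$clinical$tumor_purity,
                      threshold = cfg$purity_threshold,
                      models = cfg$purity_models,
                      seed = derive_seed(seed, "purity")))
  }

  shap <- NULL
  if (cfg$n_explain > 0) {
    shap <- with_stage("explain", map(assay_names, function(nm) {
      model <- models[[nm]]
      tr <- prep[[nm]]$train; te <- prep[[nm]]$test
      if (model$spec$input_dim > length(omics_features(tr))) {
        tr <- pad_features(tr, model$spec$input_dim)
        te <- pad_features(te, model$spec$input_dim)
      }
      n_bg <- min(cfg$n_background, nrow(tr))
      n_ex <- min(cfg$n_explain, nrow(te))
      bg <- tr[seq_len(n_bg), , drop = FALSE]
      xs <- te[seq_len(n_ex), , drop = FALSE]
      d <- model$spec$input_dim
      attr_ <- if (d > cfg$gradient_threshold) {
        gradient_shap_latent(model, xs, bg, latent_index = 1, n_steps = 20)
      } else {
        kernel_shap_latent(model, xs, bg, latent_index = 1,
                           mode = if (d <= 12) "exact" else "sampled",
                           n_coalitions = cfg$shap_coalitions,
                           seed = derive_seed(seed, paste0("shap_", nm)))
      }
      list(attribution = attr_,
           top = top_biomarkers(attr_, k = min(10, d)))
    }))
    names(shap) <- assay_names
  }

  summary <- list(
    n_samples = nrow(aligned$clinical),
    n_train = nrow(parts$train$clinical),
    n_test = nrow(parts$test$clinical),
    latent_dims = as.list(map_int(assay_names, ~ as.integer(selected_latent[[.x]]))),
    tensor_shape_train = dim(tensors$train$values),
    tensor_shape_test = dim(tensors$test$values),
    selected_rank = rank,
    corcondia_table = rank_diag,
    cp_mse_train = reconstruction_mse(tensors$train, cp$train),
    cp_mse_test = reconstruction_mse(tensors$test, cp$test),
    cp_corcondia_train = corcondia(tensors$train, cp$train),
    logrank_p_train = strat$train$fit$logrank_p,
    logrank_p_test = strat$test$fit$logrank_p,
    cox_hr_train = strat$train$fit$cox_hr,
    cox_hr_test = strat$test$fit$cox_hr,
    group_sizes_train = as.list(strat$train$fit$n_per_group),
    group_sizes_test = as.list(strat$test$fit$n_per_group),
    purity = purity,
    seed = seed
  )
  names(summary$latent_dims) <- assay_names

  res <- structure(list(config = cfg, parts = parts, latents = latents,
                        models = models, tensors = tensors, cp = cp,
                        stratification = strat, purity = purity, shap = shap,
                        summary = summary),
                   class = "pipeline_result")
  if (!is.null(cfg$outdir)) write_pipeline_artifacts(res, cfg$outdir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  samples: %d (train %d / test %d)\n", s$n_samples, s$n_train, s$n_test))
  cat(sprintf("  tensor: train %s, test %s\n",
              paste(s$tensor_shape_train, collapse = "x"),
              paste(s$tensor_shape_test, collapse = "x")))
  cat(sprintf("  CP rank %d: MSE train %.4g / test %.4g\n",
              s$selected_rank, s$cp_mse_train, s$cp_mse_test))
  cat(sprintf("  log-rank p: train %.4g / test %.4g\n",
              s$logrank_p_train, s$logrank_p_test))
  invisible(x)
}

write_pipeline_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$latents)) {
    readr::write_csv(res$latents[[nm]]$train,
                     file.path(outdir, paste0("latent_train_", nm, ".csv")))
    readr::write_csv(res$latents[[nm]]$test,
                     file.path(outdir, paste0("latent_test_", nm, ".csv")))
    write_training_history(res$models[[nm]],
                           file.path(outdir, paste0("history_", nm, ".csv")))
  }
  write_cp_factors(res$cp$train, outdir, "cp_train")
  write_cp_factors(res$cp$test, outdir, "cp_test")
  for (p in c("train", "test")) {
    readr::write_csv(res$stratification[[p]]$groups,
                     file.path(outdir, paste0("risk_groups_", p, ".csv")))
    readr::write_csv(res$stratification[[p]]$fit$km,
                     file.path(outdir, paste0("km_", p, ".csv")))
  }
  if (!is.null(res$purity)) {
    readr::write_csv(res$purity, file.path(outdir, "purity_classification.csv"))
  }
  if (!is.null(res$shap)) {
    for (nm in names(res$shap)) {
      readr::write_csv(res$shap[[nm]]$top,
                       file.path(outdir, paste0("top_biomarkers_", nm, ".csv")))
    }
  }
  s <- res$summary
  s$group_sizes_train <- map(s$group_sizes_train, as.integer)
  s$group_sizes_test <- map(s$group_sizes_test, as.integer)
  jsonlite::write_json(s, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
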