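# Patient stratification on the CP patient-mode factors, survival
# evaluation (KM / log-rank / Cox via the survival package), and tumor-purity
# classification.

#' Canberra distance matrix
#'
#' Pairwise Canberra dissimilarity `sum_i |x_i - y_i| / (|x_i| + |y_i|)` with
#' the convention that 0/0 terms contribute 0. (Base R's
#' `dist(method = "canberra")` divides by `|x_i + y_i|` instead, which differs
#' for mixed-sign coordinates such as CP factor scores.)
#'
#' @param M numeric matrix, rows = samples.
#' @return a `dist` object.
#' @export
canberra_dist <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xi <- M[rep(i, n), , drop = FALSE]
    num <- abs(xi - M)
    den <- abs(xi) + abs(M)
    frac <- num / den
    frac[den == 0] <- 0
    D[i, ] <- rowSums(frac)
  }
  as.dist(D)
}

#' Agglomerative clustering with Ward linkage
#'
#' Computes the chosen dissimilarity (Canberra with the 0/0 := 0 convention,
#' or Chebyshev / maximum distance) and merges clusters with the
#' Lance-Williams Ward update applied directly to that dissimilarity
#' (`hclust(method = "ward.D")`). Deterministic for a fixed input matrix.
#'
#' @param M numeric matrix (samples x factors), e.g. the CP patient mode `A`.
#' @param k number of clusters (>= 2).
#' @param distance `"canberra"` or `"chebyshev"`.
#' @param linkage only `"ward"` is supported.
#' @return integer cluster labels `0 .. k-1`, named by `rownames(M)` when
#'   present, with the `hclust` tree in attribute `"tree"`.
#' @export
hierarchical_clusters <- function(M, k = 2, distance = c("canberra", "chebyshev"),
                                  linkage = "ward") {
  distance <- match.arg(distance)
  if (!identical(linkage, "ward")) {
    abort("only ward linkage is supported", class = "tensoromics_invalid_spec")
  }
  M <- as.matrix(M)
  if (k < 2) abort("k must be >= 2", class = "tensoromics_invalid_k")
  if (k > nrow(M)) {
    abort(sprintf("k (%d) exceeds the number of samples (%d)", k, nrow(M)),
          class = "tensoromics_invalid_k")
  }
  D <- if (distance == "canberra") canberra_dist(M) else stats::dist(M, method = "maximum")
  tree <- hclust(D, method = "ward.D")
  labels <- cutree(tree, k = k) - 1L
  names(labels) <- rownames(M)
  attr(labels, "tree") <- tree
  labels
}

#' Rank clusters into risk groups by observed survival
#'
#' Clusters are ranked by ascending median observed time, so rank 1 (the
#' shortest median survival) is the high-risk group; ties break toward the
#' cluster with the higher event rate. For `k = 2` the labels are
#' `"high"`/`"low"`, for `k = 3` `"high"`/`"intermediate"`/`"low"`.
#'
#' @param labels integer cluster labels aligned with `surv` (as from
#'   [hierarchical_clusters()]).
#' @param surv clinical tibble (`sample_id`, `os_time`, `os_event`).
#' @return a `risk_groups` tibble: `sample_id`, `cluster`, `risk_rank`,
#'   `risk_label`.
#' @export
assign_risk_labels <- function(labels, surv) {
  check_survival(surv)
  labels <- as.integer(labels)
  if (length(labels) != nrow(surv)) {
    abort("labels and survival table have different lengths",
          class = "tensoromics_schema_error")
  }
  stats_tbl <- tibble(cluster = labels, os_time = surv$os_time,
                      os_event = surv$os_event) |>
    group_by(.data$cluster) |>
    summarise(med = median(.data$os_time), ev = mean(.data$os_event),
              .groups = "drop") |>
    arrange(.data$med, desc(.data$ev))
  stats_tbl$risk_rank <- seq_len(nrow(stats_tbl))
  k <- nrow(stats_tbl)
  lab_names <- if (k == 2) c("high", "low") else if (k == 3) {
    c("high", "intermediate", "low")
  } else paste0("risk_", seq_len(k))
  stats_tbl$risk_label <- lab_names
  out <- tibble(sample_id = surv$sample_id, cluster = labels) |>
    left_join(select(stats_tbl, "cluster", "risk_rank", "risk_label"),
              by = "cluster")
  class(out) <- c("risk_groups", class(out))
  out
}

#' Kaplan-Meier curves, log-rank test and Cox hazard ratio by risk group
#'
#' Fits the product-limit estimator per risk group, tests for a difference
#' with the k-sample log-rank test, and (for two groups) fits a univariate
#' Cox model of high vs low risk with Breslow tie handling.
#'
#' @param groups a `risk_groups` tibble from [assign_risk_labels()].
#' @param surv clinical tibble aligned with `groups`.
#' @return a `survfit_result`: list with `km` (tibble `group`, `time`,
#'   `survival`, `n_risk`, `n_event`), `logrank_p`, `logrank_chisq`,
#'   `cox_hr`, `cox_ci` (2-group case), `n_per_group`.
#' @export
km_logrank <- function(groups, surv) {
  check_survival(surv)
  stopifnot(identical(groups$sample_id, surv$sample_id))
  if (sum(surv$os_event) == 0) {
    abort("no events observed; the log-rank test is undefined",
          class = "tensoromics_undefined_test")
  }
  grp <- factor(groups$risk_label,
                levels = unique(groups$risk_label[order(groups$risk_rank)]))
  if (length(levels(grp)) < 2) {
    abort("need at least two nonempty groups", class = "tensoromics_invalid_spec")
  }
  dat <- data.frame(time = surv$os_time, event = surv$os_event, group = grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  km <- tibble(
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
    time = sf$time, survival = sf$surv, n_risk = sf$n.risk, n_event = sf$n.event
  )
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd_$n) - 1
  p <- pchisq(sd_$chisq, df = df, lower.tail = FALSE)
  cox_hr <- NA_real_; cox_ci <- c(NA_real_, NA_real_)
  if (length(levels(grp)) == 2) {
    # code high risk as 1 so the HR is high vs low
    dat$high <- as.integer(groups$risk_rank == 1)
    cx <- survival::coxph(survival::Surv(time, event) ~ high, data = dat,
                          ties = "breslow")
    cox_hr <- unname(exp(coef(cx)))
    ci <- exp(stats::confint(cx))
    cox_ci <- unname(ci[1, ])
  }
  structure(list(km = km, logrank_chisq = unname(sd_$chisq), logrank_p = p,
                 cox_hr = cox_hr, cox_ci = cox_ci,
                 n_per_group = table(grp)),
            class = "survfit_result")
}

#' @export
print.survfit_result <- function(x, ...) {
  cat("<survfit_result>\n  groups:",
      paste(sprintf("%s (n=%d)", names(x$n_per_group), as.integer(x$n_per_group)),
            collapse = ", "), "\n")
  cat(sprintf("  log-rank: chisq = %.3f, p = %.4g\n", x$logrank_chisq, x$logrank_p))
  if (is.finite(x$cox_hr)) {
    cat(sprintf("  Cox HR (high vs low): %.3f [%.3f, %.3f]\n",
                x$cox_hr, x$cox_ci[1], x$cox_ci[2]))
  }
  invisible(x)
}

#' Administratively censor survival at a horizon
#'
#' Samples with observed time beyond the horizon get their time set to the
#' horizon and their event flag set to 0. Never increases the event count.
#'
#' @param surv clinical tibble.
#' @param horizon time limit in the same units as `os_time` (e.g. 3000 days).
#' @return the truncated clinical tibble.
#' @export
truncate_survival <- function(surv, horizon) {
  check_survival(surv)
  if (horizon <= 0) abort("horizon must be positive", class = "tensoromics_invalid_spec")
  over <- surv$os_time > horizon
  surv$os_event[over] <- 0L
  surv$os_time[over] <- horizon
  surv
}

binarize_purity <- function(purity, threshold = 0.7) {
  factor(ifelse(purity >= threshold, "high", "low"), levels = c("low", "high"))
}

macro_f1 <- function(truth, pred) {
  lv <- levels(truth)
  f1 <- map_dbl(lv, function(l) {
    tp <- sum(pred == l & truth == l)
    fp <- sum(pred == l & truth != l)
    fn <- sum(pred != l & truth == l)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  })
  c(macro = mean(f1), weighted = sum(f1 * as.numeric(table(truth)[lv])) / length(truth))
}

# minimal SAMME AdaBoost over depth-1 rpart stumps (no installed package
# provides AdaBoost)
fit_adaboost <- function(x_train, y_train, n_rounds = 50) {
  n <- nrow(x_train)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  df <- data.frame(y = y_train, x_train)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y_train)) / sum(w)
    if (err >= 0.5 || err <= 1e-12) {
      if (err <= 1e-12) { stumps <- c(stumps, list(fit)); alphas <- c(alphas, 10) }
      break
    }
    alpha <- log((1 - err) / err)
    w <- w * exp(alpha * (pred != y_train))
    w <- w / sum(w)
    stumps <- c(stumps, list(fit)); alphas <- c(alphas, alpha)
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y_train))
}

predict_adaboost <- function(model, x_new) {
  df <- data.frame(x_new)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    idx <- cbind(seq_len(nrow(df)), as.integer(pred))
    votes[idx] <- votes[idx] + model$alphas[m]
  }
  factor(model$levels[max.col(votes, ties.method = "first")], levels = model$levels)
}

#' Classify tumor purity from CP patient factors
#'
#' Binarizes purity at the threshold (`>= threshold` is high), trains the
#' requested classifiers on the training features and evaluates accuracy,
#' macro-F1 and weighted-F1 on the test features. Random-forest
#' hyperparameters can be grid-searched (`ntree`, `mtry`, `maxnodes`) with
#' out-of-bag accuracy as the selection criterion.
#'
#' @param train_features,test_features numeric matrices of patient factors
#'   (e.g. CP mode `A` scores for each partition).
#' @param train_purity,test_purity purity values in `[0, 1]` aligned with the
#'   feature rows.
#' @param threshold binarization cut (default 0.7).
#' @param models character vector among `"logistic"`, `"knn"`,
#'   `"naive_bayes"`, `"decision_tree"`, `"svm"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"adaboost"`.
#' @param rf_grid optional data frame of random-forest settings to search,
#'   with columns among `ntree`, `mtry`, `maxnodes`.
#' @param seed integer seed.
#' @return tibble with `model`, `accuracy`, `macro_f1`, `weighted_f1`
#'   (random-forest rows carry the selected grid point in attribute
#'   `"rf_selected"`).
#' @export
classify_purity <- function(train_features, test_features, train_purity,
                            test_purity, threshold = 0.7,
                            models = c("logistic", "knn", "naive_bayes",
                                       "decision_tree", "svm", "random_forest",
                                       "gradient_boosting", "adaboost"),
                            rf_grid = NULL, seed = 1L) {
  stopifnot(threshold > 0, threshold < 1)
  if (any(c(train_purity, test_purity) < 0 | c(train_purity, test_purity) > 1)) {
    abort("purity must lie in [0, 1]", class = "tensoromics_schema_error")
  }
  Xtr <- as.matrix(train_features); Xte <- as.matrix(test_features)
  colnames(Xtr) <- colnames(Xte) <- paste0("f", seq_len(ncol(Xtr)))
  ytr <- binarize_purity(train_purity, threshold)
  yte <- binarize_purity(test_purity, threshold)
  if (length(unique(ytr)) < 2) {
    abort("purity labels are single-class after binarization",
          class = "tensoromics_degenerate_labels")
  }
  if (all(apply(Xtr, 2, function(v) diff(range(v)) == 0))) {
    abort("all training features are constant; nothing to classify on",
          class = "tensoromics_degenerate_features")
  }
  rf_selected <- NULL
  fit_one <- function(model) {
    pred <- switch(
      model,
      logistic = {
        df <- data.frame(y = ytr, Xtr)
        fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
        p <- predict(fit, data.frame(Xte), type = "response")
        factor(ifelse(p >= 0.5, "high", "low"), levels = levels(ytr))
      },
      knn = class::knn(Xtr, Xte, ytr, k = 5),
      naive_bayes = predict(e1071::naiveBayes(Xtr, ytr), Xte),
      decision_tree = predict(rpart::rpart(y ~ ., data = data.frame(y = ytr, Xtr),
                                           method = "class"),
                              data.frame(Xte), type = "class"),
      svm = predict(e1071::svm(Xtr, ytr), Xte),
      random_forest = {
        grid <- rf_grid %||% data.frame(ntree = c(100, 133, 200))
        oob <- map_dbl(seq_len(nrow(grid)), function(i) {
          args <- c(list(x = Xtr, y = ytr), as.list(grid[i, , drop = FALSE]))
          fit <- do.call(randomForest::randomForest, args)
          1 - fit$err.rate[fit$ntree, "OOB"]
        })
        best <- which.max(oob)
        rf_selected <<- grid[best, , drop = FALSE]
        args <- c(list(x = Xtr, y = ytr), as.list(grid[best, , drop = FALSE]))
        predict(do.call(randomForest::randomForest, args), Xte)
      },
      gradient_boosting = {
        dtr <- xgboost::xgb.DMatrix(Xtr, label = as.numeric(ytr == "high"))
        fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                                max_depth = 3, eta = 0.3,
                                                nthread = 1),
                                  data = dtr, nrounds = 50, verbose = 0)
        p <- predict(fit, xgboost::xgb.DMatrix(Xte))
        factor(ifelse(p >= 0.5, "high", "low"), levels = levels(ytr))
      },
      adaboost = predict_adaboost(fit_adaboost(Xtr, ytr), Xte),
      abort(paste0("unknown model: ", model), class = "tensoromics_invalid_spec")
    )
    f1 <- macro_f1(yte, factor(pred, levels = levels(yte)))
    tibble(model = model, accuracy = mean(pred == yte),
           macro_f1 = unname(f1["macro"]), weighted_f1 = unname(f1["weighted"]))
  }
  out <- withr::with_seed(seed, bind_rows(map(models, fit_one)))
  attr(out, "rf_selected") <- rf_selected
  out
}
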