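test_that("Canberra distance uses |x|+|y| denominators and 0/0 = 0", {
  M <- rbind(c(0, 0), c(0, 0))
  expect_equal(as.vector(canberra_dist(M)), 0)
  M2 <- rbind(c(1, 0), c(3, 0))
  expect_equal(as.vector(canberra_dist(M2)), 2 / 4)   # |1-3|/(1+3), 0/0 term -> 0
  # mixed signs: |x - y| / (|x| + |y|), not |x + y|
  M3 <- rbind(c(-1), c(1))
  expect_equal(as.vector(canberra_dist(M3)), 1)
})

test_that("well-separated blobs are clustered exactly, deterministically", {
  set.seed(3)
  M <- rbind(matrix(rnorm(100, 0, 0.3), 50), matrix(rnorm(100, 5, 0.3), 50))
  truth <- rep(0:1, each = 50)
  lab <- hierarchical_clusters(M, 2)
  agreement <- max(mean(lab == truth), mean(lab == 1 - truth))
  expect_equal(agreement, 1)
  expect_identical(as.integer(lab), as.integer(hierarchical_clusters(M, 2)))
  lab_cheb <- hierarchical_clusters(M, 2, distance = "chebyshev")
  expect_equal(max(mean(lab_cheb == truth), mean(lab_cheb == 1 - truth)), 1)
})

test_that("clustering guards k and degenerate sizes", {
  M <- rbind(c(0, 0), c(10, 10))
  expect_equal(sort(as.integer(hierarchical_clusters(M, 2))), c(0L, 1L))
  expect_error(hierarchical_clusters(M, 3), class = "tensoromics_invalid_k")
  expect_error(hierarchical_clusters(M, 1), class = "tensoromics_invalid_k")
})

test_that("risk ranks follow ascending median survival with event-rate tie-break", {
  surv <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                         os_time = c(400, 410, 390, 1500, 1490, 1510),
                         os_event = c(1L, 1L, 0L, 0L, 0L, 1L))
  rg <- assign_risk_labels(c(0, 0, 0, 1, 1, 1), surv)
  expect_equal(unique(rg$risk_label[rg$cluster == 0]), "high")
  expect_equal(unique(rg$risk_label[rg$cluster == 1]), "low")
  # equal medians: the higher event rate is the higher risk
  surv2 <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                          os_time = c(500, 500, 500, 500),
                          os_event = c(1L, 1L, 0L, 0L))
  rg2 <- assign_risk_labels(c(0, 0, 1, 1), surv2)
  expect_equal(unique(rg2$risk_rank[rg2$cluster == 0]), 1)
  # three clusters rank 1..3 by ascending median
  surv3 <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                          os_time = c(100, 110, 900, 950, 2000, 2100),
                          os_event = rep(1L, 6))
  rg3 <- assign_risk_labels(c(2, 2, 0, 0, 1, 1), surv3)
  expect_equal(unique(rg3$risk_label[rg3$cluster == 2]), "high")
  expect_equal(unique(rg3$risk_label[rg3$cluster == 0]), "intermediate")
  expect_equal(unique(rg3$risk_label[rg3$cluster == 1]), "low")
})

test_that("identical survival in both groups gives log-rank p = 1", {
  base <- tibble::tibble(os_time = c(100, 200, 300, 400, 500),
                         os_event = c(1L, 0L, 1L, 1L, 0L))
  surv <- dplyr::bind_rows(base, base)
  surv$sample_id <- sprintf("s%d", 1:10)
  surv <- surv[, c("sample_id", "os_time", "os_event")]
  rg <- assign_risk_labels(rep(c(0, 1), each = 5), surv)
  fit <- km_logrank(rg, surv)
  expect_equal(fit$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(fit$logrank_p, 1, tolerance = 1e-9)
})

test_that("KM curves follow the product-limit formula and are valid", {
  surv <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                         os_time = c(10, 20, 30, 40, 15, 25, 35, 45),
                         os_event = c(1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L))
  rg <- assign_risk_labels(rep(c(0, 1), each = 4), surv)
  fit <- km_logrank(rg, surv)
  for (g in unique(fit$km$group)) {
    s <- fit$km$survival[fit$km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
    # after the first death among n at risk: S = 1 - 1/n
    first <- fit$km[fit$km$group == g, ][1, ]
    expect_equal(first$survival, 1 - first$n_event / first$n_risk)
  }
  expect_true(is.finite(fit$cox_hr))
  expect_error(km_logrank(rg, dplyr::mutate(surv, os_event = 0L)),
               class = "tensoromics_undefined_test")
})

test_that("a strong planted hazard ratio is detected with high power", {
  hits <- vapply(1:60, function(s) {
    co <- generate_cohort(cohort_spec(n_samples = 300, assay_dims = c(a = 3),
                                      risk_effect = 1.1, seed = 7000 + s))
    rg <- assign_risk_labels(as.integer(co$latent$factor_1 > 0), co$clinical)
    km_logrank(rg, co$clinical)$logrank_p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("survival truncation censors at the horizon and never adds events", {
  surv <- tibble::tibble(sample_id = c("a", "b", "c"),
                         os_time = c(4200, 2999, 3000),
                         os_event = c(1L, 1L, 1L))
  tr <- truncate_survival(surv, 3000)
  expect_equal(tr$os_time, c(3000, 2999, 3000))
  expect_equal(tr$os_event, c(0L, 1L, 1L))
  expect_lte(sum(tr$os_event), sum(surv$os_event))
  # all under the horizon: identity
  expect_identical(truncate_survival(surv, 5000), surv)
  expect_error(truncate_survival(surv, -1), class = "tensoromics_invalid_spec")
})

test_that("purity binarization boundary is >= threshold", {
  # 0.70 itself must land in the high class: train on clearly separated
  # points, predict the boundary cases through the returned metrics
  tr_x <- matrix(c(seq(0, 1, length.out = 20)), ncol = 1)
  tr_p <- as.numeric(tr_x >= 0.5) * 0.6 + 0.2   # 0.2 or 0.8
  te_x <- matrix(c(0.1, 0.9, 0.9), ncol = 1)
  te_p <- c(0.69, 0.70, 0.71)
  res <- classify_purity(tr_x, te_x, tr_p, te_p, threshold = 0.7,
                         models = "knn", seed = 1)
  # knn on x predicts low/high/high; that matches labels iff 0.70 is "high"
  expect_equal(res$accuracy, 1)
})

test_that("single-class purity labels are rejected", {
  X <- matrix(rnorm(40), 20)
  expect_error(classify_purity(X, X, rep(0.9, 20), rep(0.9, 20)),
               class = "tensoromics_degenerate_labels")
})

test_that("separable purity is classified nearly perfectly by random forest", {
  acc <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_spec(n_samples = 240, assay_dims = c(a = 3),
                                      latent_dim = 4, seed = 300 + s))
    Z <- as.matrix(co$latent[, -1])
    purity <- plogis(4 * Z[, 2])       # deterministic function of the features
    tr <- 1:160; te <- 161:240
    res <- classify_purity(Z[tr, ], Z[te, ], purity[tr], purity[te],
                           models = "random_forest", seed = s)
    res$accuracy
  }, 0)
  expect_gte(mean(acc), 0.95)
})

test_that("all eight classifier families run and report the three metrics", {
  co <- generate_cohort(cohort_spec(n_samples = 160, assay_dims = c(a = 3),
                                    latent_dim = 4, purity_effect = 3, seed = 77))
  Z <- as.matrix(co$latent[, -1])
  purity <- co$clinical$tumor_purity
  res <- classify_purity(Z[1:110, ], Z[111:160, ], purity[1:110], purity[111:160],
                         seed = 2)
  expect_equal(nrow(res), 8)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_true(all(is.finite(res$macro_f1)))
  expect_true(all(is.finite(res$weighted_f1)))
  expect_s3_class(attr(res, "rf_selected"), "data.frame")
})
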