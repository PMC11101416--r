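test_that("exact Kernel SHAP equals brute-force permutation Shapley (d <= 6)", {
  model <- small_model(d = 5, latent = 2, seed = 21)
  co <- tiny_cohort(n = 30, dims = c(a = 5), seed = 22)
  m <- scaled_assay(co)
  x <- m[1, , drop = FALSE]
  bg <- m[5:20, ]
  ks <- kernel_shap_latent(model, x, bg, latent_index = 2, mode = "exact")
  baseline <- colMeans(tensoromics:::omics_values(bg))
  g <- function(v) tensoromics:::encode_matrix(model, matrix(v, 1))[, 2]
  oracle <- permutation_shapley(g, tensoromics:::omics_values(x)[1, ], baseline)
  expect_equal(unname(ks$phi[1, ]), oracle, tolerance = 1e-8)
})

test_that("efficiency holds per sample: sum(phi) = g(x) - g(baseline)", {
  model <- small_model(d = 8, latent = 2, seed = 31)
  co <- tiny_cohort(n = 40, dims = c(a = 8), seed = 32)
  m <- scaled_assay(co)
  ks <- kernel_shap_latent(model, m[1:4, ], m[10:30, ], latent_index = 1,
                           mode = "exact")
  expect_equal(unname(rowSums(ks$phi)), unname(ks$g_x - ks$g_baseline),
               tolerance = 1e-6)
})

test_that("linear encoders have the closed-form attribution w_i (x_i - b_i)", {
  w <- c(2, -1, 0.5, 3)
  model <- linear_encoder(w)
  x <- matrix(c(1, 2, 3, 4), 1, dimnames = list(NULL, paste0("f", 1:4)))
  b <- matrix(c(0, 1, 0, 2), 1, dimnames = list(NULL, paste0("f", 1:4)))
  ks <- kernel_shap_latent(model, x, b, mode = "exact")
  expect_equal(unname(ks$phi[1, ]), w * (x[1, ] - b[1, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (steps in c(1, 7)) {
    gs <- gradient_shap_latent(model, x, b, n_steps = steps)
    expect_equal(unname(gs$phi[1, ]), w * (x[1, ] - b[1, ]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("ignored and symmetric features get null and equal attributions", {
  # feature 3 ignored; features 1 and 2 interchangeable
  w <- c(1.5, 1.5, 0)
  model <- linear_encoder(w)
  x <- matrix(c(2, 2, 9), 1, dimnames = list(NULL, paste0("f", 1:3)))
  b <- matrix(0, 1, 3, dimnames = list(NULL, paste0("f", 1:3)))
  ks <- kernel_shap_latent(model, x, b, mode = "exact")
  expect_equal(unname(ks$phi[1, 3]), 0, tolerance = 1e-12)
  expect_equal(unname(ks$phi[1, 1]), unname(ks$phi[1, 2]), tolerance = 1e-12)
})

test_that("sampled Kernel SHAP with a full coalition budget matches exact", {
  model <- small_model(d = 8, latent = 2, seed = 41)
  co <- tiny_cohort(n = 30, dims = c(a = 8), seed = 42)
  m <- scaled_assay(co)
  ks_e <- kernel_shap_latent(model, m[2, ], m[5:25, ], mode = "exact")
  ks_s <- kernel_shap_latent(model, m[2, ], m[5:25, ], mode = "sampled",
                             n_coalitions = 2^8)
  expect_equal(ks_s$phi, ks_e$phi, tolerance = 1e-6)
  expect_error(kernel_shap_latent(small_model(d = 16, latent = 2, seed = 1),
                                  matrix(0, 1, 16), matrix(1, 1, 16),
                                  mode = "exact"),
               class = "tensoromics_too_many_features")
})

test_that("gradient SHAP vanishes at the baseline and integrates to completeness", {
  model <- small_model(d = 8, latent = 2, seed = 51)
  co <- tiny_cohort(n = 30, dims = c(a = 8), seed = 52)
  m <- scaled_assay(co)
  same <- gradient_shap_latent(model, m[3, ], m[3, ], n_steps = 5)
  expect_true(all(same$phi == 0))
  # completeness: with a single baseline and many steps, sum(phi) converges to
  # g(x) - g(x'); the oracle is the same integral at 10x the resolution
  gs <- gradient_shap_latent(model, m[1, ], m[9, ], latent_index = 1,
                             n_steps = 200)
  gs_fine <- gradient_shap_latent(model, m[1, ], m[9, ], latent_index = 1,
                                  n_steps = 2000)
  expect_equal(sum(gs$phi), sum(gs_fine$phi), tolerance = 1e-3)
  delta <- gs$g_x - tensoromics:::encode_matrix(
    model, tensoromics:::omics_values(m[9, ]))[, 1]
  expect_equal(sum(gs_fine$phi), unname(delta), tolerance = 1e-3)
})

test_that("top_biomarkers ranks by aggregate attribution magnitude", {
  phi <- cbind(a = c(0.1, -0.1), b = c(2, 2.2), c = c(-0.5, -0.4))
  attr_ <- tensoromics:::new_shap_attribution("x", colnames(phi), phi,
                                              numeric(3), "kernel", 1,
                                              numeric(2), 0)
  top <- top_biomarkers(attr_, k = 3)
  expect_equal(top$feature, c("b", "c", "a"))
  expect_equal(top$score[1], 2.1)
  expect_setequal(top_biomarkers(attr_, k = 3, aggregate = "mean")$feature,
                  colnames(phi))
})

test_that("top biomarkers recover the largest planted loadings", {
  hits <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_spec(n_samples = 80, assay_dims = c(a = 10),
                                      latent_dim = 2, noise_sd = 0.02,
                                      seed = 500 + s))
    m <- scaled_assay(co)
    w <- co$loadings$a[1, ]                   # latent-1 loading row
    model <- linear_encoder(unname(w))
    model$feature_names <- names(w)
    ks <- kernel_shap_latent(model, m[1:15, ], m[16:80, ], mode = "sampled",
                             n_coalitions = 300, seed = s)
    top5 <- top_biomarkers(ks, k = 5)$feature
    truth5 <- names(sort(abs(w), decreasing = TRUE))[1:5]
    length(intersect(top5, truth5))
  }, 0)
  expect_true(all(hits >= 4))
})

test_that("fold enrichment and its hypergeometric tail are exact", {
  fe <- fold_enrichment(10, 50, 100, 1000)
  expect_equal(fe$fold_enrichment, 2.0)
  expect_equal(fold_enrichment(5, 50, 100, 1000)$fold_enrichment, 1.0)
  r <- fold_enrichment(5, 10, 50, 1000)
  expect_equal(r$fold_enrichment, 10.0)
  # brute-force combinatorial oracle over the urn
  oracle <- sum(vapply(5:10, function(k) {
    choose(50, k) * choose(950, 10 - k) / choose(1000, 10)
  }, 0))
  expect_equal(r$p_value, oracle, tolerance = 1e-12)
  expect_error(fold_enrichment(0, 10, 0, 100),
               class = "tensoromics_undefined_enrichment")
  expect_error(fold_enrichment(11, 10, 50, 100), class = "tensoromics_invalid_spec")
})

test_that("per-term enrichment tables cover the subset's terms", {
  ann <- tibble::tibble(gene = c("g1", "g2", "g3", "g4", "g5", "g1"),
                        term = c("T1", "T1", "T2", "T2", "T2", "T2"))
  tbl <- fold_enrichment_table(c("g1", "g2"), ann)
  expect_setequal(tbl$term, c("T1", "T2"))
  t1 <- tbl[tbl$term == "T1", ]
  expect_equal(t1$fold_enrichment, (2 / 2) / (2 / 5))
})
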