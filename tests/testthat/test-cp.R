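# independent oracles, written against the naive unfolding formulas

naive_reconstruct <- function(lambda, A, B, C) {
  d <- c(nrow(A), nrow(B), nrow(C))
  X <- array(0, d)
  for (r in seq_along(lambda)) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      X[i, j, k] <- X[i, j, k] + lambda[r] * A[i, r] * B[j, r] * C[k, r]
    }
  }
  X
}

reference_als <- function(X, R, iters = 300, seed = 1) {
  d <- dim(X)
  unf <- function(X, mode) {
    perm <- switch(mode, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    matrix(aperm(X, perm), d[mode], prod(d[-mode]))
  }
  kr <- function(P, Q) {
    out <- matrix(0, nrow(P) * nrow(Q), ncol(P))
    for (r in seq_len(ncol(P))) out[, r] <- kronecker(P[, r], Q[, r])
    out
  }
  set.seed(seed)
  A <- matrix(rnorm(d[1] * R), d[1]); B <- matrix(rnorm(d[2] * R), d[2])
  C <- matrix(rnorm(d[3] * R), d[3])
  for (it in seq_len(iters)) {
    A <- unf(X, 1) %*% kr(C, B) %*% solve(crossprod(C) * crossprod(B))
    B <- unf(X, 2) %*% kr(C, A) %*% solve(crossprod(C) * crossprod(A))
    C <- unf(X, 3) %*% kr(B, A) %*% solve(crossprod(B) * crossprod(A))
  }
  Xhat <- array(A %*% t(kr(C, B)), d)
  1 - sqrt(sum((X - Xhat)^2)) / sqrt(sum(X^2))
}

test_that("factor reconstruction equals the triple-loop outer-product sum", {
  lt <- generate_lowrank_tensor(c(8, 8, 8), 3, noise_sd = 0.1, seed = 2)
  f <- rals_cp(lt$tensor, 2, rals_config(l1_penalty = 0, seed = 1))
  expect_equal(cp_reconstruct(f), naive_reconstruct(f$lambda, f$A, f$B, f$C),
               tolerance = 1e-10)
})

test_that("an exact rank-1 tensor is recovered to numerical precision", {
  lt <- generate_lowrank_tensor(c(10, 5, 8), 1, noise_sd = 0, seed = 4)
  f <- rals_cp(lt$tensor, 1, rals_config(l1_penalty = 0, seed = 7))
  rel_err <- sqrt(sum((lt$tensor - cp_reconstruct(f))^2)) / sqrt(sum(lt$tensor^2))
  expect_lt(rel_err, 1e-8)
  expect_equal(f$lambda[1], lt$factors$lambda[1], tolerance = 1e-6)
})

test_that("noisy rank-3 factors are recovered with high congruence", {
  lt <- generate_lowrank_tensor(c(30, 9, 16), 3, noise_sd = 0.01, seed = 5)
  f <- rals_cp(lt$tensor, 3, rals_config(l1_penalty = 0, seed = 2))
  cg <- factor_congruence(f, lt$factors)
  expect_true(all(cg$congruence_a > 0.95))
  expect_true(all(cg$congruence_b > 0.95))
  expect_true(all(cg$congruence_c > 0.95))
  expect_equal(reconstruction_mse(lt$tensor, f), 0.01^2, tolerance = 1)
})

test_that("unpenalized RALS matches an independent dense ALS reference", {
  lt <- generate_lowrank_tensor(c(12, 7, 6), 2, noise_sd = 0.05, seed = 9)
  f <- rals_cp(lt$tensor, 2, rals_config(l1_penalty = 0, tol = 1e-12,
                                         max_iter = 2000, seed = 3))
  ref_fit <- reference_als(lt$tensor, 2, iters = 2000, seed = 11)
  expect_equal(f$fit, ref_fit, tolerance = 1e-6)
})

test_that("the unpenalized objective is non-increasing at every sweep", {
  for (s in 1:3) {
    lt <- generate_lowrank_tensor(c(15, 8, 6), 3, noise_sd = 0.2, seed = s)
    f <- rals_cp(lt$tensor, 3, rals_config(l1_penalty = 0, seed = s + 50))
    expect_true(all(diff(f$obj_trace) <= 1e-9 * max(f$obj_trace[1], 1)))
  }
})

test_that("the L1 penalty shrinks factors without destroying the fit", {
  lt <- generate_lowrank_tensor(c(20, 8, 10), 2, noise_sd = 0.02, seed = 13)
  f0 <- rals_cp(lt$tensor, 2, rals_config(l1_penalty = 0, seed = 1))
  f1 <- rals_cp(lt$tensor, 2, rals_config(l1_penalty = 0.01, seed = 1))
  expect_gt(f1$fit, 0.8 * f0$fit)
  expect_lte(sum(abs(f1$B)), sum(abs(f0$B)) + 1e-8)
})

test_that("reconstruction MSE follows its definition", {
  lt <- generate_lowrank_tensor(c(6, 5, 4), 2, noise_sd = 0, seed = 1)
  expect_equal(reconstruction_mse(lt$tensor, lt$factors), 0, tolerance = 1e-20)
  zero <- tensoromics:::new_cp_factors(c(0, 0), lt$factors$A, lt$factors$B,
                                       lt$factors$C)
  expect_equal(reconstruction_mse(lt$tensor, zero), mean(lt$tensor^2))
  bad <- generate_lowrank_tensor(c(7, 5, 4), 2, seed = 1)$factors
  expect_error(reconstruction_mse(lt$tensor, bad), class = "tensoromics_schema_error")
})

test_that("CORCONDIA matches a dense Tucker-core oracle and flags overfactoring", {
  lt <- generate_lowrank_tensor(c(12, 8, 6), 2, noise_sd = 0, seed = 3)
  f2 <- rals_cp(lt$tensor, 2, rals_config(l1_penalty = 0, seed = 1))
  # dense oracle: vec(G) = (pinv(C) kron pinv(B) kron pinv(A diag(lambda))) vec(X),
  # compared against the superdiagonal identity core
  Ai <- tensoromics:::pinv(sweep(f2$A, 2, f2$lambda, "*"))
  Bi <- tensoromics:::pinv(f2$B)
  Ci <- tensoromics:::pinv(f2$C)
  G <- array(kronecker(Ci, kronecker(Bi, Ai)) %*% as.vector(lt$tensor),
             rep(2, 3))
  ideal <- array(0, rep(2, 3)); for (r in 1:2) ideal[r, r, r] <- 1
  oracle <- 100 * (1 - sum((G - ideal)^2) / 2)
  expect_equal(corcondia(lt$tensor, f2), oracle, tolerance = 1e-8)
  expect_gt(corcondia(lt$tensor, f2), 99)
  f3 <- suppressWarnings(rals_cp(lt$tensor, 3, rals_config(l1_penalty = 0, seed = 1)))
  expect_lt(suppressWarnings(corcondia(lt$tensor, f3)), 90)
})

test_that("rank-1 exactness gives core consistency 100", {
  lt <- generate_lowrank_tensor(c(10, 5, 8), 1, noise_sd = 0, seed = 6)
  f <- rals_cp(lt$tensor, 1, rals_config(l1_penalty = 0, seed = 2))
  expect_equal(corcondia(lt$tensor, f), 100, tolerance = 1e-6)
})

test_that("select_rank returns the planted rank and full diagnostics", {
  lt <- generate_lowrank_tensor(c(30, 9, 16), 3, noise_sd = 0, seed = 21)
  sel <- suppressWarnings(
    select_rank(lt$tensor, 1:6, rals_config(l1_penalty = 0, seed = 2,
                                            init = "hosvd")))
  expect_equal(sel$rank, 3)
  expect_equal(sel$diagnostics$rank, 1:6)
  expect_true(all(c("corcondia", "mse") %in% names(sel$diagnostics)))
  lt1 <- generate_lowrank_tensor(c(10, 6, 5), 1, noise_sd = 0, seed = 1)
  expect_equal(suppressWarnings(
    select_rank(lt1$tensor, 1:4, rals_config(l1_penalty = 0, seed = 1,
                                             init = "hosvd"))$rank), 1)
  one <- select_rank(lt1$tensor, 1, rals_config(l1_penalty = 0, seed = 1))
  expect_equal(one$rank, 1)
  expect_equal(nrow(one$diagnostics), 1)
})

test_that("projection onto fitted factors reproduces training scores", {
  lt <- generate_lowrank_tensor(c(20, 6, 8), 2, noise_sd = 0, seed = 8)
  f <- rals_cp(lt$tensor, 2, rals_config(l1_penalty = 0, seed = 1, init = "hosvd"))
  A_proj <- cp_project(f, lt$tensor)
  expect_equal(A_proj, f$A %*% diag(f$lambda), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("tidy and glance summarize CP fits", {
  lt <- generate_lowrank_tensor(c(6, 5, 4), 2, noise_sd = 0, seed = 1)
  f <- rals_cp(lt$tensor, 2, rals_config(l1_penalty = 0, seed = 1))
  td <- tidy(f)
  expect_equal(nrow(td), (6 + 5 + 4) * 2)
  expect_setequal(unique(td$mode), c("samples", "slices", "features"))
  gl <- glance(f)
  expect_equal(gl$rank, 2)
  expect_gt(gl$fit, 0.999)
})
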