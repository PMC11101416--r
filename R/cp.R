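# Tensor primitives use the standard Kolda-Bader conventions: mode-n
# unfolding X(n), Khatri-Rao (columnwise Kronecker) products, and
# X(1) = A diag(lambda) (C kr B)'.

unfold_tensor <- function(X, mode) {
  d <- dim(X)
  perm <- switch(mode, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  matrix(aperm(X, perm), d[mode], prod(d[-mode]))
}

refold_tensor <- function(M, mode, dims) {
  perm <- switch(mode, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  aperm(array(M, dims[perm]), order(perm))
}

khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (r in seq_len(ncol(A))) out[, r] <- kronecker(A[, r], B[, r])
  out
}

# mode-n product of a 3-way array with a matrix U (rows become the new extent)
ttm <- function(X, U, mode) {
  d <- dim(X)
  M <- U %*% unfold_tensor(X, mode)
  d[mode] <- nrow(U)
  refold_tensor(M, mode, d)
}

new_cp_factors <- function(lambda, A, B, C, fit = NA_real_, n_iter = NA_integer_,
                           converged = NA, obj_trace = NULL) {
  structure(list(rank = length(lambda), lambda = as.numeric(lambda),
                 A = A, B = B, C = C, fit = fit, n_iter = n_iter,
                 converged = converged, obj_trace = obj_trace),
            class = "cp_factors")
}

#' @export
print.cp_factors <- function(x, ...) {
  cat(sprintf("<cp_factors> rank %d over modes %d x %d x %d\n",
              x$rank, nrow(x$A), nrow(x$B), nrow(x$C)))
  cat("  lambda:", paste(signif(x$lambda, 4), collapse = ", "), "\n")
  if (is.finite(x$fit)) {
    cat(sprintf("  fit: %.6f after %d sweeps (converged: %s)\n",
                x$fit, x$n_iter, x$converged))
  }
  invisible(x)
}

#' Reconstruct a 3-way tensor from CP factors
#'
#' Computes `sum_r lambda_r A_r o B_r o C_r`.
#'
#' @param f a `cp_factors` object.
#' @return a 3-way array of shape `(I, J, K)`.
#' @export
cp_reconstruct <- function(f) {
  stopifnot(inherits(f, "cp_factors"))
  X1 <- f$A %*% (t(khatri_rao(f$C, f$B)) * f$lambda)
  array(X1, c(nrow(f$A), nrow(f$B), nrow(f$C)))
}

#' RALS configuration
#'
#' @param l1_penalty soft-thresholding level applied to each factor matrix
#'   after its least-squares update; 0 gives plain ALS with a monotone
#'   objective.
#' @param max_iter maximum number of ALS sweeps.
#' @param tol convergence tolerance on the change in relative fit.
#' @param seed seed for the random initialization.
#' @param init `"random"` (uniform factors) or `"hosvd"` (leading singular
#'   vectors of each unfolding).
#' @return an `rals_config` list.
#' @export
rals_config <- function(l1_penalty = 0.01, max_iter = 500, tol = 1e-7,
                        seed = 1L, init = c("random", "hosvd")) {
  stopifnot(l1_penalty >= 0, max_iter >= 1, tol > 0)
  structure(list(l1_penalty = l1_penalty, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed), init = match.arg(init)),
            class = "rals_config")
}

#' CP decomposition by regularized alternating least squares
#'
#' Fits the rank-`R` CANDECOMP/PARAFAC model
#' `X ~ sum_r lambda_r A_r o B_r o C_r` by cycling least-squares updates of
#' the three factor matrices. An L1 penalty is applied by coordinate-wise
#' soft-thresholding after each normal-equation solve; with `l1_penalty = 0`
#' this is plain ALS and the squared-error objective is non-increasing at
#' every sweep. Iteration stops when the relative fit changes by less than
#' `tol` or after `max_iter` sweeps. Columns are normalized to unit norm with
#' the scale absorbed into `lambda`, components sorted by decreasing
#' `lambda`.
#'
#' @param X a 3-way array or a [stack_tensor()] result.
#' @param rank number of rank-one components.
#' @param cfg an [rals_config()].
#' @return a `cp_factors` object; `fit` is `1 - ||X - Xhat||_F / ||X||_F`,
#'   `obj_trace` records the penalized objective per sweep, and row labels of
#'   `A`/`B` carry sample IDs and slice labels when `X` is a fused tensor.
#' @export
rals_cp <- function(X, rank, cfg = rals_config()) {
  sample_ids <- NULL; slice_labels <- NULL
  if (inherits(X, "fused_tensor")) {
    sample_ids <- X$sample_ids
    slice_labels <- paste0(X$slice_map$assay, "_", X$slice_map$chunk)
    X <- X$values
  }
  stopifnot(length(dim(X)) == 3, rank >= 1)
  if (!all(is.finite(X))) abort("tensor contains non-finite values",
                                class = "tensoromics_schema_error")
  d <- dim(X)
  if (rank > max(d)) warn(sprintf("rank %d exceeds the largest mode extent %d",
                                  rank, max(d)))
  Xn <- list(unfold_tensor(X, 1), unfold_tensor(X, 2), unfold_tensor(X, 3))
  normX2 <- sum(X^2)

  unit_cols <- function(M) {
    nrm <- sqrt(colSums(M^2))
    nz <- nrm > 0
    M[, nz] <- sweep(M[, nz, drop = FALSE], 2, nrm[nz], "/")
    M
  }
  fac <- withr::with_seed(cfg$seed, {
    if (cfg$init == "random") {
      map(d, ~ unit_cols(matrix(runif(.x * rank), .x, rank)))
    } else {
      map(1:3, function(m) {
        s <- svd(Xn[[m]], nu = min(rank, d[m]))
        U <- s$u
        if (ncol(U) < rank) U <- cbind(U, unit_cols(matrix(runif(d[m] * (rank - ncol(U))), d[m])))
        U
      })
    }
  })
  lambda <- rep(1, rank)

  # factor columns are kept unit-norm with the scale in lambda, so the L1
  # threshold acts on a comparable scale at every mode
  resid2 <- function() {
    X1hat <- fac[[1]] %*% (t(khatri_rao(fac[[3]], fac[[2]])) * lambda)
    sum((Xn[[1]] - X1hat)^2)
  }
  obj <- function() {
    resid2() + cfg$l1_penalty *
      sum(abs(sweep(fac[[1]], 2, lambda, "*")), abs(fac[[2]]), abs(fac[[3]]))
  }

  fit_prev <- -Inf
  obj_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  others <- list(c(3, 2), c(3, 1), c(2, 1))
  while (it < cfg$max_iter) {
    it <- it + 1
    for (m in 1:3) {
      o <- others[[m]]
      KR <- khatri_rao(fac[[o[1]]], fac[[o[2]]])
      G <- crossprod(fac[[o[1]]]) * crossprod(fac[[o[2]]])
      Fm <- Xn[[m]] %*% KR %*% pinv(G)
      if (!all(is.finite(Fm))) {
        abort(sprintf("decomposition diverged at sweep %d (mode %d)", it, m),
              class = "tensoromics_decomposition_diverged")
      }
      if (cfg$l1_penalty > 0) Fm <- soft_threshold(Fm, cfg$l1_penalty)
      lambda <- sqrt(colSums(Fm^2))
      nz <- lambda > 0
      Fm[, nz] <- sweep(Fm[, nz, drop = FALSE], 2, lambda[nz], "/")
      fac[[m]] <- Fm
    }
    obj_trace <- c(obj_trace, obj())
    fit <- 1 - sqrt(max(resid2(), 0)) / sqrt(normX2)
    if (is.finite(fit_prev) && abs(fit - fit_prev) < cfg$tol) {
      converged <- TRUE
      fit_prev <- fit
      break
    }
    fit_prev <- fit
  }

  ord <- order(lambda, decreasing = TRUE)
  lambda <- lambda[ord]
  fac <- map(fac, ~ .x[, ord, drop = FALSE])
  for (r in seq_len(rank)) {
    sa <- sign(fac[[1]][which.max(abs(fac[[1]][, r])), r]); sa <- ifelse(sa == 0, 1, sa)
    sb <- sign(fac[[2]][which.max(abs(fac[[2]][, r])), r]); sb <- ifelse(sb == 0, 1, sb)
    fac[[1]][, r] <- fac[[1]][, r] * sa
    fac[[2]][, r] <- fac[[2]][, r] * sb
    fac[[3]][, r] <- fac[[3]][, r] * sa * sb
  }
  if (!is.null(sample_ids)) rownames(fac[[1]]) <- sample_ids
  if (!is.null(slice_labels)) rownames(fac[[2]]) <- slice_labels
  new_cp_factors(lambda, fac[[1]], fac[[2]], fac[[3]], fit = fit_prev, n_iter = it,
                 converged = converged, obj_trace = obj_trace)
}

#' Mean squared reconstruction error of a CP model
#'
#' @param X 3-way array or `fused_tensor`.
#' @param f `cp_factors`.
#' @return mean over all tensor entries of the squared residual.
#' @export
reconstruction_mse <- function(X, f) {
  if (inherits(X, "fused_tensor")) X <- X$values
  Xhat <- cp_reconstruct(f)
  if (!identical(dim(X), dim(Xhat))) {
    abort("tensor and factor shapes disagree", class = "tensoromics_schema_error")
  }
  mean((X - Xhat)^2)
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Computes the least-squares Tucker core implied by the fitted CP factor
#' matrices (via pseudo-inverses, with the weights absorbed into the sample
#' mode) and scores how close it is to the ideal superdiagonal of ones:
#' `100 * (1 - ||G - I||^2 / R)`. A perfect CP structure scores 100; low or
#' negative values indicate overfactoring, including degenerate extra
#' components whose weights collapse toward zero.
#'
#' @param X 3-way array or `fused_tensor` the factors were fitted to.
#' @param f `cp_factors`.
#' @return the core consistency percentage (<= 100).
#' @export
corcondia <- function(X, f) {
  if (inherits(X, "fused_tensor")) X <- X$values
  stopifnot(inherits(f, "cp_factors"))
  for (M in list(f$A, f$B, f$C)) {
    if (qr(M)$rank < ncol(M)) {
      warn("rank-deficient factor matrix; CORCONDIA uses the pseudo-inverse")
      break
    }
  }
  A_scaled <- sweep(f$A, 2, f$lambda, "*")
  G <- ttm(ttm(ttm(X, pinv(A_scaled), 1), pinv(f$B), 2), pinv(f$C), 3)
  ideal <- array(0, dim = rep(f$rank, 3))
  for (r in seq_len(f$rank)) ideal[r, r, r] <- 1
  100 * (1 - sum((G - ideal)^2) / f$rank)
}

#' Select the CP rank with CORCONDIA
#'
#' Fits each candidate rank with [rals_cp()] and returns the largest rank
#' whose core consistency stays at or above `threshold`, together with the
#' full diagnostics table. If no candidate reaches the threshold, the
#' best-scoring rank is returned with a warning.
#'
#' @param X 3-way array or `fused_tensor`.
#' @param candidate_ranks integer vector of ranks to try.
#' @param cfg an [rals_config()].
#' @param threshold core-consistency cutoff (default 90).
#' @return list with `rank` (the selection) and `diagnostics`
#'   (tibble `rank`, `corcondia`, `mse`, `fit`).
#' @export
select_rank <- function(X, candidate_ranks, cfg = rals_config(), threshold = 90) {
  if (length(candidate_ranks) == 0) abort("candidate_ranks must be nonempty",
                                          class = "tensoromics_invalid_spec")
  candidate_ranks <- sort(unique(as.integer(candidate_ranks)))
  diag_tbl <- map(candidate_ranks, function(r) {
    f <- rals_cp(X, r, cfg)
    tibble(rank = r, corcondia = corcondia(X, f),
           mse = reconstruction_mse(X, f), fit = f$fit)
  })
  diag_tbl <- bind_rows(diag_tbl)
  ok <- diag_tbl$rank[diag_tbl$corcondia >= threshold]
  if (length(ok)) {
    rank <- max(ok)
  } else {
    rank <- diag_tbl$rank[which.max(diag_tbl$corcondia)]
    warn(sprintf("no candidate rank reached core consistency %.0f; returning best-scoring rank %d",
                 threshold, rank))
  }
  list(rank = rank, diagnostics = diag_tbl)
}

#' Project new samples onto fitted CP components
#'
#' Computes least-squares sample-mode scores for a (new) tensor against the
#' slice- and feature-mode factors of a fitted model:
#' `A_new = X(1) (C kr B) ((C'C)*(B'B))^+`. Applied to the training tensor
#' itself this reproduces `A diag(lambda)` up to fit error, so train and test
#' patients get comparable coordinates — the representation used when a
#' classifier fitted on training patients is applied to test patients.
#'
#' @param f `cp_factors` fitted on the training tensor.
#' @param X 3-way array or `fused_tensor` with the same slice and feature
#'   extents.
#' @return numeric matrix (samples x rank), rownames = sample IDs when
#'   available.
#' @export
cp_project <- function(f, X) {
  ids <- NULL
  if (inherits(X, "fused_tensor")) { ids <- X$sample_ids; X <- X$values }
  d <- dim(X)
  if (d[2] != nrow(f$B) || d[3] != nrow(f$C)) {
    abort("slice/feature extents do not match the fitted factors",
          class = "tensoromics_schema_error")
  }
  G <- crossprod(f$C) * crossprod(f$B)
  A <- unfold_tensor(X, 1) %*% khatri_rao(f$C, f$B) %*% pinv(G)
  rownames(A) <- ids
  A
}

#' Match two CP solutions and measure factor congruence
#'
#' CP factors are identified only up to column permutation, scaling and
#' paired sign flips. Columns of `f1` are matched to columns of `f2` greedily
#' by the product over modes of absolute cosine similarity, and the per-mode
#' congruence (absolute cosine) of each matched pair is returned.
#'
#' @param f1,f2 `cp_factors` objects of equal rank and mode extents.
#' @return tibble with `component`, `matched_to`, `congruence_a`,
#'   `congruence_b`, `congruence_c`.
#' @export
factor_congruence <- function(f1, f2) {
  stopifnot(f1$rank == f2$rank)
  unit <- function(M) sweep(M, 2, pmax(sqrt(colSums(M^2)), .Machine$double.eps), "/")
  cosab <- function(M1, M2) abs(crossprod(unit(M1), unit(M2)))
  Ca <- cosab(f1$A, f2$A); Cb <- cosab(f1$B, f2$B); Cc <- cosab(f1$C, f2$C)
  score <- Ca * Cb * Cc
  R <- f1$rank
  perm <- integer(R)
  avail <- seq_len(R)
  for (r in order(-f1$lambda)) {
    j <- avail[which.max(score[r, avail])]
    perm[r] <- j
    avail <- setdiff(avail, j)
  }
  tibble(component = seq_len(R), matched_to = perm,
         congruence_a = Ca[cbind(seq_len(R), perm)],
         congruence_b = Cb[cbind(seq_len(R), perm)],
         congruence_c = Cc[cbind(seq_len(R), perm)])
}

#' Export CP factors as text artifacts
#'
#' Writes one CSV per mode (rows labelled by sample IDs, slice labels or
#' latent index) and a JSON with the weights, rank and fit.
#'
#' @param f `cp_factors`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_cp_factors <- function(f, dir, prefix = "cp") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in c("A", "B", "C")) {
    M <- f[[m]]
    tb <- as_tibble(as.data.frame(M))
    names(tb) <- paste0("component_", seq_len(ncol(M)))
    lbl <- rownames(M) %||% as.character(seq_len(nrow(M)))
    tb <- bind_cols(tibble(label = lbl), tb)
    p <- file.path(dir, sprintf("%s_mode_%s.csv", prefix, m))
    readr::write_csv(tb, p)
    paths <- c(paths, p)
  }
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(rank = f$rank, lambda = f$lambda, fit = f$fit,
                            n_iter = f$n_iter, converged = f$converged),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, js))
}
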