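#' Specify a synthetic multi-omics cohort
#'
#' Describes a cohort in which a small number of latent molecular programs
#' drive every omics assay and, through the first program, overall survival.
#' The first latent factor is the risk program and is given twice the standard
#' deviation of the nuisance factors, so it carries a dominant share of the
#' molecular variance; the second factor drives tumor purity.
#'
#' @param n_samples number of patients.
#' @param assay_dims named integer vector, feature count per assay. Defaults
#'   mimic a focal copy-number panel, miRNA, RNA-seq and methylation assay at
#'   desk scale.
#' @param latent_dim number of generative latent programs (>= 2 when
#'   `purity_effect` is non-zero).
#' @param risk_effect log hazard-ratio per unit of the first latent factor.
#' @param noise_sd standard deviation of the additive measurement noise.
#' @param censor_rate target marginal probability of right-censoring in
#'   `[0, 1]`.
#' @param purity_effect slope of the second latent factor on the logit of
#'   tumor purity.
#' @param seed integer seed; the same spec and seed reproduce the cohort
#'   bit-identically.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_samples = 300,
                        assay_dims = c(snv = 69, mirna = 800, rna = 2000, meth = 5000),
                        latent_dim = 4,
                        risk_effect = 1.1,
                        noise_sd = 0.1,
                        censor_rate = 0.3,
                        purity_effect = 1,
                        seed = 1L) {
  if (length(n_samples) != 1 || !is.finite(n_samples) || n_samples < 1) {
    abort("n_samples must be a positive count", class = "tensoromics_invalid_spec")
  }
  if (length(assay_dims) == 0 || any(assay_dims < 1)) {
    abort("assay_dims must be a nonempty vector of counts >= 1",
          class = "tensoromics_invalid_spec")
  }
  if (is.null(names(assay_dims)) || any(!nzchar(names(assay_dims)))) {
    names(assay_dims) <- paste0("assay", seq_along(assay_dims))
  }
  if (latent_dim < 1) abort("latent_dim must be >= 1", class = "tensoromics_invalid_spec")
  if (noise_sd < 0 || risk_effect < 0) {
    abort("noise_sd and risk_effect must be non-negative", class = "tensoromics_invalid_spec")
  }
  if (censor_rate < 0 || censor_rate > 1) {
    abort("censor_rate must lie in [0, 1]", class = "tensoromics_invalid_spec")
  }
  structure(
    list(n_samples = as.integer(n_samples), assay_dims = assay_dims,
         latent_dim = as.integer(latent_dim), risk_effect = risk_effect,
         noise_sd = noise_sd, censor_rate = censor_rate,
         purity_effect = purity_effect, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic multi-omics cohort with survival outcomes
#'
#' Draws latent factors `Z` (`n_samples x latent_dim`; factor 1 has sd 2,
#' the rest sd 1), per-assay Gaussian loading matrices, and builds each assay
#' as `Z %*% L + noise`, shifted so all values are positive with an
#' assay-specific offset. Survival times follow an exponential
#' proportional-hazards model with log-hazard `risk_effect * Z[, 1]`;
#' censoring times are independent exponentials calibrated so the marginal
#' censoring fraction matches `censor_rate`. Tumor purity is
#' `plogis(purity_effect * Z[, 2])` plus Gaussian noise, clipped to `[0, 1]`.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements
#'   * `assays`: named list of omics tibbles (`sample_id` + feature columns),
#'   * `clinical`: tibble with `sample_id`, `os_time` (days), `os_event`,
#'     `tumor_purity`,
#'   * `latent`: the true latent factor tibble (ground truth for tests).
#'   * `loadings`: the per-assay true loading matrices (latent x features).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_samples = 50,
#'   assay_dims = c(a = 10, b = 20), seed = 1))
#' names(cohort$assays)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n_samples
  withr::with_seed(spec$seed, {
    ids <- sprintf("S%04d", seq_len(n))
    factor_sd <- c(2, rep(1, spec$latent_dim - 1))[seq_len(spec$latent_dim)]
    Z <- matrix(rnorm(n * spec$latent_dim), n) %*% diag(factor_sd, spec$latent_dim)

    loadings <- list()
    assays <- imap(as.list(spec$assay_dims), function(d, nm) {
      L <- matrix(rnorm(spec$latent_dim * d, sd = 1 / sqrt(spec$latent_dim)),
                  spec$latent_dim, d,
                  dimnames = list(NULL, paste0(nm, "_f", seq_len(d))))
      loadings[[nm]] <<- L
      V <- Z %*% L + matrix(rnorm(n * d, sd = spec$noise_sd), n)
      V <- V - min(V) + match(nm, names(spec$assay_dims))  # positive, assay-specific offset
      new_omics_tbl(V, ids, colnames(L), nm)
    })

    base_rate <- 1 / 1000  # median uncensored survival ~693 days
    t_event <- rexp(n, rate = base_rate * exp(spec$risk_effect * Z[, 1]))
    if (spec$censor_rate >= 1) {
      os_time <- t_event * runif(n)
      os_event <- rep(0L, n)
    } else if (spec$censor_rate <= 0) {
      os_time <- t_event
      os_event <- rep(1L, n)
    } else {
      # calibrate the censoring rate c so that mean_i P(C < t_i) = censor_rate
      f <- function(cr) mean(1 - exp(-cr * t_event)) - spec$censor_rate
      cr <- uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-12)$root
      t_cens <- rexp(n, rate = cr)
      os_event <- as.integer(t_event <= t_cens)
      os_time <- pmin(t_event, t_cens)
    }

    purity <- plogis(spec$purity_effect * Z[, 2]) + rnorm(n, sd = 0.05)
    purity <- pmin(pmax(purity, 0), 1)

    clinical <- tibble(sample_id = ids, os_time = os_time,
                       os_event = os_event, tumor_purity = purity)
    latent <- as_tibble(as.data.frame(Z))
    names(latent) <- paste0("factor_", seq_len(spec$latent_dim))
    latent <- bind_cols(tibble(sample_id = ids), latent)
    list(assays = assays, clinical = clinical, latent = latent, loadings = loadings)
  })
}

#' Generate a noisy low-rank 3-way tensor with known CP factors
#'
#' Builds `sum_r lambda_r a_r o b_r o c_r` from random unit-norm factor
#' columns with decreasing positive weights, plus i.i.d. Gaussian noise.
#' Used as ground truth for CP-recovery tests.
#'
#' @param shape integer vector `(I, J, K)`.
#' @param rank number of rank-one components; must not exceed `min(shape)`
#'   so recovery is identifiable.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer seed.
#' @return list with `tensor` (3-way array) and `factors` (a [cp_factors]
#'   object holding the generating weights and factor matrices).
#' @export
generate_lowrank_tensor <- function(shape, rank, noise_sd = 0, seed = 1L) {
  if (length(shape) != 3 || any(shape < 1)) {
    abort("shape must be three positive extents", class = "tensoromics_invalid_spec")
  }
  if (rank < 1) abort("rank must be >= 1", class = "tensoromics_invalid_spec")
  if (rank > min(shape)) {
    abort("rank must not exceed min(shape) for identifiable fixtures",
          class = "tensoromics_invalid_spec")
  }
  withr::with_seed(seed, {
    unit_cols <- function(nr) {
      M <- matrix(rnorm(nr * rank), nr, rank)
      sweep(M, 2, sqrt(colSums(M^2)), "/")
    }
    A <- unit_cols(shape[1]); B <- unit_cols(shape[2]); C <- unit_cols(shape[3])
    lambda <- sort(runif(rank, 1, 3), decreasing = TRUE)
    X <- cp_reconstruct(new_cp_factors(lambda, A, B, C))
    if (noise_sd > 0) X <- X + array(rnorm(prod(shape), sd = noise_sd), dim = shape)
    list(tensor = X, factors = new_cp_factors(lambda, A, B, C))
  })
}

#' Write a synthetic cohort to disk in the layout the pipeline reads
#'
#' One TSV per assay (samples as rows, `sample_id` first column) and a
#' clinical TSV with `sample_id`, `os_time`, `os_event`, `tumor_purity`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory, created if needed.
#' @return invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- imap(cohort$assays, function(m, nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(m, p)
    p
  })
  clin <- file.path(dir, "clinical.tsv")
  readr::write_tsv(cohort$clinical, clin)
  invisible(c(unlist(paths), clinical = clin))
}
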