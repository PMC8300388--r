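#' Random k-fold assignment
#'
#' Partitions `n` individuals into `k` folds whose sizes differ by at most
#' one.
#'
#' @param n number of individuals.
#' @param k number of folds (>= 2, <= n).
#' @param seed integer seed.
#' @return integer vector of fold labels, length `n`.
#' @export
make_folds <- function(n, k, seed = 1) {
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k must be <= n")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Repeated k-fold cross-validated GEBV accuracy
#'
#' For each repeat, individuals are split into `n_folds` folds; for each
#' fold, variance components are re-estimated by [ai_reml()] on the training
#' folds and the mixed-model equations are solved jointly over all
#' individuals, the held-out fold being unphenotyped. The held-out GEBVs are
#' pooled over the folds of a repeat and correlated (Pearson) with the
#' phenotype - one accuracy per repeat. Folds whose REML fit did not
#' converge are flagged, excluded from the pooled correlation, and reported
#' with a warning.
#'
#' @param dataset a `genotype_dataset`.
#' @param phenotypes data frame with `sample_id` plus trait columns, or a
#'   named numeric vector.
#' @param panel optional [panel_selection()]; markers are restricted through
#'   [subset_markers()] before the GRM is built.
#' @param trait trait column to use (default: first non-ID column).
#' @param n_folds,n_repeats cross-validation geometry (default 10 x 10).
#' @param seed master seed; repeat `r` uses `seed + r`.
#' @return a list of class `cv_result`: `accuracies` (one per repeat),
#'   `mean_accuracy`, `sd_accuracy`, `folds` (n x n_repeats matrix),
#'   `variance_components` (per repeat x fold data frame), `n_excluded`,
#'   `seed`.
#' @export
cv_accuracy <- function(dataset, phenotypes, panel = NULL, trait = NULL,
                        n_folds = 10, n_repeats = 10, seed = 1) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!is.null(panel)) dataset <- subset_markers(dataset, panel)

  if (is.numeric(phenotypes) && !is.null(names(phenotypes))) {
    ids <- names(phenotypes); y_all <- unname(phenotypes)
    if (is.null(trait)) trait <- "trait"
  } else {
    if (is.null(trait)) {
      trait <- setdiff(names(phenotypes), "sample_id")[1]
    }
    ids <- phenotypes$sample_id; y_all <- phenotypes[[trait]]
  }
  keep <- dataset$samples %in% ids
  ds <- if (all(keep)) dataset else {
    genotype_dataset(dataset$dosages[keep, , drop = FALSE], dataset$map,
                     dataset$samples[keep])
  }
  y <- y_all[match(ds$samples, ids)]
  n <- length(y)
  G <- build_grm(ds)

  acc <- numeric(n_repeats)
  folds_mat <- matrix(NA_integer_, n, n_repeats)
  vc_rows <- list()
  n_excl <- 0L
  for (r in seq_len(n_repeats)) {
    folds <- make_folds(n, n_folds, seed + r)
    folds_mat[, r] <- folds
    gebv <- rep(NA_real_, n)
    ok <- rep(TRUE, n)
    for (f in seq_len(n_folds)) {
      tr <- which(folds != f)
      vc <- ai_reml(y[tr], G[tr, tr])
      fit <- solve_mme(y[tr], G, vc, train = tr)
      gebv[folds == f] <- fit$g_hat[folds == f]
      vc_rows[[length(vc_rows) + 1]] <- data.frame(
        repeat_ = r, fold = f, sigma_g2 = vc$sigma_g2,
        sigma_e2 = vc$sigma_e2, converged = vc$converged)
      if (!vc$converged) {
        ok[folds == f] <- FALSE
        n_excl <- n_excl + 1L
        warning("REML did not converge in repeat ", r, " fold ", f,
                "; fold excluded from pooling", call. = FALSE)
      }
    }
    acc[r] <- stats::cor(gebv[ok], y[ok])
  }

  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc), folds = folds_mat,
                 variance_components = do.call(rbind, vc_rows),
                 n_excluded = n_excl, trait = trait, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): mean accuracy %.4f (sd %.4f) over %d repeat(s)\n",
              x$trait, x$mean_accuracy, x$sd_accuracy, length(x$accuracies)))
  invisible(x)
}
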