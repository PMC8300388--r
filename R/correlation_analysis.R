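#' Within-level z-standardization
#'
#' Standardizes values to mean 0 and sample standard deviation 1 (n - 1
#' denominator) separately within each level, so every SNP-number level
#' contributes equally to a pooled correlation.
#'
#' @param x numeric values.
#' @param level grouping factor (same length as `x`).
#' @return numeric vector of standardized values, order preserved.
#' @export
standardize_within_level <- function(x, level) {
  stopifnot(length(x) == length(level))
  sds <- tapply(x, level, stats::sd)
  bad <- names(sds)[!is.finite(sds) | sds == 0]
  if (length(bad) > 0) {
    stop("zero or undefined standard deviation within level(s): ",
         paste(bad, collapse = ", "))
  }
  stats::ave(x, level, FUN = function(v) (v - mean(v)) / stats::sd(v))
}

#' Pooled within-level-standardized correlation test
#'
#' Standardizes one density measurement and each selected trait's accuracy
#' within every SNP-number level, pairs each standardized measurement value
#' with the standardized accuracies of its own row, pools the pairs across
#' rows and traits, and tests the Pearson correlation with the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df (two-sided).
#'
#' @param table a panel summary table: data frame with columns `snp_level`,
#'   `method`, the measurement columns `sigma_d2_1e10`, `r2_mean`, `r2_var`,
#'   and accuracy columns `acc_<trait>`.
#' @param measure one of `"sigma_d2"`, `"r2_mean"`, `"r2_var"` (the first is
#'   matched to column `sigma_d2_1e10`).
#' @param traits character vector of trait names (default: all `acc_*`
#'   columns).
#' @param levels optional subset of SNP-number levels to pool over.
#' @return a list of class `correlation_test`: `r`, `t_value`, `p_value`,
#'   `n_pairs`, `measure`, `traits`, `levels`.
#' @export
pooled_correlation <- function(table, measure = c("sigma_d2", "r2_mean",
                                                  "r2_var"),
                               traits = NULL, levels = NULL) {
  measure <- match.arg(measure)
  mcol <- if (measure == "sigma_d2") "sigma_d2_1e10" else measure
  if (!mcol %in% names(table)) stop("missing column: ", mcol)
  if (is.null(traits)) {
    traits <- sub("^acc_", "", grep("^acc_", names(table), value = TRUE))
  }
  if (!is.null(levels)) table <- table[table$snp_level %in% levels, ]
  zx <- standardize_within_level(table[[mcol]], table$snp_level)
  xx <- numeric(0); yy <- numeric(0)
  for (tr in traits) {
    acol <- paste0("acc_", tr)
    if (!acol %in% names(table)) stop("missing column: ", acol)
    zy <- standardize_within_level(table[[acol]], table$snp_level)
    xx <- c(xx, zx); yy <- c(yy, zy)
  }
  n <- length(xx)
  if (n < 3) stop("fewer than 3 pairs")
  r <- stats::cor(xx, yy)
  t_value <- r * sqrt((n - 2) / (1 - r^2))
  p_value <- 2 * stats::pt(-abs(t_value), df = n - 2)
  structure(list(r = r, t_value = t_value, p_value = p_value, n_pairs = n,
                 measure = measure, traits = traits,
                 levels = sort(unique(table$snp_level))),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("correlation_test: %s vs accuracy(%s) over levels {%s}\n  r = %.4f, t = %.3f, p = %.4g (n = %d pairs)\n",
              x$measure, paste(x$traits, collapse = ","),
              paste(x$levels, collapse = ","), x$r, x$t_value, x$p_value,
              x$n_pairs))
  invisible(x)
}

## md5 of the packaged panel-summary fixture, fixed at package build
.table1_md5 <- "4fd079515e73daa24e96f4fee901dfba"

#' Load the packaged low/moderate-density panel summary table
#'
#' The packaged 33-row table (11 SNP-number levels x 3 pruning methods) of
#' density measurements (gap variance in 10^10 bp^2, adjacent-r2 mean and
#' variance) and cross-validated GEBV accuracies for three dairy traits,
#' from the Holstein reference analysis. The file's md5 checksum is
#' verified on load.
#'
#' @param path path to the CSV (defaults to the copy shipped in the
#'   package).
#' @return data frame of class `panel_summary` with columns `snp_level`
#'   (thousands of SNPs), `method`, `sigma_d2_1e10`, `r2_mean`, `r2_var`,
#'   `acc_FP`, `acc_MY`, `acc_SCS`.
#' @export
load_table1_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_panel_summary.csv",
                        package = "panelprune", mustWork = TRUE)
  }
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .table1_md5)) {
    stop("integrity error: panel summary fixture checksum mismatch (",
         md5, ")")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("snp_level", "method", "sigma_d2_1e10", "r2_mean", "r2_var",
            "acc_FP", "acc_MY", "acc_SCS")
  if (!all(need %in% names(tab))) stop("malformed panel summary table")
  cnt <- table(tab$snp_level)
  if (any(cnt != 3)) stop("each level must carry exactly 3 methods")
  class(tab) <- c("panel_summary", "data.frame")
  tab
}

#' Pairwise relative accuracy differences between pruning methods
#'
#' For each level and trait, the percent difference of each method's
#' accuracy relative to each other method - a raw view of how much one
#' pruning strategy gains over another at matched panel sizes.
#'
#' @param table a panel summary table (see [load_table1_fixture()]).
#' @param levels optional subset of levels.
#' @return data frame with columns `snp_level`, `trait`, `method`,
#'   `baseline`, `rel_diff_pct`.
#' @export
accuracy_relative_differences <- function(table, levels = NULL) {
  if (!is.null(levels)) table <- table[table$snp_level %in% levels, ]
  traits <- sub("^acc_", "", grep("^acc_", names(table), value = TRUE))
  out <- list()
  for (lev in unique(table$snp_level)) {
    sub <- table[table$snp_level == lev, ]
    for (tr in traits) {
      a <- stats::setNames(sub[[paste0("acc_", tr)]], sub$method)
      for (m1 in names(a)) for (m2 in setdiff(names(a), m1)) {
        out[[length(out) + 1]] <- data.frame(
          snp_level = lev, trait = tr, method = m1, baseline = m2,
          rel_diff_pct = 100 * (a[[m1]] - a[[m2]]) / a[[m2]])
      }
    }
  }
  do.call(rbind, out)
}
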