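#' Physical gaps between adjacent markers
#'
#' Gaps are computed only between consecutive markers on the same chromosome;
#' the result has length `n_markers - n_chromosomes`.
#'
#' @param map a marker map (sorted by chromosome, position).
#' @return integer vector of bp gaps (empty with a warning if no chromosome
#'   holds two markers).
#' @export
adjacent_gaps <- function(map) {
  map <- validate_marker_map(map)
  g <- unlist(lapply(split(map$position_bp, map$chromosome), diff),
              use.names = FALSE)
  if (length(g) == 0) {
    warning("no chromosome holds two markers; no gaps defined")
    return(integer(0))
  }
  g
}

#' r2 between adjacent markers
#'
#' Squared Pearson correlation of dosage columns for every within-chromosome
#' adjacent pair. Pairs in which either column is monomorphic have no defined
#' correlation; they are skipped and counted in attribute
#' `"n_monomorphic_skipped"`.
#'
#' @param dataset a `genotype_dataset`.
#' @return numeric vector of r2 values in `[0, 1]`.
#' @export
adjacent_r2 <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  map <- dataset$map
  m <- nrow(map)
  if (m < 2) return(structure(numeric(0), n_monomorphic_skipped = 0L))
  left <- which(map$chromosome[-m] == map$chromosome[-1])
  if (length(left) == 0) return(structure(numeric(0),
                                          n_monomorphic_skipped = 0L))
  D <- dataset$dosages
  if (anyNA(D)) {
    r2 <- vapply(left, function(i) {
      suppressWarnings(stats::cor(D[, i], D[, i + 1],
                                  use = "complete.obs"))^2
    }, numeric(1))
  } else {
    X <- D[, left, drop = FALSE]; Y <- D[, left + 1, drop = FALSE]
    n <- nrow(D)
    mx <- colMeans(X); my <- colMeans(Y)
    sxy <- colSums(X * Y) - n * mx * my
    sxx <- colSums(X * X) - n * mx^2
    syy <- colSums(Y * Y) - n * my^2
    r2 <- sxy^2 / (sxx * syy)
  }
  skipped <- !is.finite(r2)
  structure(pmin(1, r2[!skipped]),
            n_monomorphic_skipped = sum(skipped))
}

#' Marker-density measurements for a panel
#'
#' The four density statistics of a panel: mean and variance of the physical
#' distance between adjacent SNPs, and mean and variance of the adjacent-pair
#' r2. Variances are sample variances (n - 1 denominator). `d_var_1e10`
#' restates the gap variance in 10^10 bp^2 units, the convention used when
#' tabulating panels.
#'
#' @param dataset a `genotype_dataset`, already restricted to the panel.
#' @return a list of class `density_measures` with `d_mean`, `d_var`,
#'   `d_var_1e10`, `r2_mean`, `r2_var`, `n_gaps`, `n_r2`,
#'   `n_monomorphic_skipped`.
#' @export
density_measures <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  gaps <- adjacent_gaps(dataset$map)
  if (length(gaps) < 2) stop("fewer than 2 gaps: variance undefined")
  r2 <- adjacent_r2(dataset)
  structure(list(
    d_mean = mean(gaps), d_var = stats::var(gaps),
    d_var_1e10 = stats::var(gaps) / 1e10,
    r2_mean = if (length(r2) > 0) mean(r2) else NA_real_,
    r2_var = if (length(r2) > 1) stats::var(r2) else NA_real_,
    n_gaps = length(gaps), n_r2 = length(r2),
    n_monomorphic_skipped = attr(r2, "n_monomorphic_skipped")),
    class = "density_measures")
}

#' @export
print.density_measures <- function(x, ...) {
  cat(sprintf("density_measures: d_mean %.1f bp, d_var %.4g bp^2, r2_mean %.4f, r2_var %.4g (%d gaps)\n",
              x$d_mean, x$d_var, x$r2_mean, x$r2_var, x$n_gaps))
  invisible(x)
}

#' One-row text summary of a panel's density measurements
#'
#' @param dm a `density_measures`.
#' @param method,n_markers identifiers to prepend.
#' @return a one-row data frame (method, n_markers, d_mean, d_var, r2_mean,
#'   r2_var).
#' @export
density_row <- function(dm, method, n_markers) {
  data.frame(method = method, n_markers = n_markers, d_mean = dm$d_mean,
             d_var = dm$d_var, r2_mean = dm$r2_mean, r2_var = dm$r2_var,
             stringsAsFactors = FALSE)
}
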