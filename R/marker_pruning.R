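#' Panel selection container
#'
#' An ordered subset of marker columns defining one SNP panel, together with
#' the method and threshold that produced it.
#'
#' @param method one of `"PhyD"`, `"GenD"`, `"RanD"`, `"scenario"`.
#' @param indices sorted, unique marker column indices (genome order).
#' @param threshold the bp or r2 threshold used (`NA` when not applicable).
#' @param target_count requested panel size (`NA` when not applicable).
#' @param seed seed used for any randomised step (`NA` if none).
#' @return a list of class `panel_selection`.
#' @export
panel_selection <- function(method, indices, threshold = NA,
                            target_count = NA, seed = NA) {
  indices <- as.integer(indices)
  if (length(indices) == 0) stop("a panel must contain at least one marker")
  if (is.unsorted(indices, strictly = TRUE)) {
    stop("panel indices must be sorted and unique")
  }
  structure(list(method = method, threshold = threshold,
                 indices = indices, target_count = target_count, seed = seed),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("panel_selection:", x$method, "-", length(x$indices), "markers",
      if (!is.na(x$threshold)) paste0("(threshold ", signif(x$threshold, 4), ")"),
      "\n")
  invisible(x)
}

#' @export
length.panel_selection <- function(x) length(x$indices)

#' Write a panel as a marker-ID list
#'
#' One marker ID per line, compatible with PLINK's `--extract`.
#'
#' @param selection a `panel_selection`.
#' @param map the marker map the indices refer to.
#' @param path output file.
#' @export
write_panel <- function(selection, map, path) {
  writeLines(map$marker_id[selection$indices], path)
  invisible(path)
}

#' Physical-distance pruning (PhyD)
#'
#' Greedy left-to-right scan per chromosome: keep the first marker, then keep
#' the next marker whose distance from the last kept marker is at least
#' `min_gap_bp`. Every adjacent kept pair within a chromosome therefore has a
#' gap of at least the threshold.
#'
#' @param map a marker map (sorted by chromosome, position).
#' @param min_gap_bp minimum physical distance in bp between adjacent kept
#'   markers (0 keeps everything).
#' @return a [panel_selection()] of method `"PhyD"`.
#' @export
prune_phyd <- function(map, min_gap_bp) {
  map <- validate_marker_map(map)
  if (min_gap_bp < 0) stop("min_gap_bp must be >= 0")
  keep <- logical(nrow(map))
  for (idx in split(seq_len(nrow(map)), map$chromosome)) {
    pos <- map$position_bp[idx]
    last <- -Inf
    for (i in seq_along(idx)) {
      if (pos[i] - last >= min_gap_bp) {
        keep[idx[i]] <- TRUE
        last <- pos[i]
      }
    }
  }
  sel <- panel_selection("PhyD", which(keep), threshold = min_gap_bp)
  stopifnot(phyd_min_gap(map, sel$indices) >= min_gap_bp)
  sel
}

## smallest adjacent within-chromosome gap among kept markers (Inf if none)
phyd_min_gap <- function(map, indices) {
  g <- unlist(lapply(split(map$position_bp[indices],
                           map$chromosome[indices]), diff),
              use.names = FALSE)
  if (length(g) == 0) Inf else min(g)
}

#' LD-based pruning (GenD)
#'
#' Sliding-window pairwise-r2 pruning: within each window of `window_kb` kb
#' of physical span, compute r2 (squared Pearson correlation of dosages)
#' between every pair of surviving markers and, while any pair exceeds
#' `r2_max`, remove one member; the window then advances by `step_kb` kb.
#' Windows never span chromosome boundaries. When a pair exceeds the
#' threshold the member with the smaller minor allele frequency is removed
#' (ties: the later, higher-position member) - a deterministic rule. A final
#' verification pass rescans every window position and stops if any
#' surviving pair still exceeds the threshold.
#'
#' @param dataset a `genotype_dataset`.
#' @param r2_max maximum tolerated pairwise r2, in `(0, 1]`.
#' @param window_kb,step_kb window span and step in kb; the window must not
#'   be smaller than the step.
#' @return a [panel_selection()] of method `"GenD"`.
#' @export
prune_gend <- function(dataset, r2_max, window_kb = 50, step_kb = 5) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!(r2_max > 0 && r2_max <= 1)) stop("r2_max must be in (0, 1]")
  if (window_kb < step_kb) stop("window smaller than step")
  map <- dataset$map
  D <- dataset$dosages
  maf <- pmin(colMeans(D, na.rm = TRUE) / 2,
              1 - colMeans(D, na.rm = TRUE) / 2)
  keep <- rep(TRUE, nrow(map))
  for (idx in split(seq_len(nrow(map)), map$chromosome)) {
    pos <- map$position_bp[idx]
    for (s in window_starts(pos, window_kb, step_kb)) {
      inw <- idx[pos >= s & pos < s + window_kb * 1000]
      inw <- inw[keep[inw]]
      if (length(inw) < 2) next
      keep[prune_window(D, map, maf, inw, r2_max)] <- FALSE
    }
  }
  sel <- panel_selection("GenD", which(keep), threshold = r2_max)
  viol <- gend_violations(dataset, sel$indices, r2_max, window_kb, step_kb)
  if (nrow(viol) > 0) stop("internal error: LD pruning left violating pairs")
  sel
}

window_starts <- function(pos, window_kb, step_kb) {
  if (length(pos) < 2) return(numeric(0))
  seq(min(pos), max(pos), by = step_kb * 1000)
}

## Remove-loop for one window; returns the global indices to drop.
prune_window <- function(D, map, maf, inw, r2_max) {
  R2 <- suppressWarnings(stats::cor(D[, inw, drop = FALSE],
                                    use = "pairwise.complete.obs"))^2
  R2[!is.finite(R2)] <- 0
  diag(R2) <- 0
  drop <- integer(0)
  repeat {
    mx <- max(R2)
    if (mx <= r2_max) break
    hit <- which(R2 == mx, arr.ind = TRUE)[1, ]
    i <- inw[hit[1]]; j <- inw[hit[2]]
    victim <- if (maf[i] < maf[j]) i
              else if (maf[j] < maf[i]) j
              else max(i, j)                              # tie: later position
    k <- which(inw == victim)
    R2[k, ] <- 0; R2[, k] <- 0
    drop <- c(drop, victim)
  }
  drop
}

## Rescan all window positions over a pruned panel; returns violating pairs.
## The window grid is anchored at the full chromosome's first marker - the
## same grid the pruning pass walked - so the check is exact, not shifted.
gend_violations <- function(dataset, indices, r2_max, window_kb = 50,
                            step_kb = 5) {
  map <- dataset$map
  out <- list()
  for (idx in split(indices, map$chromosome[indices])) {
    pos <- map$position_bp[idx]
    full_pos <- map$position_bp[map$chromosome == map$chromosome[idx[1]]]
    for (s in window_starts(full_pos, window_kb, step_kb)) {
      inw <- idx[pos >= s & pos < s + window_kb * 1000]
      if (length(inw) < 2) next
      R2 <- suppressWarnings(stats::cor(dataset$dosages[, inw, drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      R2[!is.finite(R2)] <- 0
      diag(R2) <- 0
      hits <- which(R2 > r2_max, arr.ind = TRUE)
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
      if (nrow(hits) > 0) {
        out[[length(out) + 1]] <- data.frame(i = inw[hits[, 1]],
                                             j = inw[hits[, 2]],
                                             r2 = R2[hits])
      }
    }
  }
  if (length(out) == 0) data.frame(i = integer(0), j = integer(0),
                                   r2 = numeric(0))
  else unique(do.call(rbind, out))
}

#' Random pruning (RanD)
#'
#' Uniform sample of markers without replacement, returned in genome order.
#'
#' @param map a marker map.
#' @param n_target panel size, `1 <= n_target <=` number of markers.
#' @param seed integer seed.
#' @return a [panel_selection()] of method `"RanD"`.
#' @export
prune_rand <- function(map, n_target, seed = 1) {
  m <- nrow(map)
  if (n_target < 1 || n_target > m) stop("n_target out of range")
  set.seed(seed)
  panel_selection("RanD", sort(sample.int(m, n_target)),
                  target_count = n_target, seed = seed)
}

#' Prune to an exact panel size
#'
#' Bisects the method's threshold (bp gap for PhyD, r2 for GenD) until the
#' achieved panel size brackets `n_target`, then enforces the exact count by
#' seeded uniform removal of surplus markers from the larger bracketing
#' panel. PhyD panel size is non-increasing in the gap threshold; GenD panel
#' size is non-decreasing in the r2 threshold. The GenD search is capped at
#' r2 = 0.999, so perfect-LD duplicates always collapse and a panel-size
#' ceiling exists; a target above the ceiling raises a "target unreachable"
#' error reporting the achievable maximum.
#'
#' @param dataset a `genotype_dataset`.
#' @param method `"PhyD"` or `"GenD"`.
#' @param n_target exact panel size wanted.
#' @param seed seed for the surplus-removal draw.
#' @param window_kb,step_kb GenD window geometry.
#' @return a [panel_selection()] with exactly `n_target` markers.
#' @export
prune_to_count <- function(dataset, method = c("PhyD", "GenD"), n_target,
                           seed = 1, window_kb = 50, step_kb = 5) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "genotype_dataset"))
  m <- nrow(dataset$map)
  if (n_target < 1 || n_target > m) stop("n_target out of range")

  if (method == "PhyD" && n_target == m) {
    return(panel_selection(method, seq_len(m), threshold = 0,
                           target_count = n_target, seed = seed))
  }
  if (method == "PhyD") {
    count_at <- function(thr) prune_phyd(dataset$map, thr)
    lo <- 0
    hi <- max(unlist(lapply(split(dataset$map$position_bp,
                                  dataset$map$chromosome),
                            function(p) diff(range(p))))) + 1
    sel_lo <- count_at(lo)                                # largest panel
    if (length(sel_lo) < n_target) {
      stop("target unreachable: at most ", length(sel_lo),
           " markers selectable")
    }
    sel_hi <- count_at(hi)
    if (length(sel_hi) >= n_target) {
      sel <- sel_hi
    } else {
      ## invariant: count(lo) >= n_target > count(hi)
      while (hi - lo > 1) {
        mid <- (lo + hi) %/% 2
        s <- count_at(mid)
        if (length(s) >= n_target) { lo <- mid; sel_lo <- s } else hi <- mid
      }
      sel <- sel_lo
    }
  } else {
    cap <- 0.999
    count_at <- function(thr) prune_gend(dataset, thr, window_kb, step_kb)
    sel_cap <- count_at(cap)
    if (length(sel_cap) < n_target) {
      stop("target unreachable: at most ", length(sel_cap),
           " markers selectable at r2 <= ", cap)
    }
    lo <- 1e-6; hi <- cap; sel_hi <- sel_cap
    sel_lo0 <- count_at(lo)
    if (length(sel_lo0) >= n_target) {
      sel <- sel_lo0; hi <- lo
    } else {
      ## invariant: count(hi) >= n_target > count(lo)
      while (hi - lo > 1e-4) {
        mid <- (lo + hi) / 2
        s <- count_at(mid)
        if (length(s) >= n_target) { hi <- mid; sel_hi <- s } else lo <- mid
      }
      sel <- sel_hi
    }
  }

  surplus <- length(sel) - n_target
  idx <- sel$indices
  if (surplus > 0) {
    set.seed(seed)
    idx <- sort(idx[-sample.int(length(idx), surplus)])
  }
  panel_selection(method, idx, threshold = sel$threshold,
                  target_count = n_target, seed = seed)
}

#' Rank-gap scenario sampler
#'
#' Walks the genome-ordered marker list by rank: start at marker 1 and
#' repeatedly advance by a gap of markers - the constant `mean_gap` when
#' `gap_variance` is 0, otherwise an integer drawn from
#' `Normal(mean_gap, sqrt(gap_variance))`, rounded to the nearest integer and
#' truncated below at 1 - until the index exceeds `n_markers_total`. All
#' resulting panels share the same mean rank gap but differ in its variance.
#'
#' @param n_markers_total number of markers in the genome-ordered list.
#' @param mean_gap mean rank gap (default 67).
#' @param gap_variance variance of the normal gap draw (0 = deterministic).
#' @param seed integer seed.
#' @return a [panel_selection()] of method `"scenario"` whose indices are
#'   1-based ranks.
#' @export
scenario_gap_sample <- function(n_markers_total, mean_gap = 67,
                                gap_variance = 0, seed = 1) {
  if (mean_gap < 1) stop("mean_gap must be >= 1")
  if (gap_variance < 0) stop("gap_variance must be >= 0")
  if (mean_gap >= n_markers_total) stop("mean_gap must be < n_markers_total")
  set.seed(seed)
  if (gap_variance == 0) {
    idx <- seq(1L, n_markers_total, by = as.integer(mean_gap))
  } else {
    sd <- sqrt(gap_variance)
    idx <- 1
    repeat {
      gaps <- pmax(1L, as.integer(round(stats::rnorm(
        ceiling(2 * n_markers_total / mean_gap) + 10, mean_gap, sd))))
      idx <- c(idx, idx[length(idx)] + cumsum(gaps))
      if (idx[length(idx)] > n_markers_total) break
    }
    idx <- idx[idx <= n_markers_total]
  }
  panel_selection("scenario", idx, threshold = NA, seed = seed)
}
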