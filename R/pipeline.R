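#' End-to-end panel evaluation pipeline
#'
#' Simulates (or accepts) a genotype dataset and phenotypes, builds the grid
#' of panels over pruning methods and SNP-number levels, computes each
#' panel's density measurements and repeated k-fold cross-validated GEBV
#' accuracies per trait, assembles a panel summary table and runs the pooled
#' within-level-standardized correlation analysis on it. LD-pruning targets
#' above the achievable ceiling are recorded as skipped panels rather than
#' failing the run. Everything is written as plain text under `out_dir`;
#' identical configuration and seeds reproduce the outputs byte for byte.
#'
#' @param levels integer vector of panel sizes (marker counts).
#' @param methods subset of `c("PhyD", "GenD", "RanD")`.
#' @param config a [sim_config()] used when `dataset` is `NULL`.
#' @param dataset,phenotype_list optional pre-built `genotype_dataset` and
#'   named list of phenotype data frames (one per trait); when `NULL` both
#'   are simulated from `config` and `architectures`.
#' @param architectures named list of [trait_architecture()] objects used
#'   when simulating.
#' @param n_folds,n_repeats cross-validation geometry.
#' @param seed master seed for pruning/CV randomness.
#' @param out_dir output directory (created; must not pre-exist unless
#'   empty).
#' @return invisibly, a list with `summary_table`, `correlations`,
#'   `skipped`, `out_dir`.
#' @export
run_pipeline <- function(levels, methods = c("PhyD", "GenD", "RanD"),
                         config = sim_config(), dataset = NULL,
                         phenotype_list = NULL,
                         architectures = list(
                           FP = trait_architecture("FP_like"),
                           MY = trait_architecture("MY_like"),
                           SCS = trait_architecture("SCS_like")),
                         n_folds = 10, n_repeats = 10, seed = 1,
                         out_dir = tempfile("panelprune_run_")) {
  methods <- match.arg(methods, c("PhyD", "GenD", "RanD"),
                       several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "panels"), showWarnings = FALSE)

  if (is.null(dataset)) {
    map <- simulate_marker_map(config)
    dataset <- simulate_genotypes(map, config)
  }
  if (is.null(phenotype_list)) {
    phenotype_list <- lapply(seq_along(architectures), function(i) {
      simulate_trait(dataset, architectures[[i]],
                     seed = config$seed + 100 + i)$phenotypes
    })
    names(phenotype_list) <- names(architectures)
  }
  traits <- names(phenotype_list)

  rows <- list(); skipped <- list(); metrics <- list(); cv_rows <- list()
  for (lev in levels) {
    for (met in methods) {
      sel <- tryCatch(
        switch(met,
               RanD = prune_rand(dataset$map, lev, seed = seed + lev),
               prune_to_count(dataset, met, lev, seed = seed + lev)),
        error = function(e) {
          if (grepl("target unreachable", conditionMessage(e))) NULL
          else stop(e)
        })
      if (is.null(sel)) {
        skipped[[length(skipped) + 1]] <- data.frame(snp_level = lev,
                                                     method = met)
        next
      }
      write_panel(sel, dataset$map,
                  file.path(out_dir, "panels",
                            sprintf("%s_%d.txt", met, lev)))
      panel_ds <- subset_markers(dataset, sel)
      dm <- density_measures(panel_ds)
      metrics[[length(metrics) + 1]] <- density_row(dm, met, lev)

      accs <- numeric(length(traits))
      for (ti in seq_along(traits)) {
        cv <- cv_accuracy(panel_ds, phenotype_list[[ti]],
                          n_folds = n_folds, n_repeats = n_repeats,
                          seed = seed + 1000 * ti + lev)
        accs[ti] <- cv$mean_accuracy
        cv_rows[[length(cv_rows) + 1]] <- data.frame(
          snp_level = lev, method = met, trait = traits[ti],
          repeat_ = seq_along(cv$accuracies), accuracy = cv$accuracies)
      }
      row <- data.frame(snp_level = lev, method = met,
                        sigma_d2_1e10 = dm$d_var_1e10,
                        r2_mean = dm$r2_mean, r2_var = dm$r2_var)
      for (ti in seq_along(traits)) row[[paste0("acc_", traits[ti])]] <- accs[ti]
      rows[[length(rows) + 1]] <- row
    }
  }
  summary_table <- do.call(rbind, rows)
  class(summary_table) <- c("panel_summary", "data.frame")

  correlations <- NULL
  full_levels <- unique(summary_table$snp_level[
    stats::ave(seq_len(nrow(summary_table)), summary_table$snp_level,
               FUN = length) == 3])
  if (length(full_levels) >= 2) {
    cor_tab <- summary_table[summary_table$snp_level %in% full_levels, ]
    correlations <- tryCatch(
      do.call(rbind, lapply(c("sigma_d2", "r2_mean", "r2_var"), function(ms) {
        ct <- pooled_correlation(cor_tab, ms)
        data.frame(measure = ms, r = ct$r, t_value = ct$t_value,
                   p_value = ct$p_value, n_pairs = ct$n_pairs)
      })), error = function(e) NULL)
  }

  utils::write.csv(do.call(rbind, metrics),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, cv_rows),
                   file.path(out_dir, "cv_results.csv"), row.names = FALSE)
  utils::write.csv(summary_table, file.path(out_dir, "summary_table.csv"),
                   row.names = FALSE)
  if (!is.null(correlations)) {
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
  }
  manifest <- c(
    sprintf("seed=%d", seed), sprintf("sim_seed=%d", config$seed),
    sprintf("levels=%s", paste(levels, collapse = ",")),
    sprintf("methods=%s", paste(methods, collapse = ",")),
    sprintf("n_folds=%d", n_folds), sprintf("n_repeats=%d", n_repeats),
    sprintf("n_individuals=%d", length(dataset$samples)),
    sprintf("n_markers=%d", nrow(dataset$map)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(summary_table = summary_table, correlations = correlations,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else NULL,
                 out_dir = out_dir))
}

#' Reproduce the reference correlation analysis
#'
#' Runs the pooled within-level-standardized correlation tests on the
#' packaged 33-row panel summary table: the three all-level tests of each
#' density measurement against the accuracies of all three traits, and the
#' moderate-density (15-50 k) tests against the polygenic trait (SCS) only.
#'
#' @return a named list of [pooled_correlation()] results:
#'   `sigma_d2_all`, `r2_mean_all`, `r2_var_all`, `sigma_d2_scs_mod`,
#'   `r2_mean_scs_mod`, `r2_var_scs_mod`.
#' @export
reproduce_table1 <- function() {
  tab <- load_table1_fixture()
  mod <- c(15, 20, 30, 50)
  list(
    sigma_d2_all = pooled_correlation(tab, "sigma_d2"),
    r2_mean_all = pooled_correlation(tab, "r2_mean"),
    r2_var_all = pooled_correlation(tab, "r2_var"),
    sigma_d2_scs_mod = pooled_correlation(tab, "sigma_d2", "SCS", mod),
    r2_mean_scs_mod = pooled_correlation(tab, "r2_mean", "SCS", mod),
    r2_var_scs_mod = pooled_correlation(tab, "r2_var", "SCS", mod))
}

#' Rank-gap variance experiment
#'
#' The desk-scale analogue of the gap-variance mechanism: panels built by
#' [scenario_gap_sample()] share the same mean rank gap but differ in its
#' variance, so their physical-gap variance rises with the requested
#' variance while the panel size stays (nearly) constant; each panel is then
#' scored by cross-validated GEBV accuracy on the same data with the same
#' fold seed, making the scenario accuracies directly comparable.
#'
#' @param dataset a `genotype_dataset`.
#' @param phenotypes a phenotype data frame (see [cv_accuracy()]).
#' @param gap_variances variances of the rank-gap draw (default
#'   `c(0, 20, 40, 80)`).
#' @param mean_gap mean rank gap (default 67).
#' @param n_folds,n_repeats cross-validation geometry.
#' @param seed seed shared by the gap draws and (paired) fold splits.
#' @return data frame with one row per scenario: `gap_variance`,
#'   `n_markers`, `d_mean`, `d_var`, `mean_accuracy`.
#' @export
scenario_experiment <- function(dataset, phenotypes,
                                gap_variances = c(0, 20, 40, 80),
                                mean_gap = 67, n_folds = 5, n_repeats = 1,
                                seed = 1) {
  m <- nrow(dataset$map)
  out <- lapply(gap_variances, function(v) {
    sel <- scenario_gap_sample(m, mean_gap, v, seed = seed)
    ds <- subset_markers(dataset, sel)
    dm <- density_measures(ds)
    cv <- cv_accuracy(ds, phenotypes, n_folds = n_folds,
                      n_repeats = n_repeats, seed = seed)
    data.frame(gap_variance = v, n_markers = length(sel),
               d_mean = dm$d_mean, d_var = dm$d_var,
               mean_accuracy = cv$mean_accuracy)
  })
  do.call(rbind, out)
}
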