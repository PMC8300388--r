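#' Assemble a genotype dataset
#'
#' A `genotype_dataset` couples an individuals-by-markers dosage matrix with
#' its marker map. Dosages count copies of allele A (0, 1, 2 or `NA` for a
#' missing call), i.e. the matrix `M` whose centered form enters the genomic
#' relationship matrix.
#'
#' @param dosages integer or numeric matrix, individuals in rows, markers in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param map data frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`. Positions are 1-based base pairs
#'   and must be strictly increasing within each chromosome.
#' @param samples character vector of individual IDs (defaults to dosage row
#'   names, else `ind1..indN`).
#' @return an object of class `genotype_dataset` with elements `dosages`,
#'   `map`, `samples`.
#' @export
genotype_dataset <- function(dosages, map, samples = rownames(dosages)) {
  if (!is.matrix(dosages)) stop("`dosages` must be a matrix")
  if (ncol(dosages) != nrow(map)) {
    stop("structure error: dosage columns (", ncol(dosages),
         ") do not match map rows (", nrow(map), ")")
  }
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  map <- validate_marker_map(map)
  if (is.null(samples)) samples <- paste0("ind", seq_len(nrow(dosages)))
  if (anyDuplicated(samples)) stop("duplicated sample IDs")
  storage.mode(dosages) <- "integer"
  rownames(dosages) <- samples
  colnames(dosages) <- map$marker_id
  structure(list(dosages = dosages, map = map, samples = samples),
            class = "genotype_dataset")
}

validate_marker_map <- function(map) {
  need <- c("marker_id", "chromosome", "position_bp")
  if (!all(need %in% names(map))) {
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(map$allele_a)) map$allele_a <- rep("A", nrow(map))
  if (is.null(map$allele_b)) map$allele_b <- rep("B", nrow(map))
  map$marker_id <- as.character(map$marker_id)
  map$chromosome <- as.integer(map$chromosome)
  map$position_bp <- as.integer(map$position_bp)
  if (anyDuplicated(map$marker_id)) stop("marker IDs must be unique")
  ok <- unlist(lapply(split(map$position_bp, map$chromosome),
                      function(p) all(diff(p) > 0)), use.names = FALSE)
  if (!all(ok)) stop("positions must be strictly increasing within chromosome")
  rownames(map) <- NULL
  map
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", length(x$samples), "individuals x",
      nrow(x$map), "markers on", length(unique(x$map$chromosome)),
      "chromosome(s)\n")
  nmiss <- sum(is.na(x$dosages))
  if (nmiss > 0) cat("  missing calls:", nmiss, "\n")
  invisible(x)
}

## PLINK v1 .bed 2-bit codes (SNP-major):
##   00 -> homozygous A1A1 (dosage 2 of allele A)
##   01 -> missing
##   10 -> heterozygous   (dosage 1)
##   11 -> homozygous A2A2 (dosage 0)
.bed_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)          # index by code+1
.bed_dosage_to_code <- function(d) {
  code <- rep(1L, length(d))                               # missing
  code[!is.na(d) & d == 2L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 0L] <- 3L
  code
}

#' Read a PLINK v1 binary genotype trio
#'
#' Decodes `prefix.bed` (SNP-major, 2 bits per genotype) together with the
#' `.bim` marker map and `.fam` sample file into a [genotype_dataset()].
#' Markers are returned sorted by (chromosome, position).
#'
#' @param prefix path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` must
#'   exist.
#' @return a `genotype_dataset`.
#' @export
read_plink <- function(prefix) {
  files <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- files[!file.exists(files)]
  if (length(miss)) stop("missing PLINK file(s): ", paste(miss, collapse = ", "))

  fam <- utils::read.table(files[3], header = FALSE, stringsAsFactors = FALSE)
  bim <- utils::read.table(files[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "marker_id", "cm",
                                         "position_bp", "allele_a", "allele_b"))
  n <- nrow(fam); m <- nrow(bim)
  samples <- as.character(fam[[2]])

  raw <- readBin(files[1], "raw", n = file.size(files[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("format error: not a PLINK v1 .bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) {
    stop("format error: .bed is not in SNP-major mode")
  }
  bpv <- ceiling(n / 4)                                    # bytes per variant
  if (length(raw) != 3 + bpv * m) {
    stop("structure error: .bed payload size does not match .fam/.bim counts")
  }
  bytes <- as.integer(raw[-(1:3)])
  ## expand each byte into its four 2-bit genotype codes, sample-fastest
  codes <- matrix(0L, nrow = 4 * bpv, ncol = m)
  byte_mat <- matrix(bytes, nrow = bpv, ncol = m)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bpv, by = 4), ] <- (byte_mat %/% 4L^k) %% 4L
  }
  dos <- matrix(.bed_code_to_dosage[codes[seq_len(n), , drop = FALSE] + 1L],
                nrow = n, ncol = m)

  map <- bim[, c("marker_id", "chromosome", "position_bp",
                 "allele_a", "allele_b")]
  ord <- order(map$chromosome, map$position_bp)
  genotype_dataset(dos[, ord, drop = FALSE], map[ord, ], samples)
}

#' Write a genotype dataset as a PLINK v1 binary trio
#'
#' Emits a SNP-major `.bed` plus matching `.bim`/`.fam`. Writing then reading
#' with [read_plink()] is the identity on valid datasets.
#'
#' @param dataset a `genotype_dataset`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths written.
#' @export
write_plink <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (nrow(dataset$map) == 0) stop("refusing to write a zero-marker fileset")
  n <- length(dataset$samples); m <- nrow(dataset$map)

  fam <- data.frame(dataset$samples, dataset$samples, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(dataset$map$chromosome, dataset$map$marker_id, 0L,
                    dataset$map$position_bp, dataset$map$allele_a,
                    dataset$map$allele_b)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  bpv <- ceiling(n / 4)
  codes <- matrix(3L, nrow = 4 * bpv, ncol = m)            # pad bits: 11
  codes[seq_len(n), ] <- matrix(.bed_dosage_to_code(dataset$dosages),
                                nrow = n, ncol = m)
  ## PLINK pads the trailing partial byte with zero bits
  if (4 * bpv > n) codes[(n + 1):(4 * bpv), ] <- 0L
  i1 <- seq(1, 4 * bpv, by = 4)
  bytes <- codes[i1, , drop = FALSE] + 4L * codes[i1 + 1, , drop = FALSE] +
    16L * codes[i1 + 2, , drop = FALSE] + 64L * codes[i1 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a phenotype table
#'
#' Whitespace- or comma-delimited text with a header; first column is the
#' sample ID, remaining numeric columns are traits (EBVs used as phenotypes).
#'
#' @param path file path.
#' @return data frame with column `sample_id` plus one numeric column per
#'   trait.
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(tab)[1] <- "sample_id"
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample IDs in phenotypes")
  tab
}

#' Quality-control filter for markers
#'
#' Removes markers with minor allele frequency below `maf_min`, genotype call
#' rate below `call_rate_min`, or a Hardy-Weinberg equilibrium chi-square
#' (1 df, observed vs expected genotype counts) p-value below `hwe_p_min`.
#' Allele frequencies and HWE counts use non-missing calls only. A filter
#' report (markers removed per criterion) is attached as attribute
#' `"qc_report"`.
#'
#' @param dataset a `genotype_dataset`.
#' @param maf_min,call_rate_min,hwe_p_min thresholds in `[0, 1]`; the default
#'   values (0.005, 0.9, 0.01) are the standard chip-QC settings for dense
#'   cattle data.
#' @return the filtered `genotype_dataset`.
#' @export
qc_filter <- function(dataset, maf_min = 0.005, call_rate_min = 0.9,
                      hwe_p_min = 0.01) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  thr <- c(maf_min, call_rate_min, hwe_p_min)
  if (any(thr < 0 | thr > 1)) stop("thresholds must lie in [0, 1]")
  D <- dataset$dosages
  n <- nrow(D)
  called <- colSums(!is.na(D))
  call_rate <- called / n
  p <- colMeans(D, na.rm = TRUE) / 2                       # freq of allele A
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)

  n2 <- colSums(D == 2L, na.rm = TRUE)
  n1 <- colSums(D == 1L, na.rm = TRUE)
  n0 <- called - n1 - n2
  hwe_p <- hwe_chisq_p(n0, n1, n2)

  fail_maf <- maf < maf_min
  fail_cr <- call_rate < call_rate_min
  fail_hwe <- hwe_p < hwe_p_min
  keep <- which(!(fail_maf | fail_cr | fail_hwe))
  if (length(keep) == 0) stop("empty panel: all markers removed by QC")

  out <- genotype_dataset(D[, keep, drop = FALSE],
                          dataset$map[keep, , drop = FALSE],
                          dataset$samples)
  attr(out, "qc_report") <- list(
    n_input = ncol(D), n_retained = length(keep),
    n_fail_maf = sum(fail_maf), n_fail_call_rate = sum(fail_cr),
    n_fail_hwe = sum(fail_hwe))
  out
}

## HWE chi-square goodness of fit, 1 df, vectorised over markers.
## Genotype counts (n0, n1, n2) = copies of allele A being (0, 1, 2).
hwe_chisq_p <- function(n0, n1, n2) {
  nn <- n0 + n1 + n2
  p <- ifelse(nn > 0, (2 * n2 + n1) / (2 * nn), 0)
  q <- 1 - p
  e0 <- nn * q^2; e1 <- 2 * nn * p * q; e2 <- nn * p^2
  term <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
  chi2 <- term(n0, e0) + term(n1, e1) + term(n2, e2)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Restrict a dataset to the markers of a panel selection
#'
#' @param dataset a `genotype_dataset`.
#' @param selection a [panel_selection] or a sorted vector of unique marker
#'   column indices.
#' @return a `genotype_dataset` with only the selected markers, map order
#'   preserved.
#' @export
subset_markers <- function(dataset, selection) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  idx <- if (inherits(selection, "panel_selection")) selection$indices
         else as.integer(selection)
  if (length(idx) == 0) stop("empty marker selection")
  if (any(is.na(idx)) || any(idx < 1) || any(idx > nrow(dataset$map))) {
    stop("marker index out of range")
  }
  if (is.unsorted(idx, strictly = TRUE)) stop("indices must be sorted, unique")
  genotype_dataset(dataset$dosages[, idx, drop = FALSE],
                   dataset$map[idx, , drop = FALSE], dataset$samples)
}
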