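#' Simulation configuration
#'
#' Bundles the knobs of the genotype simulator. The defaults sketch a
#' desk-scale dairy-cattle-like genome: a few long autosomes, clustered
#' (heavy-tailed) marker spacing, and linkage disequilibrium that decays
#' exponentially with physical distance.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_markers total number of SNPs across all chromosomes (>= 2).
#' @param chromosome_lengths_bp vector of chromosome lengths in base pairs.
#' @param spacing_model `"uniform"` (equal adjacent gaps) or `"clustered"`
#'   (log-normal gaps, heavy right tail).
#' @param spacing_log_sd log-scale standard deviation of clustered gaps.
#' @param ld_decay_lambda_bp scale of LD decay: adjacent haplotype alleles at
#'   gap `d` have target correlation `exp(-d / lambda)`.
#' @param maf_low,maf_high minor-allele-frequency bounds, `0 < low <= high
#'   <= 0.5`.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 500, n_markers = 20000,
                       chromosome_lengths_bp = rep(1e8, 5),
                       spacing_model = c("clustered", "uniform"),
                       spacing_log_sd = 1,
                       ld_decay_lambda_bp = 5e4,
                       maf_low = 0.05, maf_high = 0.5, seed = 1) {
  spacing_model <- match.arg(spacing_model)
  if (n_markers < 2) stop("n_markers must be >= 2")
  if (ld_decay_lambda_bp <= 0) stop("ld_decay_lambda_bp must be > 0")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("need 0 < maf_low <= maf_high <= 0.5")
  }
  structure(list(n_individuals = n_individuals, n_markers = n_markers,
                 chromosome_lengths_bp = chromosome_lengths_bp,
                 spacing_model = spacing_model,
                 spacing_log_sd = spacing_log_sd,
                 ld_decay_lambda_bp = ld_decay_lambda_bp,
                 maf_low = maf_low, maf_high = maf_high,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a marker map
#'
#' Allocates markers to chromosomes proportionally to length and draws
#' strictly increasing positions per chromosome. Under `"uniform"` spacing all
#' adjacent gaps on a chromosome are equal; under `"clustered"` spacing gaps
#' are log-normal (scaled to the chromosome span, floored at 1 bp), giving
#' the heavy-tailed gap distributions seen on real dense chips.
#'
#' @param config a [sim_config()].
#' @return a marker-map data frame (`marker_id`, `chromosome`, `position_bp`,
#'   `allele_a`, `allele_b`).
#' @export
simulate_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$chromosome_lengths_bp
  m_per <- round(config$n_markers * L / sum(L))
  m_per[1] <- m_per[1] + (config$n_markers - sum(m_per))
  if (any(m_per < 1)) stop("chromosome too short to host requested markers")

  maps <- vector("list", length(L))
  for (c_i in seq_along(L)) {
    m <- m_per[c_i]
    if (L[c_i] < m) stop("chromosome ", c_i, " too short for ", m, " markers")
    if (config$spacing_model == "uniform") {
      gap <- floor(L[c_i] / m)
      pos <- 1L + gap * (seq_len(m) - 1L)
    } else {
      raw <- stats::rlnorm(m, meanlog = 0, sdlog = config$spacing_log_sd)
      gaps <- pmax(1L, round(raw * (L[c_i] - m) / sum(raw)))
      pos <- cumsum(gaps)
      if (pos[m] > L[c_i]) stop("chromosome ", c_i, " too short for ", m,
                                " markers at this spacing")
    }
    maps[[c_i]] <- data.frame(
      marker_id = sprintf("snp%d_%d", c_i, seq_len(m)),
      chromosome = c_i, position_bp = as.integer(pos),
      allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  }
  do.call(rbind, maps)
}

## First-order Markov haplotype chain. Returns a (2 * n_individuals) x m
## 0/1 matrix; the allele at marker j has marginal frequency p[j] and target
## correlation rho[j] = exp(-gap_j / lambda) with marker j - 1. The chain
## restarts at every chromosome boundary. For binary variables with unequal
## frequencies the exact transition probabilities are clipped to [0, 1],
## which can only attenuate the realized correlation.
simulate_haplotypes <- function(map, p, lambda, n_haplotypes) {
  m <- nrow(map)
  H <- matrix(0L, nrow = n_haplotypes, ncol = m)
  new_chrom <- c(TRUE, diff(map$chromosome) != 0)
  gaps <- c(0L, diff(map$position_bp))
  for (j in seq_len(m)) {
    if (new_chrom[j]) {
      H[, j] <- as.integer(stats::runif(n_haplotypes) < p[j])
    } else {
      rho <- exp(-gaps[j] / lambda)
      pa <- p[j - 1]; pb <- p[j]
      s <- sqrt(pb * (1 - pb))
      p1 <- min(1, max(0, pb + rho * s * sqrt((1 - pa) / pa)))
      p0 <- min(1, max(0, pb - rho * s * sqrt(pa / (1 - pa))))
      pj <- p0 + (p1 - p0) * (H[, j - 1] == 1L)
      H[, j] <- as.integer(stats::runif(n_haplotypes) < pj)
    }
  }
  H
}

## Reflected random walk for allele frequencies along a chromosome: the
## frequency at marker j drifts from marker j - 1 with a step SD growing
## with sqrt(gap / lambda), reflected into [low, high]. Real allele
## frequencies are spatially autocorrelated (shared genealogy); without
## this, adjacent markers with very different frequencies force the binary
## chain's transition probabilities out of [0, 1] and long-range LD
## collapses.
maf_walk <- function(map, low, high, lambda) {
  m <- nrow(map)
  new_chrom <- c(TRUE, diff(map$chromosome) != 0)
  gaps <- c(0L, diff(map$position_bp))
  p <- numeric(m)
  span <- high - low
  for (j in seq_len(m)) {
    if (new_chrom[j] || span == 0) {
      p[j] <- stats::runif(1, low, high)
    } else {
      step <- stats::rnorm(1, 0, 0.1 * span * sqrt(min(1, gaps[j] / lambda)))
      v <- p[j - 1] + step
      ## reflect into [low, high]
      repeat {
        if (v < low) v <- 2 * low - v
        else if (v > high) v <- 2 * high - v
        else break
      }
      p[j] <- v
    }
  }
  p
}

#' Simulate genotypes with distance-decaying LD
#'
#' Each marker gets a minor allele frequency from a reflected random walk
#' over `[maf_low, maf_high]` along the chromosome (allele labels are then
#' flipped at random markers so the counted-allele spectrum is two-sided).
#' Two independent haplotypes per individual are drawn from a first-order
#' Markov chain in which adjacent alleles at gap `d` target correlation
#' `exp(-d / lambda)`; dosages are the haplotype sums, so adjacent-pair
#' dosage r2 falls off with physical distance and correlation between
#' distant markers decays multiplicatively along the chain.
#'
#' @param map a marker map, typically from [simulate_marker_map()].
#' @param config a [sim_config()].
#' @return a [genotype_dataset()].
#' @export
simulate_genotypes <- function(map, config) {
  stopifnot(inherits(config, "sim_config"))
  map <- validate_marker_map(map)
  set.seed(config$seed + 1L)
  m <- nrow(map)
  p <- maf_walk(map, config$maf_low, config$maf_high,
                config$ld_decay_lambda_bp)
  n <- config$n_individuals
  H <- simulate_haplotypes(map, p, config$ld_decay_lambda_bp, 2L * n)
  dos <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
  flip <- stats::runif(m) < 0.5
  dos[, flip] <- 2L - dos[, flip]
  genotype_dataset(dos, map, sprintf("ind%04d", seq_len(n)))
}

#' Trait architecture presets
#'
#' Three genetic architectures mirroring contrasting dairy traits: a fat-
#' percentage-like trait with one or few major genes plus a polygenic
#' background (`"FP_like"`), a milk-yield-like trait with several moderate
#' loci plus background (`"MY_like"`), and a somatic-cell-score-like trait
#' that is purely polygenic (`"SCS_like"`). Effect-size tiers are relative
#' standard deviations of normal QTL effect draws.
#'
#' @param name one of `"FP_like"`, `"MY_like"`, `"SCS_like"`.
#' @param h2 narrow-sense heritability of the simulated phenotype, in
#'   `(0, 1]` (`1` means a noise-free phenotype).
#' @param n_major,major_sd,n_moderate,moderate_sd,n_small,small_sd optional
#'   overrides of the preset QTL counts and effect-size SDs.
#' @return a list of class `trait_architecture`.
#' @export
trait_architecture <- function(name = c("FP_like", "MY_like", "SCS_like"),
                               h2 = NULL, n_major = NULL, major_sd = NULL,
                               n_moderate = NULL, moderate_sd = NULL,
                               n_small = NULL, small_sd = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    FP_like  = list(n_major = 2L, major_sd = 10, n_moderate = 0L,
                    moderate_sd = 3, n_small = 300L, small_sd = 1, h2 = 0.5),
    MY_like  = list(n_major = 0L, major_sd = 10, n_moderate = 20L,
                    moderate_sd = 3, n_small = 300L, small_sd = 1, h2 = 0.4),
    SCS_like = list(n_major = 0L, major_sd = 10, n_moderate = 0L,
                    moderate_sd = 3, n_small = 500L, small_sd = 1, h2 = 0.3))
  over <- list(h2 = h2, n_major = n_major, major_sd = major_sd,
               n_moderate = n_moderate, moderate_sd = moderate_sd,
               n_small = n_small, small_sd = small_sd)
  for (nm in names(over)) if (!is.null(over[[nm]])) preset[[nm]] <- over[[nm]]
  if (!(preset$h2 > 0 && preset$h2 <= 1)) stop("h2 must be in (0, 1]")
  structure(c(list(name = name), preset), class = "trait_architecture")
}

#' Simulate an EBV-like phenotype
#'
#' Samples QTL positions without replacement, draws their additive effects
#' from the architecture's tiers, forms genetic values `g = M a`, and adds
#' Gaussian noise scaled so that `Var(g) / Var(y)` equals the target
#' heritability. The phenotype emulates a single high-reliability
#' pseudo-record per individual (overall mean only, no other fixed effects).
#'
#' @param dataset a `genotype_dataset`.
#' @param architecture a [trait_architecture()].
#' @param seed integer seed.
#' @return a list with `phenotypes` (data frame `sample_id`, trait column
#'   named after the architecture), `true_bv` (centered genetic values) and
#'   `qtl` (data frame of marker indices, tiers and effects).
#' @export
simulate_trait <- function(dataset, architecture, seed = 1) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(architecture, "trait_architecture"))
  a <- architecture
  n_qtl <- a$n_major + a$n_moderate + a$n_small
  m <- nrow(dataset$map)
  if (n_qtl > m) stop("more QTL requested than markers available")
  set.seed(seed)
  for (attempt in 1:10) {
    idx <- sort(sample.int(m, n_qtl))
    tier <- sample(rep(c("major", "moderate", "small"),
                       c(a$n_major, a$n_moderate, a$n_small)))
    eff <- stats::rnorm(n_qtl) *
      c(major = a$major_sd, moderate = a$moderate_sd,
        small = a$small_sd)[tier]
    g <- as.numeric(dataset$dosages[, idx, drop = FALSE] %*% eff)
    if (stats::var(g) > 0) break
    if (attempt == 10) stop("zero genetic variance after 10 QTL resamples")
  }
  g <- g - mean(g)
  sigma_e2 <- stats::var(g) * (1 - a$h2) / a$h2
  e <- if (sigma_e2 > 0) stats::rnorm(length(g), 0, sqrt(sigma_e2)) else 0
  y <- g + e
  phen <- data.frame(sample_id = dataset$samples, y, stringsAsFactors = FALSE)
  names(phen)[2] <- a$name
  list(phenotypes = phen, true_bv = g,
       qtl = data.frame(index = idx, tier = tier, effect = eff))
}
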