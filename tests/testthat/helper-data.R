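# Small in-code fixtures shared across tests.

make_map <- function(positions, chromosome = 1L, prefix = "m") {
  data.frame(marker_id = paste0(prefix, seq_along(positions)),
             chromosome = chromosome, position_bp = as.integer(positions),
             allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
}

make_dataset <- function(dosages, positions = 1000L * seq_len(ncol(dosages)),
                         chromosome = 1L) {
  genotype_dataset(dosages, make_map(positions, chromosome))
}

# Random well-conditioned dataset: n individuals, m markers, no LD model.
random_dataset <- function(n, m, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  dos <- sapply(p, function(pk) rbinom(n, 2, pk))
  make_dataset(matrix(as.integer(dos), nrow = n))
}

# Simulated dataset with LD for integration-style tests.
sim_dataset <- function(n = 300, m = 2000, lambda = 5e4, seed = 1,
                        spacing = "clustered", chrom_bp = rep(5e7, 2)) {
  cfg <- sim_config(n_individuals = n, n_markers = m,
                    chromosome_lengths_bp = chrom_bp,
                    spacing_model = spacing, ld_decay_lambda_bp = lambda,
                    seed = seed)
  simulate_genotypes(simulate_marker_map(cfg), cfg)
}
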