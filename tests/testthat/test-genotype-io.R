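test_that("PLINK write/read round trip is the identity, including missing calls", {
  map <- data.frame(marker_id = c("s1", "s2", "s3", "s4", "s5"),
                    chromosome = c(1L, 1L, 1L, 2L, 2L),
                    position_bp = c(100L, 250L, 900L, 50L, 60L),
                    allele_a = "A", allele_b = "B")
  set.seed(11)
  dos <- matrix(sample(c(0:2, NA), 7 * 5, replace = TRUE), nrow = 7)
  ds <- genotype_dataset(dos, map)
  prefix <- tempfile()
  write_plink(ds, prefix)
  ds2 <- read_plink(prefix)
  expect_identical(ds2$dosages, ds$dosages)
  expect_identical(ds2$map, ds$map)
  expect_identical(ds2$samples, ds$samples)

  # writing the re-read dataset reproduces the .bed byte for byte
  prefix2 <- tempfile()
  write_plink(ds2, prefix2)
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 1000),
                   readBin(paste0(prefix2, ".bed"), "raw", 1000))
})

test_that("a .bed without the PLINK magic bytes raises a format error", {
  prefix <- tempfile()
  ds <- make_dataset(matrix(c(0L, 1L, 2L), ncol = 1))
  write_plink(ds, prefix)
  writeBin(as.raw(c(0x00, 0x00, 0x01, 0xff)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
})

test_that("hand-encoded 2-bit genotypes decode to the PLINK v1 code table", {
  # one SNP, four samples: hom-A (00), het (10), hom-B (11), missing (01)
  # packed sample-fastest into one byte: 00|10|11|01 from high to low bits
  # for samples 4..1 -> 0b01111000? bits: s1 in lowest crumb.
  # s1=00, s2=10, s3=11, s4=01 -> byte = 0 + 2*4 + 3*16 + 1*64 = 120
  prefix <- tempfile()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 120)), paste0(prefix, ".bed"))
  writeLines("1\tsnp1\t0\t500\tA\tB", paste0(prefix, ".bim"))
  writeLines(paste(paste0("f", 1:4), paste0("i", 1:4), 0, 0, 0, -9),
             paste0(prefix, ".fam"))
  ds <- read_plink(prefix)
  expect_identical(as.vector(ds$dosages), c(2L, 1L, 0L, NA))
})

test_that("a single heterozygote encodes to the expected payload byte", {
  ds <- make_dataset(matrix(1L, 1, 1))
  prefix <- tempfile()
  write_plink(ds, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 10)
  expect_identical(raw, as.raw(c(0x6c, 0x1b, 0x01, 0x02)))
})

test_that("writing a zero-marker dataset is refused", {
  map0 <- data.frame(marker_id = character(0), chromosome = integer(0),
                     position_bp = integer(0))
  ds0 <- genotype_dataset(matrix(integer(0), nrow = 2, ncol = 0), map0,
                          samples = c("a", "b"))
  expect_error(write_plink(ds0, tempfile()), "zero-marker")
})

test_that("QC removes markers by MAF, call rate and HWE as specified", {
  # m1: perfect HWE proportions 25/50/25; m2: monomorphic (MAF 0)
  # m3: 50/0/50 -> chi-square = n = 100; m4: ordinary polymorphic, 30% missing
  n <- 100
  m1 <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  m2 <- rep(0L, n)
  m3 <- c(rep(0L, 50), rep(2L, 50))
  set.seed(3)
  m4 <- c(sample(c(0L, 1L, 2L), 70, replace = TRUE,
                 prob = c(0.25, 0.5, 0.25)), rep(NA, 30))
  ds <- make_dataset(cbind(m1, m2, m3, m4))

  # HWE chi-square of m3 is exactly n = 100 given expected counts 25/50/25
  chi3 <- (50 - 25)^2 / 25 + (0 - 50)^2 / 50 + (50 - 25)^2 / 25
  expect_equal(chi3, 100)

  out <- qc_filter(ds, maf_min = 0.005, call_rate_min = 0.9, hwe_p_min = 0.01)
  expect_identical(out$map$marker_id, "m1")
  rep_ <- attr(out, "qc_report")
  expect_equal(rep_$n_fail_maf, 1)        # m2
  expect_equal(rep_$n_fail_call_rate, 1)  # m4
  expect_equal(rep_$n_fail_hwe, 1)        # m3
})

test_that("perfect-HWE marker survives any hwe_p_min up to 1", {
  m1 <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  ds <- make_dataset(matrix(m1, ncol = 1))
  out <- qc_filter(ds, maf_min = 0, call_rate_min = 0, hwe_p_min = 1)
  expect_equal(ncol(out$dosages), 1)
})

test_that("QC is idempotent and (0,0,0) thresholds are the identity", {
  ds <- random_dataset(60, 30, seed = 5)
  expect_identical(qc_filter(ds, 0, 0, 0)$dosages, ds$dosages)
  once <- qc_filter(ds)
  twice <- qc_filter(once)
  expect_identical(once$dosages, twice$dosages)
  expect_identical(once$map, twice$map)
})

test_that("QC errors when every marker is removed", {
  ds <- make_dataset(matrix(0L, 10, 3))
  expect_error(qc_filter(ds), "empty panel")
})

test_that("subset_markers restricts columns and preserves map order", {
  ds <- random_dataset(20, 10, seed = 7)
  expect_identical(subset_markers(ds, 1:10)$dosages, ds$dosages)
  odd <- seq(1, 10, by = 2)
  sub <- subset_markers(ds, odd)
  expect_equal(ncol(sub$dosages), 5)
  expect_identical(sub$map$marker_id, ds$map$marker_id[odd])
  expect_error(subset_markers(ds, integer(0)), "empty")
  expect_error(subset_markers(ds, c(1L, 11L)), "out of range")
})
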