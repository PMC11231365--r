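test_that("zero-rate genome: haplotypes equal the reference", {
  t0 <- simulate_diploid_genome(1, 2e4, snp_rate = 0, sv_rate = 0,
                                seed = 3)
  expect_identical(haplotype_sequence(t0, "chr1", "HP1"),
                   t0$reference[["chr1"]])
  expect_identical(haplotype_sequence(t0, "chr1", "HP2"),
                   t0$reference[["chr1"]])
  expect_equal(nrow(t0$snps), 0)
})

test_that("hetSNP count is binomial at the requested rate", {
  truth <- simulate_diploid_genome(1, 1e6, snp_rate = 1e-3, seed = 7)
  mu <- 1e6 * 1e-3
  sigma <- sqrt(1e6 * 1e-3 * (1 - 1e-3))
  expect_lt(abs(nrow(truth$snps) - mu), 4 * sigma)
  expect_true(all(diff(truth$snps$pos) > 0))
  expect_true(all(truth$snps$hp1 != truth$snps$hp2))
  expect_true(all(truth$snps$hp1 == truth$snps$ref |
                    truth$snps$hp1 == truth$snps$alt))
})

test_that("homozygous inversion reverse-complements both haplotypes", {
  spec <- list(list("chr1", 10000, 20000, "HOM"))
  truth <- simulate_diploid_genome(1, 5e4, snp_rate = 0,
                                   inversion_spec = spec, seed = 9)
  seg <- substring(truth$reference[["chr1"]], 10001, 20000)
  for (hap in c("HP1", "HP2")) {
    hs <- haplotype_sequence(truth, "chr1", hap)
    expect_identical(substring(hs, 10001, 20000), revcomp(seg))
  }
  # heterozygous inversion touches only the carrier
  spec2 <- list(list("chr1", 10000, 20000, "HET-HP2"))
  t2 <- simulate_diploid_genome(1, 5e4, snp_rate = 0,
                                inversion_spec = spec2, seed = 9)
  expect_identical(haplotype_sequence(t2, "chr1", "HP1"),
                   t2$reference[["chr1"]])
  expect_identical(substring(haplotype_sequence(t2, "chr1", "HP2"),
                             10001, 20000),
                   revcomp(substring(t2$reference[["chr1"]], 10001, 20000)))
})

test_that("overlapping inversion requests are rejected", {
  spec <- list(list("chr1", 10000, 20000, "HOM"),
               list("chr1", 15000, 25000, "HET"))
  expect_error(simulate_diploid_genome(1, 5e4, inversion_spec = spec),
               "overlapping")
})

test_that("strand assignment follows the inheritance pattern", {
  truth <- simulate_diploid_genome(1, 5e4, snp_rate = 0, seed = 5)
  cfg0 <- cell_sim_config(n_reads = 300, sce_rate = 0,
                          background_rate = 0)
  cc <- simulate_cell_library(truth, cfg0, c(chr1 = "CC"), seed = 21)
  expect_true(all(cc$reads$strand == "C"))
  ww <- simulate_cell_library(truth, cfg0, c(chr1 = "WW"), seed = 21)
  expect_true(all(ww$reads$strand == "W"))
  expect_error(simulate_cell_library(truth, cfg0, c(chrX = "CC")),
               "pattern missing")
})

test_that("background flips the configured fraction of reads", {
  truth <- simulate_diploid_genome(1, 2e5, snp_rate = 0, seed = 5)
  cfg <- cell_sim_config(n_reads = 4000, sce_rate = 0,
                         background_rate = 0.05)
  cell <- simulate_cell_library(truth, cfg, c(chr1 = "WW"), seed = 22)
  frac <- mean(cell$reads$strand == "C")
  sigma <- sqrt(0.05 * 0.95 / nrow(cell$reads))
  expect_lt(abs(frac - 0.05), 4 * sigma)
})

test_that("WC chromosomes separate haplotypes by strand", {
  truth <- simulate_diploid_genome(1, 5e4, snp_rate = 0, seed = 5)
  cfg0 <- cell_sim_config(n_reads = 500, sce_rate = 0)
  wc <- simulate_cell_library(truth, cfg0, c(chr1 = "WC"), seed = 23)
  crick_haps <- unique(wc$reads$hap_true[wc$reads$strand == "C"])
  watson_haps <- unique(wc$reads$hap_true[wc$reads$strand == "W"])
  expect_length(crick_haps, 1)
  expect_length(watson_haps, 1)
  expect_false(crick_haps == watson_haps)
  expect_identical(crick_haps, unname(wc$wc_orientation[["chr1"]]))
})

test_that("reads within carried inversions flip strand", {
  spec <- list(list("chr1", 40000, 120000, "HET-HP1"))
  truth <- simulate_diploid_genome(1, 2e5, snp_rate = 0,
                                   inversion_spec = spec, seed = 6)
  cfg <- cell_sim_config(n_reads = 2000, sce_rate = 0)
  cell <- simulate_cell_library(truth, cfg, c(chr1 = "CC"), seed = 24)
  mid <- (cell$reads$start + cell$reads$end) %/% 2
  inside <- mid >= 40000 & mid < 120000
  expect_true(all(cell$reads$strand[inside &
                                      cell$reads$hap_true == "HP1"] == "W"))
  expect_true(all(cell$reads$strand[inside &
                                      cell$reads$hap_true == "HP2"] == "C"))
  expect_true(all(cell$reads$strand[!inside] == "C"))
})

test_that("simulation is deterministic under a fixed seed", {
  truth <- simulate_diploid_genome(1, 5e4, snp_rate = 1e-3, seed = 5)
  cfg <- cell_sim_config(n_reads = 100, barcode_error_edits = 1)
  a <- simulate_cell_library(truth, cfg, c(chr1 = "WC"), seed = 30)
  b <- simulate_cell_library(truth, cfg, c(chr1 = "WC"), seed = 30)
  expect_identical(a$reads, b$reads)
  expect_identical(a$alleles, b$alleles)
  run1 <- simulate_strand_run(truth, 2, cfg, seed = 31)
  run2 <- simulate_strand_run(truth, 2, cfg, seed = 31)
  bt <- barcode_table(names(run1$cells), generate_barcodes(2, seed = 1),
                      generate_barcodes(2, seed = 2))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  emit_multiplexed_fastq(run1, bt, f1, seed = 32)
  emit_multiplexed_fastq(run2, bt, f2, seed = 32)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every emitted read is labeled and counts are conserved", {
  run <- small_run()
  expect_equal(nrow(run$reads),
               20 * run$cells[[1]]$config$n_reads)
  expect_true(all(run$reads$hap_true %in% c("HP1", "HP2")))
  expect_true(all(run$reads$strand %in% c("C", "W")))
  per_cell <- table(run$reads$cell_id)
  expect_true(all(per_cell == run$cells[[1]]$config$n_reads))
})

test_that("duplicate barcode pairs across cells are rejected", {
  run <- small_run()
  bc <- generate_barcodes(4, seed = 40)
  bt <- barcode_table(names(run$cells)[1:2], bc[1:2], bc[3:4])
  bt$barcode1[2] <- bt$barcode1[1]
  bt$barcode2[2] <- bt$barcode2[1]
  expect_error(
    emit_multiplexed_fastq(list(truth = run$truth,
                                cells = run$cells[1:2]), bt,
                           tempfile(fileext = ".fastq")),
    "duplicate barcode pair")
})
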