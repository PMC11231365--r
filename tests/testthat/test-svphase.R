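mk_sv_reads <- function(n, chrom = "chr1", start0 = 1000L, cigar,
                        prefix = "r", hap = NULL) {
  df <- data.frame(
    read_id = sprintf("%s%03d", prefix, seq_len(n)), cell_id = "c1",
    chrom = chrom, start = start0 + seq_len(n) * 7L,
    strand = "C", mapq = 60L, cigar = cigar,
    stringsAsFactors = FALSE)
  df$end <- df$start + strandhap:::cigar_ref_width(df$cigar)
  if (!is.null(hap)) df$hap_set <- hap
  df
}

test_that("shared deletion CIGARs merge into one candidate", {
  reads <- mk_sv_reads(10, cigar = "500M120D2000M")
  cand <- extract_candidate_svs(reads)
  expect_equal(nrow(cand), 1)
  expect_identical(cand$type, "DEL")
  expect_equal(cand$length, 120)
  expect_equal(cand$n_support, 10)
  expect_lt(abs(cand$pos - (1000 + 5.5 * 7 + 500)), 50)
})

test_that("sub-50-bp events are not SV candidates", {
  reads <- mk_sv_reads(10, cigar = "500M49I2000M")
  expect_equal(nrow(extract_candidate_svs(reads)), 0)
  reads50 <- mk_sv_reads(10, cigar = "500M50I2000M")
  expect_equal(nrow(extract_candidate_svs(reads50)), 1)
})

test_that("candidate recall is high on simulated pseudobulk", {
  truth <- cached("sv_truth", simulate_diploid_genome(
    2, 1e6, snp_rate = 1e-3, sv_rate = 2e-5, seed = 401))
  run <- cached("sv_run", simulate_strand_run(
    truth, 40, cell_sim_config(n_reads = 900, sce_rate = 0), seed = 402))
  cand <- extract_candidate_svs(run$reads, min_reads = 2)
  hit <- vapply(seq_len(nrow(truth$svs)), function(i) {
    any(cand$chrom == truth$svs$chrom[i] &
          cand$type == truth$svs$type[i] &
          abs(cand$pos - truth$svs$pos[i]) <= 500 &
          pmin(cand$length, truth$svs$length[i]) /
            pmax(cand$length, truth$svs$length[i]) >= 0.75)
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("blacklist rules remove exactly the offending records", {
  svs <- data.frame(
    sv_id = sprintf("s%d", 1:6), chrom = "chr1",
    pos = c(1000L, 1900L, 50000L, 100000L, 200000L, 300000L),
    type = c("DEL", "INS", "DEL", "DEL", "INS", "DEL"),
    length = c(100L, 80L, 10001L, 200L, 60L, 70L),
    stringsAsFactors = FALSE)
  cov <- list(data.frame(chrom = "chr1",
                         start = c(0L, 99000L), end = c(98000L, 400000L),
                         coverage = c(30, 30)))
  cov[[1]]$coverage[2] <- 30
  low <- data.frame(chrom = "chr1", start = 199000L, end = 201000L,
                    coverage = 5)
  cov2 <- list(rbind(cov[[1]], low))
  difficult <- data.frame(chrom = "chr1", start = 299000L, end = 301000L)
  tandem <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  res <- filter_blacklist(svs, coverage_tracks = cov2,
                          difficult_bed = difficult, tandem_bed = tandem)
  # s1+s2: 900 bp apart -> both out; s3: > 10 kb; s5: 5x coverage;
  # s6: difficult region; s4 survives (tandem region is only 100 bp)
  expect_identical(sort(res$removed$sv_id), c("s1", "s2", "s3", "s5", "s6"))
  expect_identical(res$svs$sv_id, "s4")
  expect_identical(
    res$removed$reason[match(c("s1", "s3", "s5", "s6"),
                             res$removed$sv_id)],
    c("adjacent", "length", "coverage", "difficult"))
  # idempotent
  res2 <- filter_blacklist(res$svs, coverage_tracks = cov2,
                           difficult_bed = difficult, tandem_bed = tandem)
  expect_identical(res2$svs, res$svs)
  # missing inputs skip rules with warnings (one per skipped rule)
  w <- capture_warnings(filter_blacklist(svs))
  expect_true(any(grepl("coverage", w)))
  expect_true(any(grepl("difficult", w)))
  expect_true(any(grepl("tandem", w)))
})

test_that("SV genotyping follows the support/oppose rules", {
  sv <- data.frame(sv_id = "sv1", chrom = "chr1", pos = 1700L,
                   type = "DEL", length = 120L,
                   stringsAsFactors = FALSE)
  carrier <- function(n, hap, prefix) {
    mk_sv_reads(n, cigar = "600M120D2000M", hap = hap, prefix = prefix)
  }
  refread <- function(n, hap, prefix) {
    mk_sv_reads(n, cigar = "2720M", hap = hap, prefix = prefix)
  }
  hom <- genotype_svs(sv, rbind(carrier(4, "HP1", "a"),
                                carrier(5, "HP2", "b")))
  expect_identical(hom$genotype, "HOM")
  het <- genotype_svs(sv, rbind(carrier(5, "HP1", "a"),
                                refread(6, "HP2", "b")))
  expect_identical(het$genotype, "HET-HP1")
  expect_gte(het$oppose_hp2, 2)
  low <- genotype_svs(sv, rbind(carrier(1, "HP1", "a"),
                                refread(6, "HP2", "b")))
  expect_identical(low$genotype, "unresolved")
  # label symmetry: swapping read sets mirrors the heterozygous call
  swapped <- rbind(carrier(5, "HP2", "a"), refread(6, "HP1", "b"))
  expect_identical(genotype_svs(sv, swapped)$genotype, "HET-HP2")
})

test_that("phases switch inside HOM inversions and drop inside HET", {
  svs <- data.frame(
    sv_id = c("s1", "s2", "s3", "s4"), chrom = "chr1",
    pos = c(150L, 160L, 450L, 900L), type = "DEL", length = 60L,
    genotype = c("HET-HP1", "HOM", "HET-HP2", "HET-HP1"),
    stringsAsFactors = FALSE)
  inversions <- data.frame(chrom = "chr1", start = c(100L, 400L),
                           end = c(200L, 500L),
                           genotype = c("HOM", "HET"),
                           stringsAsFactors = FALSE)
  out <- switch_phase_in_inversions(svs, inversions)
  expect_identical(out$genotype[out$sv_id == "s1"], "HET-HP2")
  expect_identical(out$genotype[out$sv_id == "s2"], "HOM")
  expect_false("s3" %in% out$sv_id)
  expect_identical(out$genotype[out$sv_id == "s4"], "HET-HP1")
})

test_that("nearest-hetSNP distances equal the brute-force minimum", {
  set.seed(403)
  svs <- data.frame(sv_id = sprintf("s%d", 1:5), chrom = "chr1",
                    pos = as.integer(sample(1e5, 5)),
                    type = sample(c("DEL", "INS"), 5, replace = TRUE),
                    length = as.integer(sample(50:500, 5)),
                    stringsAsFactors = FALSE)
  snps <- data.frame(chrom = "chr1", pos = as.integer(sample(1e5, 7)),
                     stringsAsFactors = FALSE)
  out <- nearest_hetsnp_distances(svs, snps)
  for (i in 1:5) {
    bks <- c(svs$pos[i],
             svs$pos[i] + if (svs$type[i] == "DEL") svs$length[i] else 0L)
    expect_equal(out$nearest_hetsnp_distance[i],
                 min(abs(outer(snps$pos, bks, "-"))))
  }
  far <- nearest_hetsnp_distances(
    data.frame(sv_id = "x", chrom = "chr2", pos = 20000L, type = "INS",
               length = 60L, stringsAsFactors = FALSE),
    data.frame(chrom = "chr2", pos = 34000L, stringsAsFactors = FALSE))
  expect_equal(far$nearest_hetsnp_distance, 14000)
  expect_identical(as.character(far$distance_bucket), ">10kb")
  zero <- nearest_hetsnp_distances(
    data.frame(sv_id = "z", chrom = "chr2", pos = 500L, type = "DEL",
               length = 60L, stringsAsFactors = FALSE),
    data.frame(chrom = "chr2", pos = 500L, stringsAsFactors = FALSE))
  expect_equal(zero$nearest_hetsnp_distance, 0)
})
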