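test_that("anchor calling keeps balanced sites and drops skewed ones", {
  mk_obs <- function(pos, alleles) {
    data.frame(read_id = sprintf("p%d.%d", pos, seq_along(alleles)),
               chrom = "chr1", pos = pos, allele = alleles,
               stringsAsFactors = FALSE)
  }
  obs <- rbind(mk_obs(100L, rep(c("A", "G"), each = 20)),
               mk_obs(200L, c(rep("A", 39), "G")),
               mk_obs(300L, rep(c("C", "T"), c(12, 28))))
  ref <- c(chr1 = strrep("A", 400))
  anchors <- call_anchor_hetsnps(obs, reference = NULL)
  expect_true(100L %in% anchors$pos)   # 20/20 split
  expect_false(200L %in% anchors$pos)  # 39/1 is homozygous + error
  expect_true(300L %in% anchors$pos)   # 0.3 minor fraction
  # reference orientation: ref allele must be one of the two
  anchors_ref <- call_anchor_hetsnps(obs, reference = ref)
  expect_true(100L %in% anchors_ref$pos)
  expect_false(300L %in% anchors_ref$pos) # neither C nor T matches ref A
})

test_that("orientation scores match hand-computed counts", {
  # 5 anchors, enumerated alleles
  ai <- list(crick = c("A", "C", "G", "T", "A"),
             watson = c("T", "G", "C", "A", "T"))
  # parallel partner: same strands carry the same haplotype
  aj <- list(crick = c("A", "C", "G", NA, "A"),
             watson = c("T", "G", "C", "A", NA))
  sc <- orientation_score(ai, aj)
  expect_equal(sc$agree_parallel, 4 + 4)
  expect_equal(sc$agree_antiparallel, 0)
  expect_equal(sc$log2fc, log2(9 / 1))
  # antiparallel partner: strands swapped
  ak <- list(crick = aj$watson, watson = aj$crick)
  sc2 <- orientation_score(ai, ak)
  expect_equal(sc2$agree_parallel, 0)
  expect_equal(sc2$agree_antiparallel, 8)
  expect_lt(sc2$log2fc, 0)
  # no shared anchors -> undefined
  an <- list(crick = rep(NA_character_, 5), watson = rep(NA_character_, 5))
  expect_true(is.na(orientation_score(ai, an)$log2fc))
})

test_that("orientation clustering recovers the simulated bipartition", {
  run <- small_run()
  truth <- small_truth()
  states <- call_strand_state(chrom_counts(run$reads), min_reads = 50)
  anchors <- call_anchor_hetsnps(run$alleles, reference = truth$reference)
  r1 <- reconstruct_round1(run$reads, run$alleles, states, anchors,
                           "chr1", truth$chrom_lengths[["chr1"]],
                           truth$reference)
  cl <- r1$clusters
  expect_gt(length(cl$cluster1) + length(cl$cluster2), 1)
  # truth: cluster <=> which haplotype each cell sequences on Crick
  ori <- run$wc_orientation[, "chr1"]
  o1 <- unique(ori[cl$cluster1])
  o2 <- unique(ori[cl$cluster2])
  expect_length(o1, 1)
  expect_length(o2, 1)
  expect_false(o1 == o2)
})

test_that("a cell with random alleles is excluded as inconsistent", {
  set.seed(42)
  n_anchor <- 60
  hap1 <- sample(c("A", "C"), n_anchor, replace = TRUE)
  hap2 <- ifelse(hap1 == "A", "C", "A")
  mk_cell <- function(flip = FALSE) {
    if (flip) list(crick = hap2, watson = hap1)
    else list(crick = hap1, watson = hap2)
  }
  cells <- list(c1 = mk_cell(), c2 = mk_cell(), c3 = mk_cell(TRUE),
                noise = list(crick = sample(c("A", "C"), n_anchor, TRUE),
                             watson = sample(c("A", "C"), n_anchor, TRUE)))
  n <- length(cells)
  m <- matrix(NA_real_, n, n, dimnames = list(names(cells), names(cells)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- orientation_score(cells[[i]], cells[[j]])$log2fc
  }
  cl <- cluster_orientations(m)
  expect_setequal(cl$cluster1, c("c1", "c2"))
  expect_setequal(cl$cluster2, "c3")
  expect_true("noise" %in% cl$excluded)
})

test_that("haplotype read sets merge Crick and Watson across clusters", {
  reads <- data.frame(
    read_id = sprintf("r%d", 1:8),
    cell_id = rep(c("a", "b"), each = 4), chrom = "chr1",
    start = 0L, end = 100L,
    strand = rep(c("C", "C", "W", "W"), 2),
    stringsAsFactors = FALSE)
  rs <- build_haplotype_readsets(reads, "a", "b")
  expect_setequal(rs$read_id[rs$hap_set == "HP1"],
                  c("r1", "r2", "r7", "r8"))
  expect_setequal(rs$read_id[rs$hap_set == "HP2"],
                  c("r3", "r4", "r5", "r6"))
  expect_equal(nrow(rs), nrow(reads)) # partition conserves reads
  # degenerate: single cluster
  rs1 <- build_haplotype_readsets(reads, "a", character(0))
  expect_true(all(rs1$hap_set[rs1$strand == "C"] == "HP1"))
  expect_true(all(rs1$hap_set[rs1$strand == "W"] == "HP2"))
})

test_that("consensus calls need >= 2 reads and 80% agreement per hap", {
  ref <- c(chr1 = strrep("A", 100))
  mk <- function(h1, h2, pos = 10L) {
    n1 <- length(h1); n2 <- length(h2)
    readsets <- data.frame(
      read_id = sprintf("r%d", seq_len(n1 + n2)),
      hap_set = rep(c("HP1", "HP2"), c(n1, n2)),
      stringsAsFactors = FALSE)
    alleles <- data.frame(read_id = readsets$read_id, chrom = "chr1",
                          pos = pos, allele = c(h1, h2),
                          stringsAsFactors = FALSE)
    call_consensus_snps(readsets, alleles, ref)
  }
  v <- mk(rep("A", 5), rep("G", 4))
  expect_equal(nrow(v), 1)
  expect_identical(c(v$hp1, v$hp2, v$ref, v$alt), c("A", "G", "A", "G"))
  expect_equal(nrow(mk("A", rep("G", 4))), 0)        # single HP1 read
  expect_equal(nrow(mk(c(rep("A", 3), rep("G", 3)),
                       rep("G", 4))), 0)             # 50% < 80% agreement
  expect_equal(nrow(mk(rep("A", 4), rep("A", 4))), 0) # no difference
  hom <- mk(rep("G", 4), rep("G", 4))
  expect_equal(nrow(hom), 1)                          # hom-alt call
  expect_identical(hom$alt, "G")
})

test_that("round 2 extends round 1 on a noise-free simulation", {
  run <- small_run()
  truth <- small_truth()
  ph <- phase_strand_run(run$reads, run$alleles, truth$chrom_lengths,
                         truth$reference)
  expect_gt(nrow(ph$round1), 0)
  k1 <- paste(ph$round1$chrom, ph$round1$pos)
  k2 <- paste(ph$round2$chrom, ph$round2$pos)
  expect_true(all(k1 %in% k2))
  ev1 <- evaluate_phasing(ph$round1, truth$snps)
  ev2 <- evaluate_phasing(ph$round2, truth$snps)
  expect_gte(ev2$recall, ev1$recall)
  # no round-1 variants -> empty round 2, flagged
  expect_warning(r2 <- round2_reconstruct(run$reads, run$alleles,
                                          ph$round1[0, ],
                                          truth$reference),
                 "no round-1 variants")
  expect_equal(nrow(r2$variants), 0)
})

test_that("inversion corrections flip HOM phases and drop HET variants", {
  variants <- data.frame(
    chrom = c("chr1", "chr1", "chr1"),
    pos = c(150L, 450L, 900L),
    ref = "A", alt = "G",
    hp1 = c("A", "A", "A"), hp2 = c("G", "G", "G"),
    stringsAsFactors = FALSE)
  inversions <- data.frame(chrom = "chr1",
                           start = c(100L, 400L), end = c(200L, 500L),
                           genotype = c("HOM", "HET"),
                           stringsAsFactors = FALSE)
  out <- apply_inversion_corrections(variants, inversions)
  expect_equal(nrow(out), 2)                    # HET variant excluded
  expect_identical(out$hp1[out$pos == 150L], "G") # HOM swapped
  expect_identical(out$hp2[out$pos == 150L], "A")
  expect_identical(out$hp1[out$pos == 900L], "A") # outside untouched
})

test_that("known hetSNPs phase only with consistent multi-read linkage", {
  phased <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                       hp1 = "A", hp2 = "G", stringsAsFactors = FALSE)
  known <- data.frame(chrom = "chr1", pos = c(200L, 300L, 400L),
                      ref = c("C", "C", "C"), alt = c("T", "T", "T"),
                      stringsAsFactors = FALSE)
  reads <- data.frame(
    read_id = sprintf("r%d", 1:7), cell_id = "c1", chrom = "chr1",
    start = 0L, end = 500L, strand = "C", stringsAsFactors = FALSE)
  alleles <- rbind(
    # r1-r3: HP1-tagged (A at the phased site), T at 200 -> concordant
    data.frame(read_id = c("r1", "r2", "r3"), chrom = "chr1", pos = 100L,
               allele = "A"),
    data.frame(read_id = c("r1", "r2", "r3"), chrom = "chr1", pos = 200L,
               allele = "T"),
    # r4: single read linking site 300
    data.frame(read_id = "r4", chrom = "chr1", pos = 100L, allele = "A"),
    data.frame(read_id = "r4", chrom = "chr1", pos = 300L, allele = "T"),
    # r5-r6 vs r7 + one more: conflicting 2-vs-2 votes at site 400
    data.frame(read_id = c("r5", "r6"), chrom = "chr1", pos = 100L,
               allele = "A"),
    data.frame(read_id = c("r5", "r6"), chrom = "chr1", pos = 400L,
               allele = c("T", "C")),
    data.frame(read_id = "r7", chrom = "chr1", pos = 100L, allele = "G"),
    data.frame(read_id = "r7", chrom = "chr1", pos = 400L, allele = "T"))
  out <- link_known_snps(phased, known, reads, alleles)
  expect_true(200L %in% out$pos)
  lk <- out[out$pos == 200L, ]
  expect_identical(lk$hp1, "T")
  expect_identical(lk$hp2, "C")
  expect_false(300L %in% out$pos) # one read is below the support rule
  expect_false(400L %in% out$pos) # conflicting votes
})

test_that("phasing metrics handle identity, flips and single errors", {
  truth <- data.frame(chrom = rep(c("chr1", "chr2"), each = 50),
                      pos = rep(seq(100, by = 98, length.out = 50), 2),
                      ref = "A", alt = "G",
                      hp1 = rep(c("A", "G"), 50),
                      hp2 = rep(c("G", "A"), 50),
                      stringsAsFactors = FALSE)
  expect_equal(evaluate_phasing(truth, truth)$recall, 1)
  expect_equal(evaluate_phasing(truth, truth)$hamming_error_rate, 0)
  # flipping every phase on one chromosome costs nothing
  flipped <- truth
  sel <- flipped$chrom == "chr1"
  tmp <- flipped$hp1[sel]
  flipped$hp1[sel] <- flipped$hp2[sel]
  flipped$hp2[sel] <- tmp
  ev <- evaluate_phasing(flipped, truth)
  expect_equal(ev$hamming_error_rate, 0)
  expect_equal(ev$genotype_precision, 1)
  # exactly one mis-phased variant out of 100 -> 1%
  one <- truth
  one$hp1[1] <- truth$hp2[1]
  one$hp2[1] <- truth$hp1[1]
  expect_equal(evaluate_phasing(one, truth)$hamming_error_rate, 0.01)
})

test_that("metrics are invariant under a global haplotype relabeling", {
  run <- small_run()
  truth <- small_truth()
  ph <- phase_strand_run(run$reads, run$alleles, truth$chrom_lengths,
                         truth$reference)
  ev <- evaluate_phasing(ph$variants, truth$snps)
  swapped <- transform(ph$variants, hp1 = hp2, hp2 = hp1)
  ev2 <- evaluate_phasing(swapped, truth$snps)
  expect_equal(ev$hamming_error_rate, ev2$hamming_error_rate)
  expect_equal(ev$precision, ev2$precision)
  expect_equal(ev$recall, ev2$recall)
})
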