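asm_truth <- function() {
  cached("asm_truth",
         simulate_diploid_genome(2, 2e6, snp_rate = 0, seed = 501))
}

asm_run <- function() {
  cached("asm_run", simulate_strand_run(
    asm_truth(), 40, cell_sim_config(n_reads = 800, sce_rate = 0),
    seed = 502))
}

asm_contigs <- function() {
  cached("asm_contigs", simulate_contigs(asm_truth(), target_len = 2e5,
                                         seed = 503))
}

test_that("strand matrix values follow (C - W) / (C + W)", {
  reads <- data.frame(
    read_id = sprintf("r%d", 1:40), cell_id = rep(c("a", "b"), 20),
    chrom = "chr1", start = as.integer(seq(0, 39) * 4000),
    strand = c(rep("C", 20), rep("C", 10), rep("W", 10)),
    stringsAsFactors = FALSE)
  reads$end <- reads$start + 1000L
  reads$strand[reads$cell_id == "a"] <- "C"
  reads$strand[reads$cell_id == "b"] <- rep(c("C", "W"), 10)
  contigs <- data.frame(contig_id = "ctg1", chrom = "chr1",
                        start = 0L, end = 200000L, orientation = "+",
                        stringsAsFactors = FALSE)
  mat <- contig_strand_matrix(reads, contigs)
  expect_equal(unname(mat$values["ctg1", "a"]), 1)   # 20 C, 0 W
  expect_equal(unname(mat$values["ctg1", "b"]), 0)   # 10 C, 10 W
  # reverse orientation flips the sign
  contigs$orientation <- "-"
  mat2 <- contig_strand_matrix(reads, contigs)
  expect_equal(unname(mat2$values["ctg1", "a"]), -1)
  # short contigs are filtered
  contigs$end <- 99999L
  expect_error(contig_strand_matrix(reads, contigs), "100000")
})

test_that("clusters recover chromosome identity exactly", {
  res <- cluster_assembly(asm_run()$reads, asm_contigs(), n_clusters = 2)
  contigs <- asm_contigs()
  cl <- res$clusters
  chrom_of <- contigs$chrom[match(names(cl), contigs$contig_id)]
  expect_equal(length(unique(paste(cl, chrom_of))), 2)
  # identical rows land in the same cluster; degenerate k = n
  mat <- res$matrix
  expect_error(cluster_contigs(mat, n_clusters = nrow(mat$values) + 1),
               "exceeds")
  singletons <- cluster_contigs(mat, n_clusters = nrow(mat$values))
  expect_equal(length(unique(singletons)), nrow(mat$values))
})

test_that("orientation sub-clusters match the simulated orientations", {
  res <- cluster_assembly(asm_run()$reads, asm_contigs(), n_clusters = 2)
  contigs <- asm_contigs()
  for (g in names(res$subclusters)) {
    s <- res$subclusters[[g]]
    o1 <- unique(contigs$orientation[match(s$sub1, contigs$contig_id)])
    o2 <- unique(contigs$orientation[match(s$sub2, contigs$contig_id)])
    expect_lte(length(o1), 1)
    expect_lte(length(o2), 1)
    if (length(o1) && length(o2)) expect_false(o1 == o2)
  }
  # uniformly oriented cluster stays in one sub-cluster
  mat <- res$matrix
  ids <- names(res$clusters)[res$clusters == 1]
  same_ori <- ids[contigs$orientation[match(ids, contigs$contig_id)] ==
                    contigs$orientation[match(ids[1], contigs$contig_id)]]
  sub <- split_orientation(mat, same_ori)
  expect_setequal(sub$sub1, same_ori)
  expect_length(sub$sub2, 0)
  # two anti-correlated rows separate
  fake <- mat
  fake$values <- rbind(A = rep(c(1, -1), 10), B = rep(c(-1, 1), 10))
  sp <- split_orientation(fake, c("A", "B"))
  expect_length(sp$sub1, 1)
  expect_length(sp$sub2, 1)
})

test_that("cluster assignment survives a cell strand relabeling", {
  mat <- contig_strand_matrix(asm_run()$reads, asm_contigs())
  flipped_reads <- asm_run()$reads
  sel <- flipped_reads$cell_id == "cell001"
  flipped_reads$strand[sel] <- ifelse(flipped_reads$strand[sel] == "C",
                                      "W", "C")
  mat2 <- contig_strand_matrix(flipped_reads, asm_contigs())
  expect_identical(cluster_contigs(mat, 2), cluster_contigs(mat2, 2))
})

test_that("cluster sequence concatenation and coordinate lift round-trip", {
  seqs <- c(a = strandhap:::random_dna(1, 150000),
            b = strandhap:::random_dna(1, 200000))
  cs <- build_cluster_sequence(seqs, "a", "b", gap = 1000)
  expect_equal(nchar(cs$sequence), 150000 + 1000 + 200000)
  # single forward contig is unchanged
  single <- build_cluster_sequence(seqs["a"], "a", character(0))
  expect_identical(single$sequence, unname(seqs["a"]))
  # round trip: cluster position -> contig position -> base agreement
  set.seed(504)
  pos <- sort(sample(0:(nchar(cs$sequence) - 1), 300))
  lift <- lift_cluster_to_contig(pos, cs$map)
  ok <- !is.na(lift$contig_id)
  expect_gt(sum(ok), 0)
  for (i in which(ok)[1:50]) {
    base_cluster <- substr(cs$sequence, pos[i] + 1, pos[i] + 1)
    raw <- substr(seqs[[lift$contig_id[i]]], lift$pos[i] + 1,
                  lift$pos[i] + 1)
    expected <- if (lift$orientation[i] == "-") revcomp(raw) else raw
    expect_identical(base_cluster, expected)
  }
  # gap positions are unmapped
  gap_pos <- 150000 + 5
  expect_true(is.na(lift_cluster_to_contig(gap_pos, cs$map)$contig_id))
})

test_that("variant lifting restores reference coordinates and alleles", {
  truth <- asm_truth()
  contigs <- asm_contigs()
  seqs <- stats::setNames(
    substring(truth$reference[contigs$chrom], contigs$start + 1,
              contigs$end),
    contigs$contig_id)
  rev_ids <- contigs$contig_id[contigs$orientation == "-"]
  seqs[rev_ids] <- revcomp(seqs[rev_ids])
  ids <- contigs$contig_id[contigs$chrom == "chr1"]
  ori <- contigs$orientation[match(ids, contigs$contig_id)]
  cs <- build_cluster_sequence(seqs, ids[ori == "+"], ids[ori == "-"])
  placements <- data.frame(contig_id = contigs$contig_id,
                           chrom = contigs$chrom,
                           start = contigs$start,
                           strand = contigs$orientation,
                           stringsAsFactors = FALSE)
  set.seed(505)
  pos <- sort(sample(0:(nchar(cs$sequence) - 1), 200))
  vars <- data.frame(pos = pos,
                     ref = substring(cs$sequence, pos + 1, pos + 1),
                     stringsAsFactors = FALSE)
  vars <- vars[vars$ref != "N", , drop = FALSE]
  lifted <- lift_variants(vars, cs$map, placements)
  expect_gte(mean(lifted$mapped), 0.99)
  ok <- which(lifted$mapped)
  genome_base <- substring(truth$reference[["chr1"]],
                           lifted$pos[ok] + 1, lifted$pos[ok] + 1)
  expect_identical(lifted$ref[ok], genome_base)
})
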