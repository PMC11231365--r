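#' High-coverage blacklist regions
#'
#' Bins the genome (10 kb default) by pseudobulk read midpoints and flags
#' bins whose read count exceeds mean + `k` standard deviations; reads in
#' such regions (collapsed repeats, mapping artefacts) are excluded from
#' anchor calling.
#'
#' @param reads pooled alignment data frame.
#' @param chrom_lengths named chromosome lengths.
#' @param bin_width bin width in bp.
#' @param k standard-deviation multiplier.
#' @return data frame of blacklist intervals (chrom, start, end).
#' @export
coverage_blacklist <- function(reads, chrom_lengths, bin_width = 1e4,
                               k = 5) {
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    n_bins <- max(1L, as.integer(ceiling(L / bin_width)))
    rd <- reads[reads$chrom == ch, , drop = FALSE]
    cnt <- tabulate(pmin((rd$start + rd$end) %/% 2L %/%
                           as.integer(bin_width), n_bins - 1L) + 1L,
                    n_bins)
    bad <- which(cnt > mean(cnt) + k * stats::sd(cnt))
    if (!length(bad)) return(NULL)
    data.frame(chrom = ch, start = (bad - 1L) * as.integer(bin_width),
               end = pmin(bad * as.integer(bin_width), as.integer(L)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  out
}

in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || !nrow(intervals)) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!any(sel)) next
    hit[sel] <- IRanges::overlapsAny(
      IRanges::IRanges(pos[sel] + 1L, pos[sel] + 1L),
      IRanges::IRanges(iv$start + 1L, iv$end))
  }
  hit
}

#' Call anchor hetSNPs from a pseudobulk pileup
#'
#' A simple binomial pileup caller over the pooled allele observations
#' (duplicate reads included): a site is emitted as a heterozygous anchor
#' when total depth reaches `min_depth`, the minor allele fraction lies in
#' the `maf` band, and the minor allele count is incompatible with the
#' sequencing error rate (binomial tail below `alpha`). Sites in the
#' high-coverage blacklist are excluded.
#'
#' @param alleles pooled observed alleles (`chrom`, `pos`, `allele`).
#' @param reference optional named character vector of chromosome
#'   sequences, used to orient ref/alt; sites where neither major allele
#'   matches the reference base are skipped.
#' @param min_depth minimum site depth (default 10).
#' @param maf minor-allele-fraction band (default 0.25–0.75).
#' @param error_rate assumed per-base error rate for the binomial test.
#' @param alpha binomial tail threshold.
#' @param blacklist optional blacklist intervals.
#' @return data frame of anchors: chrom, pos, ref, alt, depth, maf,
#'   source = "anchor".
#' @export
call_anchor_hetsnps <- function(alleles, reference = NULL, min_depth = 10,
                                maf = c(0.25, 0.75), error_rate = 0.05,
                                alpha = 0.01, blacklist = NULL) {
  if (!nrow(alleles))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), maf = numeric(0),
                      source = character(0), stringsAsFactors = FALSE))
  key <- paste(alleles$chrom, alleles$pos)
  tab <- table(key, alleles$allele)
  if (ncol(tab) < 2)
    return(call_anchor_hetsnps(alleles[0, , drop = FALSE]))
  depth <- rowSums(tab)
  ord <- apply(tab, 1, function(x) order(-x)[1:2])
  major <- colnames(tab)[ord[1, ]]
  minor <- colnames(tab)[ord[2, ]]
  minor_n <- tab[cbind(seq_len(nrow(tab)), ord[2, ])]
  major_n <- tab[cbind(seq_len(nrow(tab)), ord[1, ])]
  mfrac <- minor_n / depth
  pass <- depth >= min_depth & mfrac >= maf[1] & mfrac <= maf[2] &
    stats::pbinom(minor_n - 1, depth, error_rate,
                  lower.tail = FALSE) < alpha
  ks <- rownames(tab)[pass]
  if (!length(ks))
    return(call_anchor_hetsnps(alleles[0, , drop = FALSE]))
  sp <- strsplit(ks, " ")
  chrom <- vapply(sp, `[`, character(1), 1)
  pos <- as.integer(vapply(sp, `[`, character(1), 2))
  a1 <- major[pass]; a2 <- minor[pass]
  if (!is.null(reference)) {
    refb <- substring(reference[chrom], pos + 1L, pos + 1L)
    ok <- refb == a1 | refb == a2
    alt <- ifelse(refb == a1, a2, a1)
    out <- data.frame(chrom = chrom[ok], pos = pos[ok], ref = refb[ok],
                      alt = alt[ok], depth = as.integer(depth[pass][ok]),
                      maf = mfrac[pass][ok], source = "anchor",
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = chrom, pos = pos, ref = a1, alt = a2,
                      depth = as.integer(depth[pass]), maf = mfrac[pass],
                      source = "anchor", stringsAsFactors = FALSE)
  }
  out <- out[!in_intervals(out$chrom, out$pos, blacklist), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# majority vote; ties and empty -> NA
majority_allele <- function(idx, allele, n) {
  out <- rep(NA_character_, n)
  if (!length(idx)) return(out)
  tab <- table(idx, allele)
  best <- apply(tab, 1, function(x) {
    m <- max(x)
    w <- which(x == m)
    if (length(w) > 1) NA_character_ else colnames(tab)[w]
  })
  out[as.integer(rownames(tab))] <- best
  out
}

# Per-cell Crick/Watson consensus alleles at anchor positions.
wc_strand_alleles <- function(reads, alleles, cell_ids, chrom, anchors) {
  apos <- anchors$pos[anchors$chrom == chrom]
  n <- length(apos)
  al <- alleles[alleles$chrom == chrom, , drop = FALSE]
  al$idx <- match(al$pos, apos)
  al <- al[!is.na(al$idx), , drop = FALSE]
  al$cell <- reads$cell_id[match(al$read_id, reads$read_id)]
  al$strand <- reads$strand[match(al$read_id, reads$read_id)]
  al <- al[!is.na(al$cell) & al$cell %in% cell_ids, , drop = FALSE]
  lapply(stats::setNames(cell_ids, cell_ids), function(cid) {
    sub <- al[al$cell == cid, , drop = FALSE]
    list(crick = majority_allele(sub$idx[sub$strand == "C"],
                                 sub$allele[sub$strand == "C"], n),
         watson = majority_allele(sub$idx[sub$strand == "W"],
                                  sub$allele[sub$strand == "W"], n))
  })
}

#' Orientation score for a pair of WC cells
#'
#' Compares the Crick- and Watson-strand consensus alleles of two WC cells
#' at shared anchors. `agree_parallel` counts Crick-Crick plus
#' Watson-Watson matches, `agree_antiparallel` Crick-Watson plus
#' Watson-Crick matches; the signed score is
#' `log2((agree_parallel + 1) / (agree_antiparallel + 1))`, positive for a
#' CC-WW (parallel) merge and negative for CW-WC (antiparallel).
#'
#' @param ai,aj per-cell strand allele lists (elements `crick`, `watson`)
#'   over the same anchor vector.
#' @return list with `agree_parallel`, `agree_antiparallel`, `log2fc`
#'   (NA when the cells share no informative anchors).
#' @export
orientation_score <- function(ai, aj) {
  m <- function(x, y) sum(!is.na(x) & !is.na(y) & x == y)
  shared <- function(x, y) sum(!is.na(x) & !is.na(y))
  p <- m(ai$crick, aj$crick) + m(ai$watson, aj$watson)
  a <- m(ai$crick, aj$watson) + m(ai$watson, aj$crick)
  n_shared <- shared(ai$crick, aj$crick) + shared(ai$watson, aj$watson) +
    shared(ai$crick, aj$watson) + shared(ai$watson, aj$crick)
  list(agree_parallel = p, agree_antiparallel = a,
       log2fc = if (n_shared == 0) NA_real_ else log2((p + 1) / (a + 1)))
}

#' Bipartition WC cells by orientation-score signs
#'
#' Greedy sign-consistent clustering: cells are visited in order, each
#' assigned to the side that the weighted majority of its scores against
#' already-assigned cells supports. Cells whose pairwise score signs agree
#' with the final bipartition less than `min_consistency` of the time (or
#' that share no anchors with any assigned cell) are excluded.
#'
#' @param score_mat symmetric matrix of pairwise `log2fc` values (NA on
#'   the diagonal / for undefined pairs), dimnames = cell ids.
#' @param min_consistency minimum fraction of sign-consistent pairs.
#' @param min_signal minimum mean absolute `log2fc` against the other
#'   cells; cells below it carry no usable orientation evidence.
#' @return list with `cluster1`, `cluster2`, `excluded` (cell id vectors)
#'   and the signed assignment vector `sign`.
#' @export
cluster_orientations <- function(score_mat, min_consistency = 0.7,
                                 min_signal = 0.25) {
  cells <- rownames(score_mat)
  n <- length(cells)
  s <- stats::setNames(rep(NA_real_, n), cells)
  if (n >= 1) s[1] <- 1
  for (i in seq_len(n)[-1]) {
    done <- which(!is.na(s))
    w <- score_mat[i, done]
    vote <- sum(w * s[done], na.rm = TRUE)
    s[i] <- if (all(is.na(w)) || vote == 0) NA else sign(vote)
  }
  # consistency: fraction of defined pairs whose sign matches s_i * s_j
  excluded <- character(0)
  if (n > 1) {
    cons <- vapply(seq_len(n), function(i) {
      if (is.na(s[i])) return(0)
      js <- setdiff(which(!is.na(s)), i)
      v <- score_mat[i, js]
      ok <- !is.na(v) & v != 0
      if (!any(ok)) return(0)
      mean(sign(v[ok]) == s[i] * s[js][ok])
    }, numeric(1))
    signal <- vapply(seq_len(n), function(i) {
      v <- abs(score_mat[i, -i])
      if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
    }, numeric(1))
    drop <- is.na(s) | cons < min_consistency | signal < min_signal
    excluded <- cells[drop]
    s[drop] <- NA
  }
  list(cluster1 = cells[!is.na(s) & s > 0],
       cluster2 = cells[!is.na(s) & s < 0],
       excluded = excluded, sign = s)
}

#' Assemble haplotype read sets from an orientation bipartition
#'
#' HP1 draws the Crick reads of cluster 1 and the Watson reads of
#' cluster 2; HP2 the reverse.
#'
#' @param reads alignment data frame (the chromosome's WC-cell reads).
#' @param cluster1,cluster2 cell id vectors.
#' @return `reads` restricted to the two clusters with a `hap_set` column
#'   (`"HP1"`/`"HP2"`).
#' @export
build_haplotype_readsets <- function(reads, cluster1, cluster2) {
  rd <- reads[reads$cell_id %in% c(cluster1, cluster2), , drop = FALSE]
  in1 <- rd$cell_id %in% cluster1
  rd$hap_set <- ifelse((in1 & rd$strand == "C") |
                         (!in1 & rd$strand == "W"), "HP1", "HP2")
  rownames(rd) <- NULL
  rd
}

#' Consensus SNP calling from haplotype read sets
#'
#' For every site covered by both haplotype read sets, each haplotype's
#' consensus allele must be supported by at least `min_support` reads and
#' at least `min_agree` within-haplotype agreement; a variant is emitted
#' when both haplotypes pass and at least one consensus allele differs
#' from the reference.
#'
#' @param readsets reads with a `hap_set` column.
#' @param alleles observed alleles per read.
#' @param reference named character vector of chromosome sequences.
#' @param min_support minimum supporting reads per haplotype (default 2).
#' @param min_agree minimum within-haplotype agreement (default 0.8).
#' @param source label recorded in the `source` column.
#' @return phased variant data frame: chrom, pos, ref, alt, hp1, hp2,
#'   n_hp1, n_hp2, source.
#' @export
call_consensus_snps <- function(readsets, alleles, reference,
                                min_support = 2, min_agree = 0.8,
                                source = "consensus") {
  empty <- empty_variants_df()
  if (is.null(readsets) || !nrow(readsets) ||
      is.null(readsets$hap_set) || !nrow(alleles))
    return(empty)
  al <- alleles
  al$hap <- readsets$hap_set[match(al$read_id, readsets$read_id)]
  al <- al[!is.na(al$hap), , drop = FALSE]
  if (!nrow(al)) return(empty)
  out <- lapply(unique(al$chrom), function(ch) {
    sub <- al[al$chrom == ch, , drop = FALSE]
    pos_u <- sort(unique(sub$pos))
    sub$idx <- match(sub$pos, pos_u)
    cons <- lapply(c("HP1", "HP2"), function(h) {
      hs <- sub[sub$hap == h, , drop = FALSE]
      tab <- table(factor(hs$idx, levels = seq_along(pos_u)), hs$allele)
      if (!ncol(tab)) {
        return(list(allele = rep(NA_character_, length(pos_u)),
                    n = integer(length(pos_u))))
      }
      top <- max.col(tab, ties.method = "first")
      top_n <- tab[cbind(seq_len(nrow(tab)), top)]
      tot <- rowSums(tab)
      tied <- rowSums(tab == top_n & tab > 0) > 1L & top_n > 0L
      ok <- top_n >= min_support & tot > 0 &
        (top_n / pmax(tot, 1L)) >= min_agree & !tied
      list(allele = ifelse(ok, colnames(tab)[top], NA_character_),
           n = as.integer(top_n))
    })
    refb <- substring(reference[[ch]], pos_u + 1L, pos_u + 1L)
    h1 <- cons[[1]]$allele; h2 <- cons[[2]]$allele
    pass <- !is.na(h1) & !is.na(h2) & (h1 != refb | h2 != refb) &
      (h1 == refb | h2 == refb | h1 == h2)
    if (!any(pass)) return(NULL)
    alt <- ifelse(h1[pass] != refb[pass], h1[pass], h2[pass])
    data.frame(chrom = ch, pos = pos_u[pass], ref = refb[pass], alt = alt,
               hp1 = h1[pass], hp2 = h2[pass],
               n_hp1 = cons[[1]]$n[pass], n_hp2 = cons[[2]]$n[pass],
               source = source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Largest run of bins compatible with a WC state for one cell; returns
# a (start, end) interval or NULL when the whole chromosome qualifies.
wc_consistent_interval <- function(reads, cell_id, chrom, chrom_length,
                                   bin_width = 1e6, min_bin_reads = 10) {
  rd <- reads[reads$cell_id == cell_id & reads$chrom == chrom, ,
              drop = FALSE]
  n_bins <- max(1L, as.integer(ceiling(chrom_length / bin_width)))
  if (n_bins == 1L || !nrow(rd)) return(NULL)
  bin <- pmin((rd$start + rd$end) %/% 2L %/% as.integer(bin_width),
              n_bins - 1L)
  crick <- tabulate(bin[rd$strand == "C"] + 1L, n_bins)
  tot <- tabulate(bin + 1L, n_bins)
  pc <- ifelse(tot > 0, crick / tot, 0.5)
  deviant <- tot >= min_bin_reads & (pc > 0.8 | pc < 0.2)
  if (!any(deviant)) return(NULL)
  r <- rle(!deviant)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(c(0L, 0L))
  best <- runs[which.max(r$lengths[runs])]
  c((starts[best] - 1L) * as.integer(bin_width),
    min(ends[best] * as.integer(bin_width), as.integer(chrom_length)))
}

#' Round-1 haplotype reconstruction for one chromosome
#'
#' Selects the chromosome's WC cells (restricting each cell to its largest
#' SCE-free segment), scores and clusters their template-strand
#' orientations at the anchors, assembles haplotype read sets and calls
#' consensus SNPs.
#'
#' @param reads,alleles run-level alignment and allele tables.
#' @param states strand-state calls ([call_strand_state()]).
#' @param anchors anchor hetSNPs ([call_anchor_hetsnps()]).
#' @param chrom chromosome.
#' @param chrom_length chromosome length.
#' @param reference named reference sequence vector.
#' @param min_support,min_agree consensus thresholds.
#' @return list with `variants`, `readsets`, `clusters`, `scores`.
#' @export
reconstruct_round1 <- function(reads, alleles, states, anchors, chrom,
                               chrom_length, reference,
                               min_support = 2, min_agree = 0.8) {
  wc <- states$cell_id[states$chrom == chrom & states$pattern == "WC"]
  empty <- list(variants = empty_variants_df(), readsets = NULL,
                clusters = NULL, scores = NULL)
  if (length(wc) < 2) return(empty)
  rd <- reads[reads$chrom == chrom & reads$cell_id %in% wc, , drop = FALSE]
  if ("duplicate" %in% names(rd) && any(rd$duplicate)) {
    # duplicates stay in consensus support; nothing to drop here
  }
  # SCE guard: keep each cell's largest WC-consistent segment
  for (cid in wc) {
    iv <- wc_consistent_interval(rd, cid, chrom, chrom_length)
    if (!is.null(iv)) {
      drop <- rd$cell_id == cid &
        !((rd$start + rd$end) %/% 2L >= iv[1] &
            (rd$start + rd$end) %/% 2L < iv[2])
      rd <- rd[!drop, , drop = FALSE]
    }
  }
  sa <- wc_strand_alleles(rd, alleles, wc, chrom, anchors)
  n <- length(wc)
  score_mat <- matrix(NA_real_, n, n, dimnames = list(wc, wc))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    sc <- orientation_score(sa[[i]], sa[[j]])
    score_mat[i, j] <- score_mat[j, i] <- sc$log2fc
  }
  cl <- cluster_orientations(score_mat)
  if (!length(cl$cluster1) && !length(cl$cluster2)) return(empty)
  readsets <- build_haplotype_readsets(rd, cl$cluster1, cl$cluster2)
  variants <- call_consensus_snps(readsets, alleles, reference,
                                  min_support = min_support,
                                  min_agree = min_agree,
                                  source = "consensus-round1")
  list(variants = variants, readsets = readsets, clusters = cl,
       scores = score_mat)
}

#' Round-2 haplotype reconstruction
#'
#' Re-annotates the reads of all cells (any strand pattern) against the
#' round-1 phased hetSNPs, keeps reads unambiguously assigned to one
#' haplotype, and repeats consensus SNP calling on the enlarged read sets.
#'
#' @param reads,alleles run-level tables (all cells).
#' @param round1_variants phased variants from round 1.
#' @param reference named reference sequence vector.
#' @param min_support,min_agree consensus thresholds.
#' @return list with `variants` and `readsets` (haplotype-tagged reads).
#' @export
round2_reconstruct <- function(reads, alleles, round1_variants, reference,
                               min_support = 2, min_agree = 0.8) {
  if (is.null(round1_variants) || !nrow(round1_variants)) {
    warning("no round-1 variants; round 2 is empty")
    return(list(variants = round1_variants, readsets = NULL))
  }
  tagged <- annotate_haplotype(reads, alleles, round1_variants)
  rs <- tagged[!is.na(tagged$haplotype_tag), , drop = FALSE]
  rs$hap_set <- rs$haplotype_tag
  variants <- call_consensus_snps(rs, alleles, reference,
                                  min_support = min_support,
                                  min_agree = min_agree,
                                  source = "consensus-round2")
  list(variants = variants, readsets = rs)
}

#' Inversion-aware phase correction
#'
#' Variants inside putative homozygous inversions have their haplotype
#' alleles swapped; variants inside putative heterozygous inversions are
#' excluded.
#'
#' @param variants phased variant data frame.
#' @param inversions inversion calls (chrom, start, end, genotype with
#'   values `"HOM"`/`"HET"`; `"HET-HP1"`/`"HET-HP2"` count as HET).
#' @return corrected variant data frame.
#' @export
apply_inversion_corrections <- function(variants, inversions) {
  if (is.null(inversions) || !nrow(inversions) || !nrow(variants))
    return(variants)
  hom <- inversions[inversions$genotype == "HOM", , drop = FALSE]
  het <- inversions[grepl("^HET", inversions$genotype), , drop = FALSE]
  swap <- in_intervals(variants$chrom, variants$pos, hom)
  tmp <- variants$hp1[swap]
  variants$hp1[swap] <- variants$hp2[swap]
  variants$hp2[swap] <- tmp
  drop <- in_intervals(variants$chrom, variants$pos, het)
  out <- variants[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Phase known (unphased) hetSNPs through read linkage
#'
#' A known heterozygous site is phased when reads already assigned to a
#' haplotype link its alleles consistently: the best ref/alt-to-haplotype
#' assignment must be supported by at least `min_support` reads with no
#' conflicting vote.
#'
#' @param phased phased variant set (used to tag reads).
#' @param known unphased known hetSNPs (chrom, pos, ref, alt).
#' @param reads,alleles run-level tables.
#' @param min_support minimum consistent linking reads (default 2).
#' @return `phased` extended with the newly phased known sites
#'   (source = "known-linked").
#' @export
link_known_snps <- function(phased, known, reads, alleles,
                            min_support = 2) {
  tagged <- annotate_haplotype(reads, alleles, phased)
  al <- alleles
  al$hap <- tagged$haplotype_tag[match(al$read_id, tagged$read_id)]
  al <- al[!is.na(al$hap), , drop = FALSE]
  have <- paste(phased$chrom, phased$pos)
  new <- known[!(paste(known$chrom, known$pos) %in% have), , drop = FALSE]
  rows <- lapply(seq_len(nrow(new)), function(i) {
    obs <- al[al$chrom == new$chrom[i] & al$pos == new$pos[i], ,
              drop = FALSE]
    if (!nrow(obs)) return(NULL)
    v <- function(allele, hap) sum(obs$allele == allele & obs$hap == hap)
    r <- new$ref[i]; a <- new$alt[i]
    # assignment A: ref|alt on HP1|HP2; assignment B: the swap
    supp_a <- v(r, "HP1") + v(a, "HP2"); conf_a <- v(r, "HP2") + v(a, "HP1")
    supp_b <- conf_a; conf_b <- supp_a
    if (supp_a >= min_support && conf_a == 0) {
      hp1 <- r; hp2 <- a
    } else if (supp_b >= min_support && conf_b == 0) {
      hp1 <- a; hp2 <- r
    } else return(NULL)
    data.frame(chrom = new$chrom[i], pos = new$pos[i], ref = r, alt = a,
               hp1 = hp1, hp2 = hp2,
               n_hp1 = v(hp1, "HP1"), n_hp2 = v(hp2, "HP2"),
               source = "known-linked", stringsAsFactors = FALSE)
  })
  linked <- do.call(rbind, rows)
  if (is.null(linked)) {
    out <- phased
  } else {
    for (col in setdiff(names(linked), names(phased)))
      phased[[col]] <- NA
    for (col in setdiff(names(phased), names(linked)))
      linked[[col]] <- NA
    out <- rbind(phased, linked[, names(phased), drop = FALSE])
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate phased variants against truth
#'
#' Precision/recall on positions and allele pairs, genotype precision on
#' the het/hom class, and the Hamming error rate: per chromosome the
#' fraction of compared hetSNPs assigned to the wrong haplotype, minimized
#' over the two possible haplotype labelings, then aggregated across
#' chromosomes weighted by compared counts.
#'
#' @param called,truth phased variant data frames (chrom, pos, ref, alt,
#'   hp1, hp2).
#' @return list with `precision`, `recall`, `genotype_precision`,
#'   `hamming_error_rate`, `n_called`, `n_truth`, `n_compared` and a
#'   `per_chrom` table.
#' @export
evaluate_phasing <- function(called, truth) {
  if (!nrow(called) || !nrow(truth)) {
    warning("no overlap between called and truth variants")
    return(list(precision = NA_real_, recall = NA_real_,
                genotype_precision = NA_real_,
                hamming_error_rate = NA_real_,
                n_called = nrow(called), n_truth = nrow(truth),
                n_compared = 0L, per_chrom = NULL))
  }
  ckey <- paste(called$chrom, called$pos)
  tkey <- paste(truth$chrom, truth$pos)
  m <- match(ckey, tkey)
  pos_match <- !is.na(m)
  pair_eq <- function(i) {
    j <- m[i]
    setequal(c(called$hp1[i], called$hp2[i]),
             c(truth$hp1[j], truth$hp2[j]))
  }
  allele_ok <- pos_match
  allele_ok[pos_match] <- vapply(which(pos_match), pair_eq, logical(1))
  gt_class <- function(h1, h2) ifelse(h1 == h2, "hom", "het")
  gt_ok <- pos_match
  gt_ok[pos_match] <-
    gt_class(called$hp1[pos_match], called$hp2[pos_match]) ==
    gt_class(truth$hp1[m[pos_match]], truth$hp2[m[pos_match]])

  # Hamming: compared = called het sites matching a truth het site with
  # the same allele pair
  cmp <- which(allele_ok & called$hp1 != called$hp2 &
                 truth$hp1[m] != truth$hp2[m])
  per_chrom <- NULL
  ham_num <- 0; ham_den <- 0
  if (length(cmp)) {
    mism <- called$hp1[cmp] != truth$hp1[m[cmp]]
    per_chrom <- do.call(rbind, lapply(
      split(mism, called$chrom[cmp]), function(x) {
        data.frame(n_compared = length(x),
                   mismatch = min(sum(x), length(x) - sum(x)))
      }))
    per_chrom$chrom <- rownames(per_chrom)
    per_chrom$hamming <- per_chrom$mismatch / per_chrom$n_compared
    ham_num <- sum(per_chrom$mismatch)
    ham_den <- sum(per_chrom$n_compared)
  }
  list(precision = mean(allele_ok),
       recall = sum(allele_ok) / nrow(truth),
       genotype_precision = if (any(pos_match)) mean(gt_ok[pos_match])
       else NA_real_,
       hamming_error_rate = if (ham_den > 0) ham_num / ham_den
       else NA_real_,
       n_called = nrow(called), n_truth = nrow(truth),
       n_compared = length(cmp), per_chrom = per_chrom)
}

#' Two-round whole-run haplotype reconstruction
#'
#' The full phasing pipeline on a simulated or imported run: pseudobulk
#' anchor calling (with high-coverage blacklist), per-chromosome WC-cell
#' orientation clustering and round-1 consensus calling, round-2
#' re-annotation of all reads, and inversion-aware phase correction.
#'
#' @param reads,alleles run-level alignment and allele tables.
#' @param chrom_lengths named chromosome lengths.
#' @param reference named reference sequence vector.
#' @param inversions optional inversion calls for phase correction.
#' @param known optional unphased known hetSNPs to link in.
#' @param rounds 1 or 2.
#' @param min_support,min_agree consensus thresholds.
#' @param min_state_reads minimum reads for strand-state calls.
#' @return list of class `strandhap_phasing`: `anchors`, `states`,
#'   `round1`, `round2`, `variants` (corrected final set), `readsets`
#'   (final haplotype-tagged reads), `blacklist`.
#' @export
phase_strand_run <- function(reads, alleles, chrom_lengths, reference,
                             inversions = NULL, known = NULL, rounds = 2,
                             min_support = 2, min_agree = 0.8,
                             min_state_reads = 50) {
  stopifnot(rounds %in% 1:2)
  states <- call_strand_state(chrom_counts(reads),
                              min_reads = min_state_reads)
  blacklist <- coverage_blacklist(reads, chrom_lengths)
  anchors <- call_anchor_hetsnps(alleles, reference = reference,
                                 blacklist = blacklist)
  r1 <- lapply(names(chrom_lengths), function(ch) {
    reconstruct_round1(reads, alleles, states, anchors, ch,
                       chrom_lengths[[ch]], reference,
                       min_support = min_support, min_agree = min_agree)
  })
  round1 <- do.call(rbind, lapply(r1, `[[`, "variants"))
  readsets <- do.call(rbind, lapply(r1, `[[`, "readsets"))
  round2 <- NULL
  if (rounds == 2) {
    r2 <- round2_reconstruct(reads, alleles, round1, reference,
                             min_support = min_support,
                             min_agree = min_agree)
    round2 <- r2$variants
    if (!is.null(r2$readsets)) readsets <- r2$readsets
  }
  final <- if (rounds == 2 && !is.null(round2) && nrow(round2)) round2
  else round1
  variants <- apply_inversion_corrections(final, inversions)
  if (!is.null(known))
    variants <- link_known_snps(variants, known, reads, alleles,
                                min_support = min_support)
  structure(list(anchors = anchors, states = states, round1 = round1,
                 round2 = round2, variants = variants,
                 readsets = readsets, blacklist = blacklist),
            class = "strandhap_phasing")
}

#' @export
print.strandhap_phasing <- function(x, ...) {
  cat("Two-round strand-based haplotype reconstruction\n")
  cat(sprintf("  anchors: %d   round1: %d   round2: %s   final: %d\n",
              nrow(x$anchors), NROW(x$round1),
              if (is.null(x$round2)) "-" else nrow(x$round2),
              NROW(x$variants)))
  invisible(x)
}
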