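#' Extract candidate SVs from alignment CIGAR strings
#'
#' Collects deletion/insertion CIGAR operations of at least `min_len` bp
#' from all reads and merges events of the same type whose positions lie
#' within `merge_window` bp and whose lengths agree within `len_tol`
#' (ratio). Candidate position and length are the medians of the merged
#' events; support is the number of merged reads.
#'
#' @param reads alignment data frame with `chrom`, `start`, `cigar`.
#' @param min_len minimum SV length in bp (default 50).
#' @param merge_window maximum breakpoint distance for merging (bp).
#' @param len_tol maximum relative length difference for merging.
#' @param min_reads minimum supporting reads per candidate.
#' @return data frame: sv_id, chrom, pos, type, length, n_support.
#' @export
extract_candidate_svs <- function(reads, min_len = 50, merge_window = 500,
                                  len_tol = 0.25, min_reads = 1) {
  empty <- data.frame(sv_id = character(0), chrom = character(0),
                      pos = integer(0), type = character(0),
                      length = integer(0), n_support = integer(0),
                      stringsAsFactors = FALSE)
  ev <- extract_read_sv_events(reads, min_len = min_len)
  if (is.null(ev) || !nrow(ev)) return(empty)
  ev <- ev[order(ev$chrom, ev$type, ev$pos), , drop = FALSE]
  # greedy single-linkage merge along the sorted positions
  grp <- integer(nrow(ev)); g <- 0L
  for (i in seq_len(nrow(ev))) {
    if (i == 1L || ev$chrom[i] != ev$chrom[i - 1L] ||
        ev$type[i] != ev$type[i - 1L] ||
        ev$pos[i] - ev$pos[i - 1L] > merge_window ||
        min(ev$length[i], ev$length[i - 1L]) /
          max(ev$length[i], ev$length[i - 1L]) < 1 - len_tol) {
      g <- g + 1L
    }
    grp[i] <- g
  }
  out <- do.call(rbind, lapply(split(ev, grp), function(x) {
    data.frame(chrom = x$chrom[1],
               pos = as.integer(stats::median(x$pos)),
               type = x$type[1],
               length = as.integer(stats::median(x$length)),
               n_support = nrow(x), stringsAsFactors = FALSE)
  }))
  out <- out[out$n_support >= min_reads, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$sv_id <- sprintf("cand%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("sv_id", "chrom", "pos", "type", "length", "n_support")]
}

#' Blacklist filtering of SV candidates
#'
#' Removes SVs that (1) lie within `adjacency` bp of another SV (both
#' members of the pair are removed), (2) are longer than `max_len`,
#' (3) overlap regions of low (`< cov_lo`) or high (`> cov_hi`) genomic
#' coverage in every provided coverage track, or (4) overlap annotated
#' difficult/tandem regions longer than 200 bp. Rules whose inputs are
#' missing are skipped with a warning. Filtering is idempotent.
#'
#' @param svs candidate data frame (chrom, pos, type, length).
#' @param coverage_tracks optional list of coverage data frames
#'   (chrom, start, end, coverage).
#' @param difficult_bed,tandem_bed optional region data frames
#'   (chrom, start, end).
#' @param adjacency adjacency distance in bp (default 1000).
#' @param max_len maximum SV length kept (default 10 kb).
#' @param cov_lo,cov_hi coverage bounds (defaults 10 and 80).
#' @param min_region region length threshold for difficult/tandem rules.
#' @return list with `svs` (retained) and `removed` (with a `reason`).
#' @export
filter_blacklist <- function(svs, coverage_tracks = NULL,
                             difficult_bed = NULL, tandem_bed = NULL,
                             adjacency = 1000, max_len = 10000,
                             cov_lo = 10, cov_hi = 80, min_region = 200) {
  reason <- rep(NA_character_, nrow(svs))
  span_start <- svs$pos
  span_end <- svs$pos + ifelse(svs$type == "DEL", svs$length, 0L)

  for (ch in unique(svs$chrom)) {
    idx <- which(svs$chrom == ch)
    if (length(idx) < 2) next
    o <- idx[order(span_start[idx])]
    d_next <- span_start[o][-1] - span_end[o][-length(o)]
    close_pair <- d_next <= adjacency
    bad <- unique(c(o[-length(o)][close_pair], o[-1][close_pair]))
    reason[bad] <- "adjacent"
  }
  long <- is.na(reason) & svs$length > max_len
  reason[long] <- "length"

  overlaps_regions <- function(regions) {
    hit <- rep(FALSE, nrow(svs))
    for (ch in unique(regions$chrom)) {
      sel <- svs$chrom == ch
      iv <- regions[regions$chrom == ch, , drop = FALSE]
      if (!any(sel) || !nrow(iv)) next
      hit[sel] <- IRanges::overlapsAny(
        IRanges::IRanges(span_start[sel] + 1L, span_end[sel] + 1L),
        IRanges::IRanges(iv$start + 1L, iv$end))
    }
    hit
  }

  if (is.null(coverage_tracks) || !length(coverage_tracks)) {
    warning("no coverage tracks provided; coverage rule skipped")
  } else {
    bad_cov <- rep(TRUE, nrow(svs))
    for (track in coverage_tracks) {
      bad <- track[track$coverage < cov_lo | track$coverage > cov_hi, ,
                   drop = FALSE]
      bad_cov <- bad_cov & overlaps_regions(bad)
    }
    reason[is.na(reason) & bad_cov] <- "coverage"
  }
  for (nm in c("difficult", "tandem")) {
    bed <- if (nm == "difficult") difficult_bed else tandem_bed
    if (is.null(bed)) {
      warning("no ", nm, " regions provided; rule skipped")
      next
    }
    bed <- bed[bed$end - bed$start > min_region, , drop = FALSE]
    if (nrow(bed))
      reason[is.na(reason) & overlaps_regions(bed)] <- nm
  }
  keep <- is.na(reason)
  removed <- svs[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- rownames(removed) <- NULL
  list(svs = out, removed = removed)
}

# match candidate SVs against per-read SV signatures extracted from CIGARs
sv_signature_match <- function(sv, events, merge_window = 500,
                               len_tol = 0.25) {
  hit <- events$chrom == sv$chrom & events$type == sv$type &
    abs(events$pos - sv$pos) <= merge_window &
    pmin(events$length, sv$length) /
      pmax(events$length, sv$length) >= 1 - len_tol
  unique(events$read_id[hit])
}

#' Genotype and phase SVs from haplotype read sets
#'
#' For every SV, reads of each haplotype either support it (they carry a
#' matching DEL/INS signature) or oppose it (they span the locus without
#' the signature). An SV is HOM when both haplotypes support it with at
#' least `min_support` reads, HET-HP1/HET-HP2 when one haplotype supports
#' and the other opposes (each with `min_support` reads), otherwise
#' unresolved.
#'
#' @param svs candidate data frame (sv_id, chrom, pos, type, length).
#' @param readsets haplotype-tagged reads (`hap_set` column, `cigar`).
#' @param min_support minimum reads per haplotype (default 2, mirroring
#'   the consensus SNP support rule).
#' @param flank bp of flank a read must span beyond the SV locus to count
#'   as an opposing (reference-agreeing) observation.
#' @return `svs` with support/oppose counts per haplotype and a
#'   `genotype` column (`HOM`, `HET-HP1`, `HET-HP2`, `unresolved`).
#' @export
genotype_svs <- function(svs, readsets, min_support = 2, flank = 50) {
  events <- extract_read_sv_events(readsets)
  n <- nrow(svs)
  out <- svs
  out$support_hp1 <- out$oppose_hp1 <- integer(n)
  out$support_hp2 <- out$oppose_hp2 <- integer(n)
  out$genotype <- character(n)
  for (i in seq_len(n)) {
    sv <- svs[i, ]
    sup_reads <- sv_signature_match(sv, events)
    span_end <- sv$pos + if (sv$type == "DEL") sv$length else 0L
    spanning <- readsets$chrom == sv$chrom &
      readsets$start + flank <= sv$pos &
      readsets$end - flank >= span_end
    sup <- readsets$read_id %in% sup_reads
    for (h in c("HP1", "HP2")) {
      hs <- readsets$hap_set == h
      out[i, paste0("support_", tolower(h))] <- sum(hs & sup)
      out[i, paste0("oppose_", tolower(h))] <- sum(hs & spanning & !sup)
    }
    s1 <- out$support_hp1[i]; s2 <- out$support_hp2[i]
    o1 <- out$oppose_hp1[i]; o2 <- out$oppose_hp2[i]
    out$genotype[i] <-
      if (s1 >= min_support && s2 >= min_support) "HOM"
      else if (s1 >= min_support && o2 >= min_support) "HET-HP1"
      else if (s2 >= min_support && o1 >= min_support) "HET-HP2"
      else "unresolved"
  }
  out
}

# per-read DEL/INS events (>= 50 bp) straight from CIGARs
extract_read_sv_events <- function(reads, min_len = 50) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      type = character(0), length = integer(0),
                      read_id = character(0), stringsAsFactors = FALSE)
  has <- grepl("[DI]", reads$cigar)
  rd <- reads[has, , drop = FALSE]
  if (!nrow(rd)) return(empty)
  out <- lapply(seq_len(nrow(rd)), function(i) {
    ops <- regmatches(rd$cigar[i], gregexpr("[0-9]+[MIDNSHP=X]",
                                            rd$cigar[i]))[[1]]
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    refpos <- rd$start[i] + c(0L, cumsum(ifelse(
      op %in% c("M", "D", "N", "=", "X"), len, 0L)))[seq_along(op)]
    keep <- op %in% c("D", "I") & len >= min_len
    if (!any(keep)) return(NULL)
    data.frame(chrom = rd$chrom[i], pos = refpos[keep],
               type = ifelse(op[keep] == "D", "DEL", "INS"),
               length = len[keep], read_id = rd$read_id[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Inversion-aware phase correction for SVs
#'
#' Heterozygous SV phases are switched (HET-HP1 <-> HET-HP2) inside
#' putative homozygous inversions; SVs inside putative heterozygous
#' inversions are dropped, consistent with the SNP rule.
#'
#' @param svs genotyped SVs ([genotype_svs()]).
#' @param inversions inversion calls (chrom, start, end, genotype).
#' @return corrected SV data frame.
#' @export
switch_phase_in_inversions <- function(svs, inversions) {
  if (is.null(inversions) || !nrow(inversions) || !nrow(svs)) return(svs)
  hom <- inversions[inversions$genotype == "HOM", , drop = FALSE]
  het <- inversions[grepl("^HET", inversions$genotype), , drop = FALSE]
  in_hom <- in_intervals(svs$chrom, svs$pos, hom)
  svs$genotype[in_hom & svs$genotype == "HET-HP1"] <- "HET-HP2.tmp"
  svs$genotype[in_hom & svs$genotype == "HET-HP2"] <- "HET-HP1"
  svs$genotype[svs$genotype == "HET-HP2.tmp"] <- "HET-HP2"
  drop <- in_intervals(svs$chrom, svs$pos, het)
  out <- svs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance from each SV to its nearest hetSNP
#'
#' The minimum over phased hetSNPs of the distance to the nearest SV
#' breakpoint, bucketed as <= 2 kb, 2-10 kb and > 10 kb.
#'
#' @param svs SV data frame (chrom, pos, type, length).
#' @param hetsnps phased hetSNP data frame (chrom, pos).
#' @return `svs` with `nearest_hetsnp_distance` and `distance_bucket`
#'   columns (NA when the chromosome has no hetSNP).
#' @export
nearest_hetsnp_distances <- function(svs, hetsnps) {
  svs$nearest_hetsnp_distance <- NA_real_
  for (i in seq_len(nrow(svs))) {
    sn <- hetsnps$pos[hetsnps$chrom == svs$chrom[i]]
    if (!length(sn)) next
    bks <- c(svs$pos[i],
             svs$pos[i] + if (svs$type[i] == "DEL") svs$length[i] else 0L)
    svs$nearest_hetsnp_distance[i] <- min(abs(outer(sn, bks, "-")))
  }
  svs$distance_bucket <- cut(svs$nearest_hetsnp_distance,
                             c(-1, 2000, 10000, Inf),
                             labels = c("<=2kb", "2-10kb", ">10kb"))
  svs
}
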