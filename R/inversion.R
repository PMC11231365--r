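#' Select cells for the Crick-Crick composite of a chromosome
#'
#' Cells whose chromosome shows a CC pattern (`p_c > 0.8`) enter the
#' composite as-is; WW cells (`p_c < 0.2`) enter with a flip flag so their
#' read directions can be switched into CC orientation. WC cells are not
#' composite material.
#'
#' @param states output of [call_strand_state()].
#' @param chrom chromosome.
#' @return data frame with cell_id and flip flag (possibly empty, with a
#'   warning).
#' @export
select_composite_cells <- function(states, chrom) {
  st <- states[states$chrom == chrom &
                 states$pattern %in% c("CC", "WW"), , drop = FALSE]
  if (!nrow(st)) {
    warning("no CC/WW cells qualify for the composite on ", chrom)
    return(data.frame(cell_id = character(0), flip = logical(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(cell_id = st$cell_id, flip = st$pattern == "WW",
             stringsAsFactors = FALSE)
}

# per-cell, per-bin Crick fraction after orientation flip
binned_pc <- function(reads, cells, chrom, chrom_length, bin_width) {
  n_bins <- max(1L, as.integer(ceiling(chrom_length / bin_width)))
  rd <- reads[reads$chrom == chrom & reads$cell_id %in% cells$cell_id, ,
              drop = FALSE]
  if ("duplicate" %in% names(rd)) rd <- rd[!rd$duplicate, , drop = FALSE]
  flip <- cells$flip[match(rd$cell_id, cells$cell_id)]
  strand <- ifelse(flip, flip_strand(rd$strand), rd$strand)
  bin <- pmin(((rd$start + rd$end) %/% 2L) %/% as.integer(bin_width),
              n_bins - 1L)
  crick <- matrix(0L, nrow(cells), n_bins,
                  dimnames = list(cells$cell_id, NULL))
  total <- crick
  if (nrow(rd)) {
    tc <- tapply(strand == "C", list(rd$cell_id, bin), sum)
    tt <- tapply(rep(1L, nrow(rd)), list(rd$cell_id, bin), sum)
    crick[rownames(tc), as.integer(colnames(tc)) + 1L] <-
      ifelse(is.na(tc), 0L, tc)
    total[rownames(tt), as.integer(colnames(tt)) + 1L] <-
      ifelse(is.na(tt), 0L, tt)
  }
  list(crick = crick, total = total, n_bins = n_bins,
       bin_width = as.integer(bin_width))
}

#' Pure single-strand-state regions per composite cell
#'
#' Bins the chromosome (1 Mb default), computes each composite cell's
#' post-flip Crick fraction per bin, groups cells with similar bin
#' profiles, and derives the expected Crick fraction per bin as the median
#' over the cells of the profile group. Maximal runs of bins where a cell
#' matches the expectation (within `tol`, with at least `min_bin_reads`
#' reads) become that cell's pure intervals; bins downstream of an SCE, or
#' without evidence, drop out.
#'
#' @param reads alignment data frame.
#' @param cells composite cell set from [select_composite_cells()].
#' @param chrom chromosome.
#' @param chrom_length chromosome length (bp).
#' @param bin_width bin width in bp (default 1 Mb).
#' @param tol tolerated deviation from the expected Crick fraction.
#' @param min_bin_reads minimum reads for a bin to count as evidence.
#' @return data frame of intervals (cell_id, chrom, start, end; 0-based
#'   half-open, bin-aligned).
#' @export
pure_cc_regions <- function(reads, cells, chrom, chrom_length,
                            bin_width = 1e6, tol = 0.1,
                            min_bin_reads = 10) {
  if (!nrow(cells))
    return(data.frame(cell_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  b <- binned_pc(reads, cells, chrom, chrom_length, bin_width)
  pc <- ifelse(b$total > 0, b$crick / b$total, NA_real_)

  # profile grouping: cells with similar binned p_c share an expectation
  groups <- rep(1L, nrow(cells))
  if (nrow(cells) >= 4) {
    filled <- pc
    filled[is.na(filled)] <- 0.5
    hc <- stats::hclust(stats::dist(filled), method = "average")
    groups <- stats::cutree(hc, h = 0.3 * sqrt(b$n_bins))
  }
  expected <- matrix(NA_real_, nrow(cells), b$n_bins)
  global_med <- apply(pc, 2, stats::median, na.rm = TRUE)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    if (length(rows) < 2) {
      # a singleton profile cannot justify itself; hold it to the
      # cross-cell consensus
      expected[rows, ] <- matrix(global_med, length(rows), b$n_bins,
                                 byrow = TRUE)
      next
    }
    med <- apply(pc[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    expected[rows, ] <- matrix(med, length(rows), b$n_bins, byrow = TRUE)
  }

  pure <- !is.na(pc) & !is.na(expected) & b$total >= min_bin_reads &
    abs(pc - expected) <= tol

  out <- lapply(seq_len(nrow(cells)), function(i) {
    r <- rle(pure[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    data.frame(cell_id = cells$cell_id[i], chrom = chrom,
               start = (starts[keep] - 1L) * b$bin_width,
               end = pmin(ends[keep] * b$bin_width,
                          as.integer(chrom_length)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cell_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the Crick-Crick composite read set
#'
#' Keeps reads that overlap their own cell's pure regions, switching the
#' strand of reads from flipped (WW) cells so the composite is CC
#' oriented.
#'
#' @param reads alignment data frame.
#' @param cells composite cell set (cell_id, flip).
#' @param pure_regions intervals from [pure_cc_regions()].
#' @return composite read data frame (same columns as `reads`).
#' @export
build_composite <- function(reads, cells, pure_regions) {
  rd <- reads[reads$cell_id %in% cells$cell_id, , drop = FALSE]
  if ("duplicate" %in% names(rd)) rd <- rd[!rd$duplicate, , drop = FALSE]
  if (!nrow(rd) || !nrow(pure_regions)) return(rd[0, , drop = FALSE])
  keep <- logical(nrow(rd))
  for (cid in unique(rd$cell_id)) {
    ri <- which(rd$cell_id == cid)
    pr <- pure_regions[pure_regions$cell_id == cid, , drop = FALSE]
    if (!nrow(pr)) next
    for (ch in unique(rd$chrom[ri])) {
      rj <- ri[rd$chrom[ri] == ch]
      pj <- pr[pr$chrom == ch, , drop = FALSE]
      if (!nrow(pj)) next
      keep[rj] <- IRanges::overlapsAny(
        IRanges::IRanges(rd$start[rj] + 1L, rd$end[rj]),
        IRanges::IRanges(pj$start + 1L, pj$end))
    }
  }
  out <- rd[keep, , drop = FALSE]
  flip <- cells$flip[match(out$cell_id, cells$cell_id)]
  out$strand <- ifelse(flip, flip_strand(out$strand), out$strand)
  rownames(out) <- NULL
  out
}

#' Scan a CC composite for putative inversions
#'
#' Candidate regions are found in two passes. Seed fragments are maximal
#' chains of Watson reads whose consecutive midpoints lie within
#' `max_gap`; adjacent Watson-enriched fragments (Watson fraction at
#' least `merge_min_pw`) separated by no more than `merge_gap` are then
#' merged and re-counted, so that a single event fragmented by local
#' coverage dips is re-joined while sparse background Watson noise (a
#' small minority fraction) never chains across it. Each candidate is
#' genotyped from the Watson fraction `p_w` among composite reads
#' (counted by midpoint): fewer than `min_reads` total reads or
#' `p_w < 0.1` filters the region out, `p_w > 0.9` is a putative
#' homozygous inversion, `0.4 < p_w < 0.6` a putative heterozygous one,
#' anything else stays ungenotyped.
#'
#' @param composite composite reads from [build_composite()].
#' @param chrom chromosome scanned.
#' @param max_gap maximum midpoint gap chaining Watson reads (bp).
#' @param merge_gap maximum distance across which Watson-enriched
#'   fragments are re-joined (bp).
#' @param merge_min_pw minimum fragment Watson fraction to take part in
#'   merging.
#' @param min_reads minimum total reads per candidate (default 20).
#' @return data frame: chrom, start, end, n_crick, n_watson, p_w,
#'   genotype (`"HOM"`, `"HET"`, `"ungenotyped"`, `"filtered"`).
#' @export
scan_inversions <- function(composite, chrom, max_gap = 5000,
                            merge_gap = 5e4, merge_min_pw = 0.3,
                            min_reads = 20) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_crick = integer(0),
                      n_watson = integer(0), p_w = numeric(0),
                      genotype = character(0), stringsAsFactors = FALSE)
  rd <- composite[composite$chrom == chrom, , drop = FALSE]
  if (!nrow(rd)) return(empty)
  mid <- (rd$start + rd$end) %/% 2L
  wmid <- sort(mid[rd$strand == "W"])
  if (!length(wmid)) return(empty)
  brk <- which(diff(wmid) > max_gap)
  lo <- wmid[c(1L, brk + 1L)]
  hi <- wmid[c(brk, length(wmid))]
  count <- function(a, b) {
    inside <- mid >= a & mid <= b
    c(n_c = sum(inside & rd$strand == "C"),
      n_w = sum(inside & rd$strand == "W"))
  }
  frag <- t(mapply(count, lo, hi))
  pw <- frag[, "n_w"] / (frag[, "n_w"] + frag[, "n_c"])
  # re-join enriched fragments split by coverage dips
  repeat {
    enriched <- pw >= merge_min_pw
    gap_next <- c(lo[-1] - hi[-length(lo)], Inf)
    j <- which(enriched[-length(lo)] & enriched[-1] &
                 gap_next[-length(lo)] <= merge_gap)
    if (!length(j)) break
    k <- j[1]
    hi[k] <- hi[k + 1]
    lo <- lo[-(k + 1)]; hi <- hi[-(k + 1)]
    frag <- t(mapply(count, lo, hi))
    pw <- frag[, "n_w"] / (frag[, "n_w"] + frag[, "n_c"])
  }
  out <- lapply(seq_along(lo), function(k) {
    n_c <- frag[k, "n_c"]; n_w <- frag[k, "n_w"]
    p_w <- n_w / (n_w + n_c)
    genotype <- if (n_w + n_c < min_reads) "filtered"
    else if (p_w > 0.9) "HOM"
    else if (p_w > 0.4 && p_w < 0.6) "HET"
    else if (p_w < 0.1) "filtered"
    else "ungenotyped"
    data.frame(chrom = chrom, start = lo[k], end = hi[k] + 1L,
               n_crick = n_c, n_watson = n_w, p_w = p_w,
               genotype = genotype, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect putative inversions across all chromosomes
#'
#' Convenience wrapper: calls strand states, selects composite cells,
#' derives pure regions, builds the composite and scans it, per
#' chromosome.
#'
#' @param reads alignment data frame (duplicates flagged).
#' @param chrom_lengths named chromosome length vector.
#' @param bin_width,tol,min_bin_reads see [pure_cc_regions()].
#' @param max_gap,min_reads see [scan_inversions()].
#' @param min_state_reads see [call_strand_state()].
#' @return inversion call data frame across chromosomes.
#' @export
detect_inversions <- function(reads, chrom_lengths, bin_width = 1e6,
                              tol = 0.1, min_bin_reads = 10,
                              max_gap = 5000, min_reads = 20,
                              min_state_reads = 50) {
  states <- call_strand_state(chrom_counts(reads),
                              min_reads = min_state_reads)
  out <- lapply(names(chrom_lengths), function(ch) {
    cells <- suppressWarnings(select_composite_cells(states, ch))
    if (!nrow(cells)) return(NULL)
    pr <- pure_cc_regions(reads, cells, ch, chrom_lengths[[ch]],
                          bin_width = bin_width, tol = tol,
                          min_bin_reads = min_bin_reads)
    comp <- build_composite(reads[reads$chrom == ch, , drop = FALSE],
                            cells, pr)
    scan_inversions(comp, ch, max_gap = max_gap, min_reads = min_reads)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- scan_inversions(empty_reads_df(), "none")
  rownames(out) <- NULL
  out
}
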