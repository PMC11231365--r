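#' Per-(cell, chromosome) strand counts and background
#'
#' Counts unique (non-duplicate) Crick and Watson reads for every cell and
#' chromosome, with the Crick fraction `p_c` and the per-chromosome
#' background `min(crick, watson) / (crick + watson)`.
#'
#' @param reads alignment data frame with `cell_id`, `chrom`, `strand` and
#'   a `duplicate` flag (duplicates are excluded from the counts).
#' @return data frame with cell_id, chrom, n_crick, n_watson, n_total,
#'   p_c and background (NA where the chromosome has no reads).
#' @export
chrom_counts <- function(reads) {
  if ("duplicate" %in% names(reads))
    reads <- reads[!reads$duplicate, , drop = FALSE]
  cells <- unique(reads$cell_id)
  chroms <- unique(reads$chrom)
  grid <- expand.grid(cell_id = cells, chrom = chroms,
                      stringsAsFactors = FALSE)
  key <- paste(reads$cell_id, reads$chrom)
  crick <- tapply(reads$strand == "C", key, sum)
  total <- tapply(rep(1L, nrow(reads)), key, sum)
  gkey <- paste(grid$cell_id, grid$chrom)
  n_crick <- as.integer(ifelse(is.na(crick[gkey]), 0L, crick[gkey]))
  n_total <- as.integer(ifelse(is.na(total[gkey]), 0L, total[gkey]))
  n_watson <- n_total - n_crick
  p_c <- ifelse(n_total > 0, n_crick / n_total, NA_real_)
  data.frame(grid, n_crick = n_crick, n_watson = n_watson,
             n_total = n_total, p_c = p_c,
             background = ifelse(n_total > 0,
                                 pmin(n_crick, n_watson) / n_total,
                                 NA_real_),
             stringsAsFactors = FALSE)
}

#' Background noise of one cell
#'
#' The mean of the four smallest per-chromosome backgrounds among the
#' cell's autosomes, a proxy for incomplete nascent-strand removal.
#'
#' @param counts `chrom_counts()` rows for a single cell.
#' @return background fraction in \[0, 0.5\].
#' @export
cell_background <- function(counts) {
  stopifnot(length(unique(counts$cell_id)) <= 1)
  auto <- counts[is_autosome(counts$chrom) & counts$n_total > 0, ,
                 drop = FALSE]
  if (nrow(auto) < 4)
    stop("need at least 4 autosomes with reads to compute cell background")
  mean(sort(auto$background)[1:4])
}

#' Per-cell QC statistics
#'
#' @param reads alignment data frame (duplicates flagged).
#' @return data frame with cell_id, unique_reads and background.
#' @export
cell_qc_stats <- function(reads) {
  counts <- chrom_counts(reads)
  uniq <- reads[!reads$duplicate, , drop = FALSE]
  cells <- unique(counts$cell_id)
  data.frame(
    cell_id = cells,
    unique_reads = as.integer(table(uniq$cell_id)[cells]),
    background = vapply(cells, function(cid) {
      cell_background(counts[counts$cell_id == cid, , drop = FALSE])
    }, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Apply library retention criteria
#'
#' A library is retained when it has at least `min_unique_reads` unique
#' reads and a background strictly below `max_background`.
#'
#' @param stats per-cell stats from [cell_qc_stats()].
#' @param min_unique_reads minimum unique read count (default 80,000; a
#'   mouse preset would use 70,000).
#' @param max_background exclusive background ceiling (default 0.05).
#' @return the retained subset of `stats`.
#' @export
filter_cells <- function(stats, min_unique_reads = 80000,
                         max_background = 0.05) {
  keep <- stats$unique_reads >= min_unique_reads &
    stats$background < max_background
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call per-chromosome strand inheritance states
#'
#' CC when `p_c > cc_min`, WW when `p_c < ww_max`, WC when `p_c` lies in
#' the symmetric band around 0.5, and unknown when the chromosome has
#' fewer than `min_reads` unique reads (or an intermediate `p_c`).
#'
#' @param counts `chrom_counts()` data frame.
#' @param min_reads minimum unique reads to call a state (default 50).
#' @param cc_min,ww_max CC/WW thresholds (defaults 0.8 and 0.2).
#' @param wc_band inclusive `p_c` band called WC (default 0.35–0.65).
#' @return `counts` with a `pattern` column (`"WW"`, `"CC"`, `"WC"` or
#'   `"unknown"`).
#' @export
call_strand_state <- function(counts, min_reads = 50, cc_min = 0.8,
                              ww_max = 0.2, wc_band = c(0.35, 0.65)) {
  p <- counts$p_c
  pattern <- rep("unknown", nrow(counts))
  known <- !is.na(p) & counts$n_total >= min_reads
  pattern[known & p > cc_min] <- "CC"
  pattern[known & p < ww_max] <- "WW"
  pattern[known & p >= wc_band[1] & p <= wc_band[2]] <- "WC"
  counts$pattern <- pattern
  counts
}
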