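#' Filter alignments to primary, nuclear, high-quality records
#'
#' Removes unmapped, secondary and supplementary records, mitochondrial
#' contigs and alignments with MAPQ below the threshold.
#'
#' @param reads alignment data frame (columns `chrom`, `start`, `end`,
#'   `strand`, `mapq`; optional logical `unmapped`, `secondary`,
#'   `supplementary`).
#' @param min_mapq minimum MAPQ kept (default 30; records with MAPQ < 30
#'   are removed).
#' @param mito contig names treated as mitochondrial.
#' @return the filtered data frame.
#' @export
filter_alignments <- function(reads, min_mapq = 30,
                              mito = c("chrM", "MT", "chrMT", "M")) {
  keep <- rep(TRUE, nrow(reads))
  for (flag in c("unmapped", "secondary", "supplementary"))
    if (flag %in% names(reads)) keep <- keep & !reads[[flag]]
  keep <- keep & !(reads$chrom %in% mito) & reads$mapq >= min_mapq
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mark PCR duplicates by strand and edge similarity
#'
#' Two reads of the same cell are duplicates when they lie on the same
#' chromosome and strand and both their start and end coordinates differ
#' by less than `edge_tol` bp (strict). Duplicate groups are the transitive
#' closure of this relation; within each group exactly one representative
#' (highest MAPQ, ties broken by longest span then leftmost start) is left
#' unflagged. Implemented as a sorted sweep bounded by `edge_tol`, so the
#' result is independent of input order.
#'
#' @param reads alignment data frame with `cell_id`, `chrom`, `start`,
#'   `end`, `strand`, `mapq`.
#' @param edge_tol edge tolerance in bp (default 20).
#' @return `reads` with a logical `duplicate` column.
#' @export
mark_duplicates <- function(reads, edge_tol = 20) {
  n <- nrow(reads)
  reads$duplicate <- logical(n)
  if (n < 2) return(reads)
  if ("cell_id" %in% names(reads)) {
    grp <- paste(reads$cell_id, reads$chrom, reads$strand)
  } else grp <- paste(reads$chrom, reads$strand)
  ord <- order(grp, reads$start, reads$end)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    b <- a + 1L
    while (b <= n) {
      j <- ord[b]
      if (grp[j] != grp[i] ||
          reads$start[j] - reads$start[i] >= edge_tol) break
      if (abs(reads$end[i] - reads$end[j]) < edge_tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      b <- b + 1L
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  for (g in split(seq_len(n), root)) {
    if (length(g) < 2) next
    rep_idx <- g[order(-reads$mapq[g],
                       -(reads$end[g] - reads$start[g]),
                       reads$start[g], g)][1]
    reads$duplicate[setdiff(g, rep_idx)] <- TRUE
  }
  reads
}

#' Annotate reads with their haplotype of origin
#'
#' A read is tagged HP1 (or HP2) when every informative allele it shows at
#' phased hetSNP positions matches that haplotype; reads with mixed
#' evidence or without any informative site are left untagged. Observed
#' alleles matching neither haplotype allele are uninformative.
#'
#' @param reads alignment data frame with `read_id`.
#' @param alleles observed alleles per read (`read_id`, `chrom`, `pos`,
#'   `allele`).
#' @param phased_snps phased variants (`chrom`, `pos`, `hp1`, `hp2`).
#' @return `reads` with a `haplotype_tag` column (`"HP1"`, `"HP2"` or
#'   `NA`).
#' @export
annotate_haplotype <- function(reads, alleles, phased_snps) {
  reads$haplotype_tag <- NA_character_
  het <- phased_snps[phased_snps$hp1 != phased_snps$hp2, , drop = FALSE]
  if (!nrow(het) || !nrow(alleles)) return(reads)
  key <- paste(het$chrom, het$pos)
  m <- match(paste(alleles$chrom, alleles$pos), key)
  ok <- !is.na(m)
  if (!any(ok)) return(reads)
  a <- alleles[ok, , drop = FALSE]
  m <- m[ok]
  vote <- ifelse(a$allele == het$hp1[m], "HP1",
                 ifelse(a$allele == het$hp2[m], "HP2", NA_character_))
  keep <- !is.na(vote)
  if (!any(keep)) return(reads)
  tab <- table(a$read_id[keep], vote[keep])
  hp1 <- if ("HP1" %in% colnames(tab)) tab[, "HP1"] else
    stats::setNames(rep(0L, nrow(tab)), rownames(tab))
  hp2 <- if ("HP2" %in% colnames(tab)) tab[, "HP2"] else
    stats::setNames(rep(0L, nrow(tab)), rownames(tab))
  tag <- ifelse(hp1 > 0 & hp2 == 0, "HP1",
                ifelse(hp2 > 0 & hp1 == 0, "HP2", NA_character_))
  idx <- match(reads$read_id, rownames(tab))
  got <- !is.na(idx)
  reads$haplotype_tag[got] <- tag[idx[got]]
  reads
}

#' Read alignments from a BAM file
#'
#' Imports the fields the pipeline uses into the package's alignment data
#' frame representation (0-based half-open coordinates; Crick = forward
#' strand, Watson = reverse strand). Requires the Rsamtools package.
#'
#' @param path BAM file path.
#' @param cell_id cell identifier attached to every record.
#' @return alignment data frame.
#' @export
read_bam_alignments <- function(path, cell_id = NA_character_) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read BAM files")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "cigar", "strand",
             "mapq", "flag"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  widths <- cigar_ref_width(b$cigar)
  flag <- b$flag
  data.frame(
    read_id = b$qname, cell_id = cell_id,
    chrom = as.character(b$rname),
    start = b$pos - 1L, end = b$pos - 1L + widths,
    strand = ifelse(as.character(b$strand) == "-", "W", "C"),
    mapq = b$mapq, duplicate = bitwAnd(flag, 1024L) > 0L,
    cigar = b$cigar,
    unmapped = bitwAnd(flag, 4L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    stringsAsFactors = FALSE)
}

# reference-consumed width of CIGAR strings (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
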