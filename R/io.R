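#' Write phased variants to a VCF file
#'
#' Single-sample VCF 4.2 with phased genotypes (`GT` like `0|1`), one
#' phase set per chromosome (PS = chromosome). Coordinates are converted
#' from the package's 0-based representation to VCF's 1-based POS.
#'
#' @param variants phased variant data frame (chrom, pos, ref, alt, hp1,
#'   hp2).
#' @param path output file path.
#' @param sample sample name in the header.
#' @return invisibly, `path`.
#' @export
write_phased_vcf <- function(variants, path, sample = "sample1") {
  gt1 <- ifelse(variants$hp1 == variants$ref, "0", "1")
  gt2 <- ifelse(variants$hp2 == variants$ref, "0", "1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=String,Description=\"Phase set\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample),
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:PS\t%s|%s:%s",
            variants$chrom, variants$pos + 1L, variants$ref,
            variants$alt, gt1, gt2, variants$chrom))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phased single-sample VCF into the variant representation
#'
#' Minimal reader for the files written by [write_phased_vcf()] and for
#' externally phased SNP VCFs with `GT` as the first FORMAT field.
#'
#' @param path VCF path.
#' @return phased variant data frame (chrom, pos, ref, alt, hp1, hp2).
#' @export
read_phased_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(empty_variants_df()[, 1:6])
  f <- do.call(rbind, strsplit(body, "\t"))
  gt <- sub(":.*", "", f[, 10])
  sep <- substr(gsub("[0-9]", "", gt), 1, 1)
  a1 <- as.integer(sub("[|/].*", "", gt))
  a2 <- as.integer(sub(".*[|/]", "", gt))
  alleles <- cbind(f[, 4], f[, 5])
  data.frame(chrom = f[, 1], pos = as.integer(f[, 2]) - 1L,
             ref = f[, 4], alt = f[, 5],
             hp1 = alleles[cbind(seq_along(a1), a1 + 1L)],
             hp2 = alleles[cbind(seq_along(a2), a2 + 1L)],
             phased = sep == "|", stringsAsFactors = FALSE)
}

#' Write intervals as BED
#'
#' BED3+ text (0-based half-open), with any extra columns appended.
#'
#' @param intervals data frame with chrom, start, end and optional extra
#'   columns.
#' @param path output path.
#' @param extra_cols extra column names to append after the first three.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path,
                      extra_cols = setdiff(names(intervals),
                                           c("chrom", "start", "end"))) {
  df <- intervals[, c("chrom", "start", "end", extra_cols), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED path.
#' @param extra_cols names for columns beyond chrom/start/end.
#' @return data frame with chrom, start, end (+ extras), 0-based
#'   half-open.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_cols) && ncol(df) >= 3 + length(extra_cols))
    names(df)[seq_along(extra_cols) + 3] <- extra_cols
  df
}

#' Write a reference genome (or haplotypes) as FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  dna <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Write all truth annotations of a simulated genome
#'
#' Writes the reference FASTA, a phased truth SNP VCF, a truth SV table
#' (TSV) and a truth inversion BED into a directory.
#'
#' @param truth a `diploid_truth` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$reference, file.path(dir, "reference.fa"))
  write_phased_vcf(truth$snps, file.path(dir, "truth_snps.vcf"),
                   sample = "truth")
  utils::write.table(truth$svs, file.path(dir, "truth_svs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(truth$inversions, file.path(dir, "truth_inversions.bed"))
  invisible(dir)
}
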