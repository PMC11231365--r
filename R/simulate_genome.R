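#' Simulate a diploid genome with truth-annotated variants
#'
#' Builds a random reference genome plus two haplotypes carrying hetSNPs,
#' structural variants (deletions/insertions of at least 50 bp) and,
#' optionally, inversions. All coordinates are 0-based half-open on the
#' reference. The returned object is the ground truth against which every
#' downstream stage of the pipeline can be evaluated.
#'
#' @param n_chroms number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length length of each chromosome in bp (scalar or vector;
#'   minimum 10 kb).
#' @param snp_rate per-bp probability of a hetSNP.
#' @param sv_rate per-bp probability of an SV event (DEL/INS, >= 50 bp).
#' @param inversion_spec optional list of inversions, each a list or vector
#'   with elements `chrom`, `start`, `end`, `genotype` where genotype is one
#'   of `"HOM"`, `"HET-HP1"`, `"HET-HP2"` (`"HET"` is taken as `"HET-HP1"`).
#'   Overlapping inversions are rejected.
#' @param sv_length_range range of SV lengths in bp (minimum 50).
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return an object of class `diploid_truth`: a list with `reference`
#'   (named character vector), `chrom_lengths`, `snps` (chrom, pos, ref,
#'   alt, hp1, hp2 alleles), `svs` (chrom, sv_id, pos, type, length,
#'   genotype, seq) and `inversions` (chrom, start, end, genotype).
#' @export
simulate_diploid_genome <- function(n_chroms = 2, chrom_length = 2e6,
                                    snp_rate = 1e-3, sv_rate = 0,
                                    inversion_spec = NULL,
                                    sv_length_range = c(50, 300),
                                    seed = 1) {
  stopifnot(n_chroms >= 1, all(chrom_length >= 1e4),
            snp_rate >= 0, sv_rate >= 0, sv_length_range[1] >= 50)
  chrom_lengths <- rep_len(as.integer(chrom_length), n_chroms)
  names(chrom_lengths) <- paste0("chr", seq_len(n_chroms))
  inv <- normalize_inversion_spec(inversion_spec, chrom_lengths)

  with_seed(seed, {
    reference <- stats::setNames(
      vapply(chrom_lengths, function(L) random_dna(1, L), character(1)),
      names(chrom_lengths))

    svs <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      simulate_chrom_svs(ch, chrom_lengths[[ch]], sv_rate, sv_length_range,
                         inv[inv$chrom == ch, , drop = FALSE])
    }))
    if (is.null(svs)) svs <- empty_svs_df()
    if (nrow(svs)) svs$sv_id <- sprintf("sv%04d", seq_len(nrow(svs)))

    snps <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      pos <- which(stats::runif(L) < snp_rate) - 1L
      if (!length(pos)) return(NULL)
      # keep SNPs clear of SV footprints so allele observations stay simple
      sv_ch <- svs[svs$chrom == ch, , drop = FALSE]
      if (nrow(sv_ch)) {
        bad <- IRanges::overlapsAny(
          IRanges::IRanges(pos + 1L, pos + 1L),
          IRanges::IRanges(sv_ch$pos + 1L - 50L,
                           sv_ch$pos + sv_ch$length + 50L))
        pos <- pos[!bad]
      }
      if (!length(pos)) return(NULL)
      ref <- substring(reference[[ch]], pos + 1L, pos + 1L)
      alt <- other_base(ref)
      alt_on_hp1 <- stats::runif(length(pos)) < 0.5
      data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                 hp1 = ifelse(alt_on_hp1, alt, ref),
                 hp2 = ifelse(alt_on_hp1, ref, alt),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(snps))
      snps <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         hp1 = character(0), hp2 = character(0),
                         stringsAsFactors = FALSE)

    structure(list(reference = reference, chrom_lengths = chrom_lengths,
                   snps = snps, svs = svs, inversions = inv),
              class = "diploid_truth")
  })
}

empty_svs_df <- function() {
  data.frame(chrom = character(0), sv_id = character(0), pos = integer(0),
             type = character(0), length = integer(0), genotype = character(0),
             seq = character(0), stringsAsFactors = FALSE)
}

normalize_inversion_spec <- function(inversion_spec, chrom_lengths) {
  if (is.null(inversion_spec) || !length(inversion_spec)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), genotype = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(inversion_spec)) {
    inv <- inversion_spec
  } else {
    inv <- do.call(rbind, lapply(inversion_spec, function(x) {
      x <- as.list(x)
      data.frame(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
                 end = as.integer(x[[3]]), genotype = as.character(x[[4]]),
                 stringsAsFactors = FALSE)
    }))
  }
  inv$genotype[inv$genotype == "HET"] <- "HET-HP1"
  stopifnot(all(inv$genotype %in% c("HOM", "HET-HP1", "HET-HP2")),
            all(inv$chrom %in% names(chrom_lengths)),
            all(inv$start >= 0), all(inv$start < inv$end),
            all(inv$end <= chrom_lengths[inv$chrom]))
  for (ch in unique(inv$chrom)) {
    x <- inv[inv$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)]))
      stop("overlapping inversions requested on ", ch)
  }
  inv[order(inv$chrom, inv$start), , drop = FALSE]
}

simulate_chrom_svs <- function(chrom, L, sv_rate, len_range, inv_ch) {
  n <- stats::rbinom(1, L, sv_rate)
  if (n == 0) return(NULL)
  margin <- 1e4
  forbidden <- IRanges::IRanges(integer(0), integer(0))
  if (nrow(inv_ch)) # keep SVs clear of inversion breakpoints
    forbidden <- IRanges::IRanges(
      c(inv_ch$start - 1000L, inv_ch$end - 1000L) + 1L,
      c(inv_ch$start + 1000L, inv_ch$end + 1000L) + 1L)
  out <- NULL
  taken <- IRanges::IRanges(integer(0), integer(0))
  tries <- 0
  while ((is.null(out) || nrow(out) < n) && tries < 50 * n) {
    tries <- tries + 1
    pos <- as.integer(stats::runif(1, margin, L - margin))
    len <- as.integer(stats::runif(1, len_range[1], len_range[2] + 1))
    span <- IRanges::IRanges(pos + 1L - 2000L, pos + len + 2000L)
    if (IRanges::overlapsAny(span, forbidden) ||
        IRanges::overlapsAny(span, taken)) next
    taken <- c(taken, span)
    type <- sample(c("DEL", "INS"), 1)
    rec <- data.frame(
      chrom = chrom, sv_id = NA_character_, pos = pos, type = type,
      length = len,
      genotype = sample(c("HOM", "HET-HP1", "HET-HP2"), 1),
      seq = if (type == "INS") random_dna(1, len) else "",
      stringsAsFactors = FALSE)
    out <- rbind(out, rec)
  }
  if (!is.null(out)) out <- out[order(out$pos), , drop = FALSE]
  out
}

# Which haplotypes carry a variant genotype label.
carriers <- function(genotype) {
  switch(genotype,
         "HOM" = c("HP1", "HP2"),
         "HET-HP1" = "HP1",
         "HET-HP2" = "HP2",
         stop("unknown genotype ", genotype))
}

#' Realize the sequence of one haplotype
#'
#' Applies the haplotype's SNP alleles, reverse-complements carried
#' inversion segments in place, and then applies DEL/INS edits, yielding the
#' actual haplotype chromosome sequence.
#'
#' @param truth a `diploid_truth` object.
#' @param chrom chromosome name.
#' @param hap `"HP1"` or `"HP2"`.
#' @return character scalar DNA sequence.
#' @export
haplotype_sequence <- function(truth, chrom, hap = c("HP1", "HP2")) {
  hap <- match.arg(hap)
  seq <- truth$reference[[chrom]]
  sn <- truth$snps[truth$snps$chrom == chrom, , drop = FALSE]
  if (nrow(sn)) {
    chars <- strsplit(seq, "")[[1]]
    chars[sn$pos + 1L] <- if (hap == "HP1") sn$hp1 else sn$hp2
    seq <- paste(chars, collapse = "")
  }
  inv <- truth$inversions[truth$inversions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(inv))) {
    if (!(hap %in% carriers(inv$genotype[i]))) next
    s <- inv$start[i]; e <- inv$end[i]
    seg <- substring(seq, s + 1L, e)
    seq <- paste0(substring(seq, 1L, s), revcomp(seg),
                  substring(seq, e + 1L))
  }
  sv <- truth$svs[truth$svs$chrom == chrom, , drop = FALSE]
  sv <- sv[order(-sv$pos), , drop = FALSE] # right-to-left keeps coords valid
  for (i in seq_len(nrow(sv))) {
    if (!(hap %in% carriers(sv$genotype[i]))) next
    p <- sv$pos[i]
    if (sv$type[i] == "DEL") {
      seq <- paste0(substring(seq, 1L, p),
                    substring(seq, p + sv$length[i] + 1L))
    } else {
      seq <- paste0(substring(seq, 1L, p), sv$seq[i],
                    substring(seq, p + 1L))
    }
  }
  seq
}

#' Truth phased variants for evaluation
#'
#' @param truth a `diploid_truth` object.
#' @return data frame of phased hetSNPs (chrom, pos, ref, alt, hp1, hp2).
#' @export
truth_phased_variants <- function(truth) {
  truth$snps
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat("Simulated diploid genome truth\n")
  cat(sprintf("  chromosomes: %d (%s bp)\n", length(x$chrom_lengths),
              paste(unique(x$chrom_lengths), collapse = "/")))
  cat(sprintf("  hetSNPs: %d   SVs: %d   inversions: %d\n",
              nrow(x$snps), nrow(x$svs), nrow(x$inversions)))
  invisible(x)
}
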