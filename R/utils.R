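#' @useDynLib strandhap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
NULL

#' Reverse-complement character DNA sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (sum(nchar(x)) > 1e5) # Biostrings pays off only on long sequences
    return(as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Levenshtein edit distance
#'
#' Unit-cost global edit distance between two strings.
#'
#' @param a,b character scalars.
#' @return integer distance.
#' @export
edit_distance <- function(a, b) {
  .edit_dist_cpp(as.character(a), as.character(b))
}

#' Best infix (semi-global) match of a pattern in a subject
#'
#' Aligns `pattern` end-to-end against the best-matching substring of
#' `subject` (free subject ends), unit costs. Used for barcode and linker
#' searches in read windows.
#'
#' @param pattern,subject character scalars.
#' @return list with `distance`, and the 1-based inclusive matched span
#'   `start`, `end` in `subject`.
#' @export
infix_edit <- function(pattern, subject) {
  r <- .infix_edit_cpp(as.character(pattern), as.character(subject))
  list(distance = r[[1]], start = r[[2]], end = r[[3]])
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Random DNA string(s).
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Substitute a base by a random different base.
other_base <- function(base) {
  bases <- c("A", "C", "G", "T")
  vapply(base, function(b) sample(setdiff(bases, b), 1L), character(1),
         USE.NAMES = FALSE)
}

# Autosome test used by QC: anything that is not a sex/mito contig.
is_autosome <- function(chrom,
                        exclude = c("chrX", "chrY", "X", "Y",
                                    "chrM", "MT", "chrMT", "M")) {
  !(chrom %in% exclude)
}

empty_variants_df <- function() {
  data.frame(chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             hp1 = character(0), hp2 = character(0),
             n_hp1 = integer(0), n_hp2 = integer(0),
             source = character(0), stringsAsFactors = FALSE)
}

empty_reads_df <- function() {
  data.frame(read_id = character(0), cell_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), mapq = integer(0),
             duplicate = logical(0), cigar = character(0),
             hap_true = character(0), stringsAsFactors = FALSE)
}
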