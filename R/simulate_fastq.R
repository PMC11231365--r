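#' Default 33-bp linker sequence
#'
#' The transposase adaptor sequence that flanks every insert; searched and
#' trimmed during demultiplexing.
#' @export
STRANDHAP_LINKER <- "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG"

#' Generate a well-separated random barcode set
#'
#' Greedy rejection sampling of random 24-nt barcodes with a minimum
#' pairwise Levenshtein distance, so that reads carrying up to
#' `floor((min_dist - 1) / 2)` edits are still uniquely assignable.
#'
#' @param n number of barcodes.
#' @param length barcode length in nt.
#' @param min_dist minimum pairwise edit distance.
#' @param seed integer seed.
#' @return character vector of barcodes, named `bc01`, `bc02`, ...
#' @export
generate_barcodes <- function(n, length = 24, min_dist = 12, seed = 1) {
  with_seed(seed, {
    out <- character(0)
    tries <- 0
    while (length(out) < n && tries < 20000L) {
      tries <- tries + 1
      cand <- random_dna(1, length)
      if (all(vapply(out, function(b) edit_distance(cand, b),
                     integer(1)) >= min_dist) &&
          all(vapply(out, function(b)
            edit_distance(cand, revcomp(b)), integer(1)) >= min_dist))
        out <- c(out, cand)
    }
    if (length(out) < n) stop("could not generate ", n,
                              " barcodes at min_dist ", min_dist)
    stats::setNames(out, sprintf("bc%02d", seq_len(n)))
  })
}

#' Combinatorial barcode table for a set of cells
#'
#' Assigns each cell a distinct (1st barcode, 2nd barcode) pair.
#'
#' @param cell_ids character vector of cell identifiers.
#' @param barcodes1,barcodes2 named barcode vectors
#'   (see [generate_barcodes()]).
#' @return data frame with cell_id, bc1_id, bc2_id, barcode1, barcode2.
#' @export
barcode_table <- function(cell_ids, barcodes1, barcodes2) {
  grid <- expand.grid(b1 = seq_along(barcodes1), b2 = seq_along(barcodes2))
  if (length(cell_ids) > nrow(grid))
    stop("not enough barcode combinations for ", length(cell_ids), " cells")
  grid <- grid[seq_along(cell_ids), , drop = FALSE]
  data.frame(cell_id = cell_ids,
             bc1_id = names(barcodes1)[grid$b1],
             bc2_id = names(barcodes2)[grid$b2],
             barcode1 = unname(barcodes1[grid$b1]),
             barcode2 = unname(barcodes2[grid$b2]),
             stringsAsFactors = FALSE)
}

# ref -> haplotype coordinate shift from carried SVs left of pos
hap_coord <- function(svs, hap, pos) {
  if (!nrow(svs)) return(pos)
  carr <- vapply(svs$genotype, function(g) hap %in% carriers(g), logical(1))
  svs <- svs[carr, , drop = FALSE]
  vapply(pos, function(p) {
    ins <- sum(svs$length[svs$type == "INS" & svs$pos < p])
    del <- sum(pmin(svs$length,
                    pmax(p - svs$pos, 0L))[svs$type == "DEL"])
    p + ins - del
  }, numeric(1))
}

#' Materialise the sequence of simulated reads
#'
#' Extracts each read's sequence from its haplotype of origin (SNP alleles,
#' inversions and SV edits applied); Watson reads are reverse-complemented
#' so the sequence is what the sequencer would report for that template
#' strand.
#'
#' @param truth a `diploid_truth`.
#' @param reads read data frame as produced by [simulate_cell_library()].
#' @return character vector of sequences, one per read row.
#' @export
read_sequences <- function(truth, reads) {
  out <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    sv <- truth$svs[truth$svs$chrom == ch, , drop = FALSE]
    for (hap in c("HP1", "HP2")) {
      ri <- which(reads$chrom == ch & reads$hap_true == hap)
      if (!length(ri)) next
      hseq <- haplotype_sequence(truth, ch, hap)
      s <- hap_coord(sv, hap, reads$start[ri])
      e <- hap_coord(sv, hap, reads$end[ri])
      seqs <- substring(hseq, s + 1, e)
      w <- reads$strand[ri] == "W"
      if (any(w)) seqs[w] <- revcomp(seqs[w])
      out[ri] <- seqs
    }
  }
  out
}

# Inject exactly k random unit edits (substitution/insertion/deletion).
inject_edits <- function(seq, k) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(k)) {
    op <- sample(c("sub", "ins", "del"), 1)
    p <- sample(length(chars), 1)
    if (op == "sub") chars[p] <- other_base(chars[p])
    else if (op == "ins") chars <- append(chars,
                                          sample(c("A", "C", "G", "T"), 1), p)
    else if (length(chars) > 1) chars <- chars[-p]
  }
  paste(chars, collapse = "")
}

apply_base_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  vapply(seq, function(s) {
    chars <- strsplit(s, "")[[1]]
    err <- stats::runif(length(chars)) < rate
    if (any(err)) chars[err] <- other_base(chars[err])
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write a multiplexed FASTQ for a simulated run
#'
#' Decorates every read with its cell's combinatorial barcodes and the
#' linker. Template-layout reads carry the forward 2nd barcode + linker at
#' the head and the reverse-complemented linker + 1st barcode at the tail;
#' non-template-layout reads are the reverse complement of that layout.
#' Barcode copies receive `barcode_error_edits` random edits each and
#' insert bases are perturbed at the configured base error rate. Truth
#' labels are carried in read names as
#' `read_id|chrom|start|end|strand|hap|layout`.
#'
#' @param run a `strand_run` (or a single `strand_cell` in a list).
#' @param barcodes barcode table from [barcode_table()]; pairs must be
#'   unique across cells.
#' @param path output FASTQ path.
#' @param linker linker sequence.
#' @param seed integer seed.
#' @return invisibly, the data frame of truth labels written.
#' @export
emit_multiplexed_fastq <- function(run, barcodes, path,
                                   linker = STRANDHAP_LINKER, seed = 1) {
  if (anyDuplicated(paste(barcodes$barcode1, barcodes$barcode2)))
    stop("duplicate barcode pair across cells")
  cells <- run$cells
  stopifnot(all(vapply(cells, function(x) x$cell_id, character(1)) %in%
                  barcodes$cell_id))
  truth <- run$truth
  with_seed(seed, {
    all_recs <- lapply(cells, function(cell) {
      bc <- barcodes[barcodes$cell_id == cell$cell_id, , drop = FALSE]
      reads <- cell$reads
      insert <- read_sequences(truth, reads)
      insert <- apply_base_errors(insert, cell$config$base_error_rate)
      k <- cell$config$barcode_error_edits
      n <- nrow(reads)
      head_bc <- vapply(rep(bc$barcode2, n), inject_edits, character(1),
                        k = k, USE.NAMES = FALSE)
      tail_bc <- vapply(rep(revcomp(bc$barcode1), n), inject_edits,
                        character(1), k = k, USE.NAMES = FALSE)
      seq <- paste0(head_bc, linker, insert, revcomp(linker), tail_bc)
      nt <- reads$layout == "N"
      seq[nt] <- revcomp(seq[nt])
      data.frame(name = sprintf("%s|%s|%d|%d|%s|%s|%s", reads$read_id,
                                reads$chrom, reads$start, reads$end,
                                reads$strand, reads$hap_true, reads$layout),
                 seq = seq, stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, all_recs)
    dna <- Biostrings::DNAStringSet(recs$seq)
    names(dna) <- recs$name
    quals <- Biostrings::BStringSet(strrep("I", nchar(recs$seq)))
    Biostrings::writeXStringSet(dna, path, format = "fastq",
                                qualities = quals)
    invisible(recs)
  })
}
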