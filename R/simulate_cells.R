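#' Configuration for a simulated single-cell strand-specific library
#'
#' @param n_reads reads to emit for the cell.
#' @param read_length_mean,read_length_sd lognormal insert length model (bp).
#'   The default mean mirrors typical Nanopore Strand-seq style fragment
#'   lengths (about 2.8 kb).
#' @param sce_rate expected sister-chromatid-exchange breakpoints per
#'   chromosome (Poisson).
#' @param background_rate probability that a read is emitted on the wrong
#'   strand (incomplete nascent-strand removal).
#' @param base_error_rate per-base substitution error probability, applied
#'   to observed alleles at polymorphic sites and to emitted sequences.
#' @param barcode_error_edits number of random edits injected into each
#'   barcode copy when writing multiplexed FASTQ.
#' @return a validated list of class `cell_sim_config`.
#' @export
cell_sim_config <- function(n_reads = 1000, read_length_mean = 2794,
                            read_length_sd = 1500, sce_rate = 0.2,
                            background_rate = 0, base_error_rate = 0,
                            barcode_error_edits = 0) {
  stopifnot(n_reads > 0,
            read_length_mean > 0, read_length_sd >= 0,
            sce_rate >= 0,
            background_rate >= 0, background_rate <= 1,
            base_error_rate >= 0, base_error_rate <= 1,
            barcode_error_edits >= 0)
  structure(list(n_reads = as.integer(n_reads),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 sce_rate = sce_rate,
                 background_rate = background_rate,
                 base_error_rate = base_error_rate,
                 barcode_error_edits = as.integer(barcode_error_edits)),
            class = "cell_sim_config")
}

#' Simulate one single-cell directional read library
#'
#' Emits reads in aligned representation (reference coordinates, strand,
#' CIGAR, observed alleles at hetSNP sites) with full truth labels. Strand
#' assignment follows the per-chromosome template-strand inheritance
#' pattern, is flipped at simulated SCE breakpoints and within inversion
#' intervals on carrier haplotypes, and a `background_rate` fraction of
#' reads is emitted on the opposite strand. On WC chromosomes one haplotype
#' is sequenced on the Crick strand and the other on the Watson strand.
#'
#' @param truth a `diploid_truth` object.
#' @param config a `cell_sim_config`.
#' @param patterns named character vector giving the inheritance pattern
#'   (`"WW"`, `"CC"` or `"WC"`) for every chromosome of `truth`.
#' @param cell_id cell identifier.
#' @param seed integer seed.
#' @return list of class `strand_cell` with elements `reads` (data frame:
#'   read_id, cell_id, chrom, start, end, strand, mapq, duplicate, cigar,
#'   hap_true, strand_true, layout), `alleles` (read_id, chrom, pos,
#'   allele), `sv_obs` (read_id, sv_id, carries), `patterns`,
#'   `wc_orientation` and `sce` (chrom, pos, hap).
#' @export
simulate_cell_library <- function(truth, config, patterns,
                                  cell_id = "cell01", seed = 1) {
  stopifnot(inherits(truth, "diploid_truth"),
            inherits(config, "cell_sim_config"))
  chroms <- names(truth$chrom_lengths)
  if (!all(chroms %in% names(patterns)))
    stop("inheritance pattern missing for chromosome(s): ",
         paste(setdiff(chroms, names(patterns)), collapse = ", "))
  stopifnot(all(patterns[chroms] %in% c("WW", "CC", "WC")))
  with_seed(seed, {
    sim_cell_impl(truth, config, patterns[chroms], cell_id)
  })
}

sim_cell_impl <- function(truth, config, patterns, cell_id) {
  chroms <- names(truth$chrom_lengths)
  lens <- truth$chrom_lengths
  n_per <- stats::rmultinom(1, config$n_reads, lens / sum(lens))[, 1]

  # WC orientation: which haplotype is on the Crick strand
  wc_orientation <- stats::setNames(
    sample(c("HP1", "HP2"), length(chroms), replace = TRUE), chroms)

  # SCE breakpoints: Poisson per chromosome, uniform position, one haplotype
  sce <- do.call(rbind, lapply(chroms, function(ch) {
    k <- stats::rpois(1, config$sce_rate)
    if (!k) return(NULL)
    data.frame(chrom = ch,
               pos = as.integer(stats::runif(k, 0, lens[[ch]])),
               hap = sample(c("HP1", "HP2"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(sce))
    sce <- data.frame(chrom = character(0), pos = integer(0),
                      hap = character(0), stringsAsFactors = FALSE)

  sdlog <- sqrt(log(1 + (config$read_length_sd / config$read_length_mean)^2))
  meanlog <- log(config$read_length_mean) - sdlog^2 / 2

  pieces <- lapply(seq_along(chroms), function(ci) {
    ch <- chroms[ci]; L <- lens[[ch]]; n <- n_per[ci]
    if (!n) return(NULL)
    len <- pmin(pmax(as.integer(stats::rlnorm(n, meanlog, sdlog)), 200L),
                as.integer(L / 2))
    start <- as.integer(stats::runif(n, 0, L - len))
    end <- start + len
    hap <- sample(c("HP1", "HP2"), n, replace = TRUE)
    mid <- (start + end) %/% 2

    strand <- template_strand(patterns[[ch]], hap, wc_orientation[[ch]])
    # SCE flips on the affected haplotype downstream of the breakpoint
    sce_ch <- sce[sce$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(sce_ch))) {
      flip <- hap == sce_ch$hap[k] & mid >= sce_ch$pos[k]
      strand[flip] <- flip_strand(strand[flip])
    }
    # inversions flip carried haplotypes inside the interval
    inv_ch <- truth$inversions[truth$inversions$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(inv_ch))) {
      carr <- carriers(inv_ch$genotype[k])
      flip <- hap %in% carr & mid >= inv_ch$start[k] & mid < inv_ch$end[k]
      strand[flip] <- flip_strand(strand[flip])
    }
    strand_true <- strand
    bg <- stats::runif(n) < config$background_rate
    strand[bg] <- flip_strand(strand[bg])

    data.frame(cell_id = cell_id, chrom = ch, start = start, end = end,
               strand = strand, mapq = 60L, duplicate = FALSE,
               hap_true = hap, strand_true = strand_true,
               stringsAsFactors = FALSE)
  })
  reads <- do.call(rbind, pieces)
  if (is.null(reads)) stop("no reads simulated")
  reads$read_id <- sprintf("%s.r%06d", cell_id, seq_len(nrow(reads)))
  reads$layout <- sample(c("T", "N"), nrow(reads), replace = TRUE)
  reads$cigar <- read_cigars(truth, reads)
  rownames(reads) <- NULL

  alleles <- observe_alleles(truth, reads, config$base_error_rate)
  sv_obs <- observe_svs(truth, reads)

  structure(list(reads = reads[, c("read_id", "cell_id", "chrom", "start",
                                   "end", "strand", "mapq", "duplicate",
                                   "cigar", "hap_true", "strand_true",
                                   "layout")],
                 alleles = alleles, sv_obs = sv_obs,
                 patterns = patterns, wc_orientation = wc_orientation,
                 sce = sce, config = config, cell_id = cell_id),
            class = "strand_cell")
}

template_strand <- function(pattern, hap, crick_hap) {
  n <- length(hap)
  switch(pattern,
         "WW" = rep("W", n),
         "CC" = rep("C", n),
         "WC" = ifelse(hap == crick_hap, "C", "W"))
}

flip_strand <- function(s) ifelse(s == "C", "W", "C")

# CIGAR of each read against the reference: matches interrupted by the
# DEL/INS events its haplotype carries fully inside the aligned span.
read_cigars <- function(truth, reads) {
  cig <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    ri <- which(reads$chrom == ch)
    sv <- truth$svs[truth$svs$chrom == ch, , drop = FALSE]
    if (!nrow(sv)) {
      cig[ri] <- paste0(reads$end[ri] - reads$start[ri], "M")
      next
    }
    for (i in ri) {
      s <- reads$start[i]; e <- reads$end[i]; h <- reads$hap_true[i]
      keep <- sv$pos >= s + 50L & (sv$pos + ifelse(sv$type == "DEL",
                                                   sv$length, 0L)) <= e - 50L
      keep <- keep & vapply(sv$genotype, function(g) h %in% carriers(g),
                            logical(1))
      svi <- sv[keep, , drop = FALSE]
      if (!nrow(svi)) { cig[i] <- paste0(e - s, "M"); next }
      svi <- svi[order(svi$pos), , drop = FALSE]
      ops <- character(0); cur <- s
      for (k in seq_len(nrow(svi))) {
        ops <- c(ops, paste0(svi$pos[k] - cur, "M"),
                 paste0(svi$length[k], if (svi$type[k] == "DEL") "D" else "I"))
        cur <- svi$pos[k] + if (svi$type[k] == "DEL") svi$length[k] else 0L
      }
      ops <- c(ops, paste0(e - cur, "M"))
      cig[i] <- paste(ops[ops != "0M"], collapse = "")
    }
  }
  cig
}

# Observed allele at every truth hetSNP covered by each read, with
# substitution errors at the configured per-base rate.
observe_alleles <- function(truth, reads, base_error_rate) {
  out <- lapply(unique(reads$chrom), function(ch) {
    sn <- truth$snps[truth$snps$chrom == ch, , drop = FALSE]
    rd <- reads[reads$chrom == ch, , drop = FALSE]
    if (!nrow(sn) || !nrow(rd)) return(NULL)
    sn <- sn[order(sn$pos), , drop = FALSE]
    i1 <- findInterval(rd$start - 0.5, sn$pos) + 1L
    i2 <- findInterval(rd$end - 1 + 0.5, sn$pos)
    n_each <- pmax(i2 - i1 + 1L, 0L)
    keep <- n_each > 0L
    if (!any(keep)) return(NULL)
    idx <- unlist(lapply(which(keep), function(j) seq(i1[j], i2[j])))
    rid <- rep(rd$read_id[keep], n_each[keep])
    hap <- rep(rd$hap_true[keep], n_each[keep])
    allele <- ifelse(hap == "HP1", sn$hp1[idx], sn$hp2[idx])
    if (base_error_rate > 0) {
      err <- stats::runif(length(allele)) < base_error_rate
      if (any(err)) allele[err] <- other_base(allele[err])
    }
    data.frame(read_id = rid, chrom = ch, pos = sn$pos[idx],
               allele = allele, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(read_id = character(0), chrom = character(0),
                      pos = integer(0), allele = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# For every truth SV whose locus a read fully spans (50 bp flanks), record
# whether the read's haplotype carries the SV (support) or not (oppose).
observe_svs <- function(truth, reads) {
  out <- lapply(unique(reads$chrom), function(ch) {
    sv <- truth$svs[truth$svs$chrom == ch, , drop = FALSE]
    rd <- reads[reads$chrom == ch, , drop = FALSE]
    if (!nrow(sv) || !nrow(rd)) return(NULL)
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(rd$start + 1L, rd$end),
      IRanges::IRanges(sv$pos + 1L - 50L,
                       sv$pos + ifelse(sv$type == "DEL", sv$length, 0L) + 50L),
      type = "any")
    if (!length(hit)) return(NULL)
    q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
    spans <- rd$start[q] + 50L <= sv$pos[s] &
      rd$end[q] - 50L >= sv$pos[s] + ifelse(sv$type[s] == "DEL",
                                            sv$length[s], 0L)
    q <- q[spans]; s <- s[spans]
    if (!length(q)) return(NULL)
    carr <- vapply(seq_along(q), function(k) {
      rd$hap_true[q[k]] %in% carriers(sv$genotype[s[k]])
    }, logical(1))
    data.frame(read_id = rd$read_id[q], sv_id = sv$sv_id[s],
               carries = carr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(read_id = character(0), sv_id = character(0),
                      carries = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a multi-cell strand-specific sequencing run
#'
#' Draws an inheritance pattern per (cell, chromosome) — each homolog's
#' template strand is Watson or Crick independently, giving WW/CC/WC at
#' 1/4, 1/4, 1/2 — and simulates every cell's library.
#'
#' @param truth a `diploid_truth` object.
#' @param n_cells number of cells.
#' @param config a `cell_sim_config` shared by all cells.
#' @param patterns `"random"` (default) or a cells-by-chromosomes character
#'   matrix of fixed patterns.
#' @param seed integer seed.
#' @return list of class `strand_run`: `truth`, `cells` (list of
#'   `strand_cell`), pooled `reads`, `alleles`, `sv_obs`, and the
#'   `patterns` and `wc_orientation` matrices.
#' @export
simulate_strand_run <- function(truth, n_cells, config,
                                patterns = "random", seed = 1) {
  chroms <- names(truth$chrom_lengths)
  cell_ids <- sprintf("cell%03d", seq_len(n_cells))
  with_seed(seed, {
    if (identical(patterns, "random")) {
      patterns <- matrix(
        sample(c("WW", "CC", "WC"), n_cells * length(chroms),
               replace = TRUE, prob = c(0.25, 0.25, 0.5)),
        nrow = n_cells, dimnames = list(cell_ids, chroms))
    }
    stopifnot(is.matrix(patterns), nrow(patterns) == n_cells)
    cell_seeds <- sample.int(.Machine$integer.max, n_cells)
    cells <- lapply(seq_len(n_cells), function(i) {
      pats <- stats::setNames(patterns[i, ], colnames(patterns))
      simulate_cell_library(truth, config, pats,
                            cell_id = cell_ids[i], seed = cell_seeds[i])
    })
    names(cells) <- cell_ids
    run <- list(truth = truth, cells = cells,
                reads = do.call(rbind, lapply(cells, `[[`, "reads")),
                alleles = do.call(rbind, lapply(cells, `[[`, "alleles")),
                sv_obs = do.call(rbind, lapply(cells, `[[`, "sv_obs")),
                patterns = patterns,
                wc_orientation = do.call(rbind, lapply(cells, `[[`,
                                                       "wc_orientation")))
    rownames(run$reads) <- NULL
    rownames(run$alleles) <- NULL
    rownames(run$sv_obs) <- NULL
    class(run) <- "strand_run"
    run
  })
}

#' @export
print.strand_run <- function(x, ...) {
  cat(sprintf("Simulated strand-specific run: %d cells, %d reads, %s\n",
              length(x$cells), nrow(x$reads),
              paste(names(x$truth$chrom_lengths), collapse = ",")))
  invisible(x)
}
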