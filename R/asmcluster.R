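#' Cut a simulated genome into assembly-like contigs
#'
#' Splits each chromosome into contigs of roughly `target_len` bp and
#' assigns each a random orientation, emulating a squashed de novo
#' assembly whose contigs may be reverse-complemented relative to the
#' reference.
#'
#' @param truth a `diploid_truth` object.
#' @param target_len approximate contig length (bp).
#' @param seed integer seed.
#' @return data frame: contig_id, chrom, start, end, orientation
#'   (`"+"`/`"-"`), length.
#' @export
simulate_contigs <- function(truth, target_len = 2e5, seed = 1) {
  with_seed(seed, {
    out <- lapply(names(truth$chrom_lengths), function(ch) {
      L <- truth$chrom_lengths[[ch]]
      n <- max(1L, as.integer(round(L / target_len)))
      cuts <- as.integer(round(seq(0, L, length.out = n + 1)))
      data.frame(chrom = ch, start = cuts[-(n + 1)], end = cuts[-1],
                 orientation = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out$contig_id <- sprintf("ctg%03d", seq_len(nrow(out)))
    out$length <- out$end - out$start
    rownames(out) <- NULL
    out[, c("contig_id", "chrom", "start", "end", "orientation", "length")]
  })
}

#' Contig-by-cell strand matrix
#'
#' Assigns reads to contigs (by midpoint), flips read strands on
#' reverse-oriented contigs, and computes the per-(contig, cell) value
#' `(crick - watson) / (crick + watson)`. Contigs shorter than
#' `min_contig_len` are filtered out; entries without reads are imputed
#' as 0 and masked via the returned count matrix.
#'
#' @param reads alignment data frame (duplicates flagged are excluded).
#' @param contigs contig table ([simulate_contigs()] or equivalent).
#' @param min_contig_len minimum contig length kept (default 100 kb).
#' @return list with `values` (contigs x cells matrix), `counts` (read
#'   counts) and the filtered `contigs` table.
#' @export
contig_strand_matrix <- function(reads, contigs, min_contig_len = 1e5) {
  contigs <- contigs[contigs$end - contigs$start >= min_contig_len, ,
                     drop = FALSE]
  if (!nrow(contigs))
    stop("no contigs of at least ",
         format(min_contig_len, scientific = FALSE), " bp")
  if ("duplicate" %in% names(reads))
    reads <- reads[!reads$duplicate, , drop = FALSE]
  cells <- sort(unique(reads$cell_id))
  values <- counts <- matrix(
    0, nrow(contigs), length(cells),
    dimnames = list(contigs$contig_id, cells))
  for (k in seq_len(nrow(contigs))) {
    ct <- contigs[k, ]
    mid <- (reads$start + reads$end) %/% 2L
    sel <- reads$chrom == ct$chrom & mid >= ct$start & mid < ct$end
    if (!any(sel)) next
    strand <- reads$strand[sel]
    if (ct$orientation == "-") strand <- flip_strand(strand)
    tab <- table(factor(reads$cell_id[sel], levels = cells),
                 factor(strand, levels = c("C", "W")))
    tot <- tab[, "C"] + tab[, "W"]
    counts[k, ] <- tot
    values[k, ] <- ifelse(tot > 0, (tab[, "C"] - tab[, "W"]) / tot, 0)
  }
  list(values = values, counts = counts, contigs = contigs)
}

#' Cluster contigs into chromosome-scale groups
#'
#' Complete-linkage agglomerative clustering (Euclidean distance) of the
#' absolute strand matrix rows; the absolute value makes the grouping
#' invariant to contig orientation and to a global Crick/Watson relabeling
#' of any cell.
#'
#' @param mat a strand matrix from [contig_strand_matrix()].
#' @param n_clusters number of clusters (30 for a human-scale assembly;
#'   simulations use the true chromosome count).
#' @return named integer vector of cluster assignments per contig.
#' @export
cluster_contigs <- function(mat, n_clusters = 30) {
  v <- abs(mat$values)
  if (n_clusters > nrow(v))
    stop("n_clusters exceeds the number of contigs")
  hc <- stats::hclust(stats::dist(v), method = "complete")
  stats::cutree(hc, k = n_clusters)
}

#' Split a contig cluster into orientation sub-clusters
#'
#' Within one (chromosome) cluster, contigs in opposite reference
#' orientations have anti-correlated signed strand profiles across WW/CC
#' cells. Each contig is assigned by the sign of the inner product of its
#' signed row with a reference row (the cluster's highest-signal contig),
#' so a cluster of uniformly oriented contigs stays in one sub-cluster.
#'
#' @param mat strand matrix ([contig_strand_matrix()]).
#' @param contig_ids contigs of one cluster.
#' @return list with `sub1` (reference-orientation contigs) and `sub2`.
#' @export
split_orientation <- function(mat, contig_ids) {
  v <- mat$values[contig_ids, , drop = FALSE]
  if (nrow(v) == 1)
    return(list(sub1 = contig_ids, sub2 = character(0)))
  ref <- v[which.max(rowSums(abs(v))), ]
  proj <- as.vector(v %*% ref)
  list(sub1 = contig_ids[proj >= 0], sub2 = contig_ids[proj < 0])
}

#' Concatenate a cluster into one scaffold sequence
#'
#' Reverse-complements the contigs of `sub2` and concatenates all contigs
#' with `gap` N bases between them, recording a coordinate map for lifting
#' positions back to contigs.
#'
#' @param contig_seqs named character vector of contig sequences.
#' @param sub1,sub2 contig id vectors from [split_orientation()].
#' @param gap gap size in bp (default 1000).
#' @return list with `sequence` and `map` (contig_id, orientation,
#'   offset, length; offsets 0-based on the cluster sequence).
#' @export
build_cluster_sequence <- function(contig_seqs, sub1, sub2, gap = 1000) {
  ids <- c(sub1, sub2)
  ori <- c(rep("+", length(sub1)), rep("-", length(sub2)))
  seqs <- contig_seqs[ids]
  seqs[ori == "-"] <- revcomp(seqs[ori == "-"])
  lens <- nchar(seqs)
  offsets <- cumsum(c(0, (lens + gap)[-length(lens)]))
  list(sequence = paste(seqs, collapse = strrep("N", gap)),
       map = data.frame(contig_id = ids, orientation = ori,
                        offset = as.integer(offsets),
                        length = as.integer(lens),
                        stringsAsFactors = FALSE))
}

#' Lift cluster coordinates back to contig coordinates
#'
#' @param pos 0-based positions on the cluster sequence.
#' @param map coordinate map from [build_cluster_sequence()].
#' @return data frame with contig_id, contig position (0-based) and
#'   orientation; positions falling into gaps yield NA.
#' @export
lift_cluster_to_contig <- function(pos, map) {
  idx <- findInterval(pos, map$offset)
  ok <- idx >= 1 & pos < map$offset[idx] + map$length[idx]
  idx[!ok] <- NA
  within <- pos - map$offset[idx]
  cpos <- ifelse(map$orientation[idx] == "-",
                 map$length[idx] - 1L - within, within)
  data.frame(contig_id = map$contig_id[idx],
             pos = as.integer(cpos),
             orientation = map$orientation[idx],
             stringsAsFactors = FALSE)
}

#' Lift cluster-based variants to reference chromosome coordinates
#'
#' Positions are lifted cluster -> contig -> reference through the
#' coordinate map and the contig-to-reference placements; alleles are
#' complemented when the net orientation is reverse. Variants on contigs
#' without a placement are flagged unmapped.
#'
#' @param variants data frame with `pos` (cluster coordinates) and allele
#'   columns `ref`, `alt`, `hp1`, `hp2` (any subset present is handled).
#' @param map coordinate map from [build_cluster_sequence()].
#' @param placements contig-to-reference alignments (contig_id, chrom,
#'   start, strand) with full-contig collinear placement.
#' @return `variants` with `chrom`, lifted `pos` and a `mapped` flag.
#' @export
lift_variants <- function(variants, map, placements) {
  lifted <- lift_cluster_to_contig(variants$pos, map)
  pl <- placements[match(lifted$contig_id, placements$contig_id), ,
                   drop = FALSE]
  clen <- map$length[match(lifted$contig_id, map$contig_id)]
  mapped <- !is.na(lifted$contig_id) & !is.na(pl$chrom)
  # position depends on the placement strand alone; the allele must be
  # complemented when the net cluster->reference orientation is reverse
  net_rev <- xor(lifted$orientation == "-", pl$strand == "-")
  ref_pos <- ifelse(pl$strand == "-",
                    pl$start + clen - 1L - lifted$pos,
                    pl$start + lifted$pos)
  variants$chrom <- ifelse(mapped, pl$chrom, NA_character_)
  variants$pos <- ifelse(mapped, as.integer(ref_pos), NA_integer_)
  flip <- mapped & net_rev
  for (col in intersect(c("ref", "alt", "hp1", "hp2"), names(variants)))
    variants[[col]][flip] <- revcomp(variants[[col]][flip])
  variants$mapped <- mapped
  variants
}

#' Strand-based clustering of an assembly, end to end
#'
#' Builds the contig strand matrix, clusters contigs into chromosome
#' groups and splits each group into orientation sub-clusters.
#'
#' @param reads alignment data frame (reads mapped to the reference in
#'   simulation, re-assigned to contigs internally).
#' @param contigs contig table.
#' @param n_clusters number of chromosome clusters.
#' @param min_contig_len minimum contig length (default 100 kb).
#' @return list with `matrix`, `clusters` (per contig) and
#'   `subclusters` (list per cluster with `sub1`/`sub2`).
#' @export
cluster_assembly <- function(reads, contigs, n_clusters,
                             min_contig_len = 1e5) {
  mat <- contig_strand_matrix(reads, contigs,
                              min_contig_len = min_contig_len)
  cl <- cluster_contigs(mat, n_clusters)
  subs <- lapply(sort(unique(cl)), function(g) {
    split_orientation(mat, names(cl)[cl == g])
  })
  names(subs) <- as.character(sort(unique(cl)))
  list(matrix = mat, clusters = cl, subclusters = subs)
}
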