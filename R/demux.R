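#' Find the best barcode hit in a read window
#'
#' Searches every barcode of a set, in forward and reverse-complement
#' orientation, against a window by semi-global Levenshtein alignment and
#' keeps the minimal-distance hit. Hits above `max_edit` are rejected. If
#' two *different* barcodes tie at the minimal distance the hit is flagged
#' ambiguous (callers discard such reads); a forward/reverse tie of the
#' same barcode resolves to forward.
#'
#' @param window character scalar (up to 200 bp read window).
#' @param barcode_set named character vector of barcodes.
#' @param max_edit maximum accepted edit distance (default 5).
#' @return `NULL` if no barcode is within `max_edit`; otherwise a list with
#'   `barcode_id`, `orientation` (`"forward"`/`"reverse"`),
#'   `edit_distance`, matched span `start`,`end` (1-based in `window`) and
#'   a `tie` flag.
#' @export
match_barcode <- function(window, barcode_set, max_edit = 5) {
  if (!length(barcode_set)) stop("empty barcode set")
  stopifnot(nchar(window) >= 1)
  ids <- names(barcode_set)
  if (is.null(ids)) ids <- sprintf("bc%02d", seq_along(barcode_set))
  best <- NULL
  for (i in seq_along(barcode_set)) {
    for (ori in c("forward", "reverse")) {
      pat <- if (ori == "forward") barcode_set[[i]] else
        revcomp(barcode_set[[i]])
      h <- infix_edit(pat, window)
      if (is.null(best) || h$distance < best$edit_distance) {
        best <- list(barcode_id = ids[i], orientation = ori,
                     edit_distance = h$distance, start = h$start,
                     end = h$end, tie = FALSE)
      } else if (h$distance == best$edit_distance &&
                 ids[i] != best$barcode_id) {
        best$tie <- TRUE
      }
    }
  }
  if (is.null(best) || best$edit_distance > max_edit) return(NULL)
  best
}

#' Classify read orientation from barcode hit evidence
#'
#' A template-strand read carries a forward 2nd barcode at its head and a
#' reverse 1st barcode at its tail; a non-template read carries a forward
#' 1st barcode at the head and a reverse 2nd barcode at the tail. Any other
#' combination of evidence (missing hits, ambiguous ties, or both layouts
#' at once) is ambiguous.
#'
#' @param head_hit1,head_hit2 best accepted hits of the 1st/2nd barcode set
#'   in the head window (`NULL` if none).
#' @param tail_hit1,tail_hit2 same for the tail window.
#' @return list with `class` (`"template"`, `"nontemplate"` or
#'   `"ambiguous"`) and, when classified, `bc1_id` and `bc2_id`.
#' @export
classify_orientation <- function(head_hit1, head_hit2,
                                 tail_hit1, tail_hit2) {
  ok <- function(h, ori) !is.null(h) && !isTRUE(h$tie) &&
    h$orientation == ori
  is_template <- ok(head_hit2, "forward") && ok(tail_hit1, "reverse")
  is_nontemplate <- ok(head_hit1, "forward") && ok(tail_hit2, "reverse")
  if (is_template && !is_nontemplate)
    return(list(class = "template", bc1_id = tail_hit1$barcode_id,
                bc2_id = head_hit2$barcode_id))
  if (is_nontemplate && !is_template)
    return(list(class = "nontemplate", bc1_id = head_hit1$barcode_id,
                bc2_id = tail_hit2$barcode_id))
  list(class = "ambiguous")
}

#' Trim linkers and reject chimeric reads
#'
#' On a template-orientation read with barcodes already removed, the linker
#' is searched within the first `search_window` bp (forward) and its
#' reverse complement within the last `search_window` bp, at edit distance
#' `max_edit`. Reads lacking either linker are discarded. After trimming,
#' a full-length scan for a remaining internal linker copy (either
#' orientation, same edit threshold) rejects the read as a chimera.
#'
#' @param seq character scalar sequence.
#' @param qual optional quality string of the same length.
#' @param linker linker sequence.
#' @param max_edit maximum linker edit distance (default 8).
#' @param search_window bp searched at each end (default 40).
#' @return list with `status` (`"ok"`, `"no-linker"` or `"chimera"`) and,
#'   when ok, the trimmed `sequence` (and `quality`).
#' @export
trim_and_dechimera <- function(seq, qual = NULL,
                               linker = STRANDHAP_LINKER,
                               max_edit = 8, search_window = 40) {
  n <- nchar(seq)
  head_win <- substr(seq, 1, min(search_window, n))
  tail_off <- max(n - search_window, 0)
  tail_win <- substr(seq, tail_off + 1, n)
  h <- infix_edit(linker, head_win)
  t <- infix_edit(revcomp(linker), tail_win)
  if (h$distance > max_edit || t$distance > max_edit)
    return(list(status = "no-linker"))
  from <- h$end + 1
  to <- tail_off + t$start - 1
  if (to < from) return(list(status = "no-linker"))
  trimmed <- substr(seq, from, to)
  fwd <- infix_edit(linker, trimmed)
  rev <- infix_edit(revcomp(linker), trimmed)
  if (min(fwd$distance, rev$distance) <= max_edit)
    return(list(status = "chimera"))
  out <- list(status = "ok", sequence = trimmed)
  if (!is.null(qual)) out$quality <- substr(qual, from, to)
  out
}

#' Demultiplex a multiplexed FASTQ into per-cell reads
#'
#' For every read, barcode hits are computed on head and tail windows of at
#' most 200 bp (never more than half the read), the read is classified as
#' template or non-template and normalized to template orientation,
#' barcodes are removed, linkers trimmed and chimeras rejected, and the
#' read is assigned to the cell identified by its (1st, 2nd) barcode
#' combination.
#'
#' @param fastq path to the multiplexed FASTQ file.
#' @param barcodes barcode table (see [barcode_table()]).
#' @param linker linker sequence.
#' @param max_bc_edit maximum barcode edit distance (default 5).
#' @param max_linker_edit maximum linker edit distance (default 8).
#' @param outdir optional directory: per-cell FASTQ files and a summary TSV
#'   are written there.
#' @return list with `reads` (data frame: read name, status, cell_id,
#'   orientation, trimmed sequence/quality) and `summary` (assigned /
#'   ambiguous / discarded counts; their sum equals the input count).
#' @export
demultiplex_run <- function(fastq, barcodes, linker = STRANDHAP_LINKER,
                            max_bc_edit = 5, max_linker_edit = 8,
                            outdir = NULL) {
  dna <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                      with.qualities = TRUE)
  seqs <- as.character(dna)
  quals <- as.character(S4Vectors::mcols(dna)$qualities)
  nm <- names(dna)
  set1 <- stats::setNames(barcodes$barcode1, barcodes$bc1_id)
  set1 <- set1[!duplicated(names(set1))]
  set2 <- stats::setNames(barcodes$barcode2, barcodes$bc2_id)
  set2 <- set2[!duplicated(names(set2))]
  pair_key <- paste(barcodes$bc1_id, barcodes$bc2_id)
  n <- length(seqs)
  status <- character(n); cell <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  out_seq <- rep(NA_character_, n); out_qual <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    s <- seqs[i]; q <- quals[i]
    L <- nchar(s)
    w <- min(200L, L %/% 2L)
    if (w < 1L) { status[i] <- "ambiguous"; next }
    head_win <- substr(s, 1, w)
    tail_win <- substr(s, L - w + 1, L)
    cls <- classify_orientation(
      match_barcode(head_win, set1, max_bc_edit),
      match_barcode(head_win, set2, max_bc_edit),
      match_barcode(tail_win, set1, max_bc_edit),
      match_barcode(tail_win, set2, max_bc_edit))
    if (cls$class == "ambiguous") { status[i] <- "ambiguous"; next }
    key <- paste(cls$bc1_id, cls$bc2_id)
    j <- match(key, pair_key)
    if (is.na(j)) { status[i] <- "ambiguous"; next }
    if (cls$class == "nontemplate") {
      s <- revcomp(s)
      q <- paste(rev(strsplit(q, "")[[1]]), collapse = "")
    }
    # barcode spans on the normalized (template-layout) read
    h2 <- match_barcode(substr(s, 1, w), set2, max_bc_edit)
    t1 <- match_barcode(substr(s, L - w + 1, L), set1, max_bc_edit)
    if (is.null(h2) || is.null(t1)) { status[i] <- "ambiguous"; next }
    from <- h2$end + 1
    to <- L - w + t1$start - 1
    if (to < from) { status[i] <- "no-linker"; next }
    tr <- trim_and_dechimera(substr(s, from, to), substr(q, from, to),
                             linker = linker, max_edit = max_linker_edit)
    if (tr$status != "ok") { status[i] <- tr$status; next }
    status[i] <- "assigned"
    cell[i] <- barcodes$cell_id[j]
    orientation[i] <- cls$class
    out_seq[i] <- tr$sequence
    out_qual[i] <- tr$quality
  }

  reads <- data.frame(name = nm, status = status, cell_id = cell,
                      orientation = orientation, sequence = out_seq,
                      quality = out_qual, stringsAsFactors = FALSE)
  summary <- list(
    input = n,
    assigned = sum(status == "assigned"),
    ambiguous = sum(status == "ambiguous"),
    discarded = sum(status %in% c("no-linker", "chimera")),
    no_linker = sum(status == "no-linker"),
    chimera = sum(status == "chimera"))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (cid in unique(stats::na.omit(cell))) {
      sel <- which(!is.na(cell) & cell == cid)
      dna_out <- Biostrings::DNAStringSet(out_seq[sel])
      names(dna_out) <- nm[sel]
      Biostrings::writeXStringSet(
        dna_out, file.path(outdir, paste0(cid, ".fastq")),
        format = "fastq",
        qualities = Biostrings::BStringSet(out_qual[sel]))
    }
    utils::write.table(
      data.frame(metric = names(summary), value = unlist(summary)),
      file.path(outdir, "demux_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, summary = summary)
}
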