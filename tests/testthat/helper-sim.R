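# Shared fixtures, built once per test session.
sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = sim_cache))
    assign(key, force(expr), envir = sim_cache)
  get(key, envir = sim_cache)
}

small_truth <- function() {
  cached("small_truth",
         simulate_diploid_genome(2, 2e5, snp_rate = 1e-3, seed = 101))
}

small_run <- function() {
  cached("small_run", simulate_strand_run(
    small_truth(), 20, cell_sim_config(n_reads = 400, sce_rate = 0),
    seed = 102))
}

# brute-force semi-global edit distance: min over all substrings
brute_infix <- function(pattern, subject) {
  n <- nchar(subject)
  best <- nchar(pattern) # empty substring alignment
  for (i in seq_len(n)) {
    subs <- substring(subject, i, i:n)
    best <- min(best, utils::adist(pattern, subs))
  }
  best
}

# brute-force O(n^2) transitive closure of the duplicate relation
brute_duplicate_groups <- function(reads, edge_tol = 20) {
  n <- nrow(reads)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- i != j &&
      reads$cell_id[i] == reads$cell_id[j] &&
      reads$chrom[i] == reads$chrom[j] &&
      reads$strand[i] == reads$strand[j] &&
      abs(reads$start[i] - reads$start[j]) < edge_tol &&
      abs(reads$end[i] - reads$end[j]) < edge_tol
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# random alignment data frame for duplicate-marking tests
random_reads <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    cell_id = "cellA",
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = as.integer(sample(0:400, n, replace = TRUE)),
    mapq = as.integer(sample(30:60, n, replace = TRUE)),
    strand = sample(c("C", "W"), n, replace = TRUE),
    stringsAsFactors = FALSE) |>
    transform(end = start + as.integer(sample(100:150, n, replace = TRUE)))
}

# truth labels parsed back out of multiplexed FASTQ read names
parse_truth_names <- function(names) {
  f <- do.call(rbind, strsplit(names, "|", fixed = TRUE))
  data.frame(read_id = f[, 1], chrom = f[, 2],
             start = as.integer(f[, 3]), end = as.integer(f[, 4]),
             strand = f[, 5], hap = f[, 6], layout = f[, 7],
             cell_id = sub("\\..*$", "", f[, 1]),
             stringsAsFactors = FALSE)
}
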