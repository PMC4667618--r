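# Independent brute-force oracles used across test files. These deliberately
# avoid the package's interval machinery (no GRanges): plain loops and
# arithmetic only.

# bp overlap of two 0-based half-open intervals
bf_overlap_bp <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# edge-to-edge gap (0 when overlapping; abutting intervals have gap 0)
bf_gap_bp <- function(s1, e1, s2, e2) max(0, s2 - e1, s1 - e2)

# distance from a region edge to a point; 0 if the point is inside
bf_edge_dist <- function(s, e, p) max(0, s - p, p - (e - 1))

# transitive-closure merge by union-find over pairwise >=1 bp overlaps
bf_merge <- function(regions) {
  n <- nrow(regions)
  if (n == 0) return(regions[0, c("chrom", "start", "end")])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (regions$chrom[i] == regions$chrom[j] &&
        bf_overlap_bp(regions$start[i], regions$end[i],
                      regions$start[j], regions$end[j]) > 0) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  out <- do.call(rbind, lapply(unique(roots), function(r) {
    idx <- which(roots == r)
    data.frame(chrom = regions$chrom[idx[1]],
               start = min(regions$start[idx]), end = max(regions$end[idx]))
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# iterate union-find merging until stable (merging two clusters can create
# a new overlap only through a third, which transitive closure handles by
# repetition)
bf_merge_regions <- function(regions) {
  prev <- -1
  cur <- as.data.frame(regions[c("chrom", "start", "end")])
  while (nrow(cur) != prev) {
    prev <- nrow(cur)
    cur <- bf_merge(cur)
  }
  tibble::as_tibble(cur)
}

# trimmed mean by explicit sort-drop-mean, floor rounding per tail
bf_trimmed_mean <- function(x, trim = 0.10) {
  n <- length(x)
  drop <- floor(n * trim)
  s <- sort(x)
  mean(s[(drop + 1):(n - drop)])
}

# exhaustive overlapping motif scan by substring comparison
bf_count_motifs <- function(seq, motifs) {
  total <- 0L
  for (m in motifs) {
    k <- nchar(m)
    if (nchar(seq) < k) next
    for (i in 1:(nchar(seq) - k + 1)) {
      if (substr(seq, i, i + k - 1) == m) total <- total + 1L
    }
  }
  total
}

rand_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                         min_len = 50, max_len = 5000) {
  start <- floor(runif(n, 0, max_pos))
  len <- floor(runif(n, min_len, max_len))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len)
}

rand_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}
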