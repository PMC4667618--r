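#' Filter reads against a repeat mask
#'
#' Collapses duplicate reads (same chromosome, position and strand) to one
#' and removes reads whose genomic extent overlaps any masked repeat
#' interval by more than `max_overlap` bp (default 5, so an overlap of
#' exactly 5 bp is kept). Overlap is computed on the raw read extent
#' (`read_length` bp from the 5' position, strand-wise), not the extended
#' fragment, since the filter is defined on reads.
#'
#' @param reads Read tibble with `chrom`, `pos` (0-based 5' position) and
#'   `strand`.
#' @param repeat_mask Region tibble of repeat-element intervals (e.g. the
#'   `repeats` element of a [simulate_genome()] result).
#' @param read_length Read length in bp.
#' @param max_overlap Largest tolerated overlap in bp (strictly more is
#'   removed).
#' @return The filtered read tibble. Idempotent.
#' @export
filter_reads <- function(reads, repeat_mask, read_length = 36L, max_overlap = 5L) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(reads)))
  reads <- distinct(reads, .data$chrom, .data$pos, .data$strand)
  if (nrow(repeat_mask) == 0 || nrow(reads) == 0) return(reads)
  s <- ifelse(reads$strand == "+", reads$pos, pmax(0, reads$pos - read_length + 1))
  e <- ifelse(reads$strand == "+", reads$pos + read_length, reads$pos + 1)
  read_gr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(s + 1, e))
  hit <- IRanges::overlapsAny(read_gr, regions_to_gr(repeat_mask),
                                    minoverlap = max_overlap + 1L)
  reads[!hit, ]
}

chrom_sizes_tbl <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
    chrom_sizes
  } else {
    tibble(chrom = names(chrom_sizes), length = as.numeric(chrom_sizes))
  }
}

# Strand-wise fragment extension from the 5' position; minus-strand reads
# extend leftward. Returns 0-based half-open [s, e), clipped to [0, len].
extend_reads <- function(reads, fragment_length, chrom_len = NULL) {
  s <- ifelse(reads$strand == "+", reads$pos, reads$pos + 1 - fragment_length)
  e <- s + fragment_length
  clipped <- s < 0
  s <- pmax(s, 0)
  if (!is.null(chrom_len)) {
    L <- chrom_len[reads$chrom]
    clipped <- clipped | e > L
    e <- pmin(e, L)
  }
  n_clip <- sum(clipped)
  if (n_clip > 0) {
    inform(paste0("extend_reads: ", n_clip,
                  " fragment(s) clipped at chromosome ends"))
  }
  tibble(chrom = reads$chrom, start = s, end = e)
}

#' Extend reads and bin densities into a coverage track
#'
#' Extends each read to `fragment_length` bp from its 5' position
#' (minus-strand reads extend leftward), distributes each fragment's
#' bp-overlap-weighted mass into fixed-size bins, and normalizes to
#' library size (tags per million). Total track mass therefore equals
#' `n_reads * fragment_length / (library_size / 1e6)`. Fragments running
#' past a chromosome end are clipped (and the clipping reported).
#'
#' @param reads Read tibble (`chrom`, `pos`, `strand`).
#' @param chrom_sizes Tibble (`chrom`, `length`) or named vector of
#'   chromosome lengths.
#' @param fragment_length Fragment extension length, bp (commonly 200 or
#'   300).
#' @param bin_size Bin width, bp (commonly 25 or 200).
#' @param library_size Declared library size; defaults to `nrow(reads)`.
#' @return A binned-track tibble (`chrom`, `start`, `end`, `value`)
#'   covering every bin of every chromosome; the final bin of a
#'   chromosome may extend past its end so that all bins share one width.
#' @export
extend_and_bin <- function(reads, chrom_sizes, fragment_length = 200L,
                           bin_size = 25L, library_size = nrow(reads)) {
  stopifnot(fragment_length >= 1, bin_size >= 1, library_size > 0)
  cs <- chrom_sizes_tbl(chrom_sizes)
  n_bins <- ceiling(cs$length / bin_size)
  offset <- setNames(cumsum(c(0, n_bins[-length(n_bins)])), cs$chrom)
  total_bins <- sum(n_bins)
  acc <- numeric(total_bins)
  if (nrow(reads) > 0) {
    ext <- extend_reads(reads, fragment_length,
                        chrom_len = setNames(cs$length, cs$chrom))
    first_bin <- floor(ext$start / bin_size)
    gbase <- offset[ext$chrom] + first_bin   # 0-based global bin index
    K <- ceiling(fragment_length / bin_size) + 1L
    idx_all <- integer(0); ov_all <- numeric(0)
    for (j in seq_len(K) - 1L) {
      bstart <- (first_bin + j) * bin_size
      ov <- pmin(ext$end, bstart + bin_size) - pmax(ext$start, bstart)
      keep <- ov > 0
      if (!any(keep)) next
      idx_all <- c(idx_all, as.integer(gbase[keep] + j) + 1L)
      ov_all <- c(ov_all, ov[keep])
    }
    if (length(idx_all) > 0) {
      agg <- rowsum(ov_all, idx_all)
      acc[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  out <- tibble(
    chrom = rep(cs$chrom, n_bins),
    start = unlist(lapply(n_bins, function(n) (seq_len(n) - 1) * bin_size),
                   use.names = FALSE)
  )
  out$end <- out$start + bin_size
  out$value <- acc / (library_size / 1e6)
  out
}

# Per-region vector of counts/mass; internal engine behind count_tags().
region_signal <- function(x, regions, fragment_length, chrom_sizes = NULL) {
  if (nrow(regions) == 0) return(numeric(0))
  region_gr <- regions_to_gr(regions)
  if ("value" %in% names(x)) {
    # binned track: bp-overlap-weighted share of each bin's mass
    bin_size <- unique(x$end - x$start)
    if (length(bin_size) != 1) abort("mixed bin sizes in track")
    hits <- GenomicRanges::findOverlaps(region_gr, regions_to_gr(x))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- pmin(regions$end[q], x$end[s]) - pmax(regions$start[q], x$start[s])
    out <- numeric(nrow(regions))
    if (length(q) > 0) {
      agg <- rowsum(ov / bin_size * x$value[s], q)
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  } else {
    chrom_len <- if (!is.null(chrom_sizes)) {
      cs <- chrom_sizes_tbl(chrom_sizes); setNames(cs$length, cs$chrom)
    } else NULL
    ext <- extend_reads(x, fragment_length, chrom_len)
    GenomicRanges::countOverlaps(region_gr, regions_to_gr(ext))
  }
}

#' Count tags over regions
#'
#' Counts, for each region, the extended reads overlapping it by at least
#' 1 bp; or, given a binned track instead of reads, the bp-overlap-weighted
#' track mass over the region. With `fragment_length = 1` reads are counted
#' as points at their 5' position, so counts over a disjoint partition of
#' the genome sum to the library size.
#'
#' @param x A read tibble (`chrom`, `pos`, `strand`) or a binned-track
#'   tibble (`chrom`, `start`, `end`, `value`).
#' @param regions Region tibble.
#' @param fragment_length Extension length for reads; ignored for tracks.
#' @param chrom_sizes Optional chromosome sizes for end clipping.
#' @param normalize If `TRUE`, scale read counts to tags per million using
#'   `library_size`.
#' @param library_size Library size for normalization (default
#'   `nrow(x)` for reads).
#' @return `regions` with a `tag_count` column appended.
#' @export
count_tags <- function(x, regions, fragment_length = 200L, chrom_sizes = NULL,
                       normalize = FALSE, library_size = NULL) {
  validate_regions(regions)
  counts <- region_signal(x, regions, fragment_length, chrom_sizes)
  if (normalize) {
    if (is.null(library_size)) {
      if ("value" %in% names(x)) abort("library_size required to normalize a track")
      library_size <- nrow(x)
    }
    counts <- counts / (library_size / 1e6)
  }
  regions$tag_count <- as.numeric(counts)
  regions
}
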