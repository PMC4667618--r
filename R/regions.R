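#' Genomic interval conventions
#'
#' All intervals in this package are 0-based, half-open `[start, end)` on a
#' named chromosome, the native convention of the BED family of formats.
#' Dialects that use 1-based closed coordinates are converted once at the
#' I/O boundary. Chromosome names are taken verbatim; no "chr" prefix
#' normalization is attempted.
#'
#' A *region tibble* is any tibble with at least the columns `chrom`
#' (character), `start` and `end` (numeric, `start >= 0`, `end > start`).
#' Most functions in the package take and return region tibbles so that
#' calls chain with the pipe.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors of 0-based half-open bounds.
#' @return `region_tbl()` returns a validated region tibble.
#' @examples
#' region_tbl("chr1", 100, 300)
#' @export
region_tbl <- function(chrom, start, end) {
  out <- tibble(chrom = as.character(chrom), start = as.numeric(start),
                end = as.numeric(end))
  validate_regions(out)
  out
}

validate_regions <- function(x, what = "region") {
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(what, " tibble lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(x$start < 0 | x$end <= x$start | !is.finite(x$start) |
                 !is.finite(x$end))
  if (length(bad) > 0) {
    abort(paste0("invalid ", what, " at row ", bad[1], ": start=",
                 x$start[bad[1]], ", end=", x$end[bad[1]],
                 " (need 0 <= start < end)"))
  }
  invisible(x)
}

# Bridge to the Bioconductor ranges stack: 0-based half-open [start, end)
# maps to the 1-based closed IRanges(start + 1, end).
regions_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

gr_to_regions <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

# Point positions (0-based bp) as width-1 GRanges.
points_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos + 1L, width = 1L))
}

#' Merge overlapping regions across island sets
#'
#' Computes the transitive closure of >= 1 bp overlaps across one or more
#' sets of called islands or peaks, the "merged genomic regions" that serve
#' as the unit of cross-sample comparison. Abutting half-open intervals
#' (`end == start`) do not overlap and are not merged.
#'
#' @param island_sets A region tibble, or a (possibly named) list of region
#'   tibbles, each with `chrom`, `start`, `end` columns.
#' @return A region tibble of disjoint merged regions, sorted by chromosome
#'   and start, with a `merged_id` column.
#' @examples
#' merge_regions(list(region_tbl("chr1", c(100, 150), c(200, 250))))
#' @export
merge_regions <- function(island_sets) {
  if (is.data.frame(island_sets)) island_sets <- list(island_sets)
  if (length(island_sets) < 1) abort("need at least one island set")
  purrr::walk(island_sets, validate_regions)
  all <- bind_rows(lapply(island_sets, function(x) x[c("chrom", "start", "end")]))
  if (nrow(all) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  merged_id = integer()))
  }
  merged <- GenomicRanges::reduce(regions_to_gr(all), min.gapwidth = 0L)
  merged <- GenomicRanges::sort(merged)
  out <- gr_to_regions(merged)
  out$merged_id <- seq_len(nrow(out))
  out
}

# Distance (bp) from a region's edge to a point, 0 when the point lies
# inside [start, end); a point on the first base past the end is 1 away.
edge_distance <- function(start, end, pos) {
  pmax(0, start - pos, pos - (end - 1))
}
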