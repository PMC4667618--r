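#' Read interval tables (BED, island tables, peak tables)
#'
#' Reads tab-delimited interval records into a region tibble, converting to
#' the package's 0-based half-open convention (BED files are already in it).
#' Three dialects are supported:
#'
#' * `"bed"`: `chrom, start, end` with optional `name, score, strand`.
#' * `"island_table"`: `chrom, start, end, tag_count` with optional `score`
#'   (a caller score such as a SICER island score). A missing score column
#'   is read as `NA`, which downstream score-based filters treat as
#'   "skip the score clause".
#' * `"peak_table"`: `chrom, start, end, summit, tag_count, p_value`, with
#'   `summit` an absolute 0-based bp position.
#'
#' Lines starting with `#` or `track` are skipped; the number skipped is
#' reported, never silently dropped. Input line order is preserved.
#'
#' @param path Path to a tab-delimited file without header.
#' @param format One of `"bed"`, `"island_table"`, `"peak_table"`.
#' @return A tibble with the dialect's columns; always `chrom`, `start`,
#'   `end` at minimum.
#' @seealso [write_intervals()]
#' @export
read_intervals <- function(path, format = c("bed", "island_table", "peak_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track([ \t]|$))", lines) & nzchar(trimws(lines))
  n_skip <- sum(!keep & nzchar(trimws(lines)))
  if (n_skip > 0) inform(paste0("read_intervals: skipped ", n_skip,
                                " comment/track line(s) in ", basename(path)))
  lineno <- which(keep)
  lines <- lines[keep]
  cols <- switch(format,
    bed = c("chrom", "start", "end", "name", "score", "strand"),
    island_table = c("chrom", "start", "end", "tag_count", "score"),
    peak_table = c("chrom", "start", "end", "summit", "tag_count", "p_value")
  )
  n_required <- switch(format, bed = 3L, island_table = 4L, peak_table = 6L)
  numeric_cols <- setdiff(cols, c("chrom", "name", "strand"))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_required)
  if (length(bad) > 0) {
    abort(paste0("malformed line ", lineno[bad[1]], " in ", basename(path),
                 ": expected >= ", n_required, " tab-delimited fields, got ",
                 nf[bad[1]]))
  }
  ncol_out <- min(max(nf), length(cols))
  get_col <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  }
  out <- lapply(seq_len(ncol_out), get_col)
  names(out) <- cols[seq_len(ncol_out)]
  out <- as_tibble(out)
  for (cc in intersect(numeric_cols, names(out))) {
    raw <- out[[cc]]
    val <- suppressWarnings(as.numeric(ifelse(raw %in% c(".", "", NA), NA, raw)))
    bad <- which(is.na(val) & !(raw %in% c(".", "", NA)))
    if (length(bad) > 0) {
      abort(paste0("malformed line ", lineno[bad[1]], " in ", basename(path),
                   ": non-numeric value '", raw[bad[1]], "' in column ", cc))
    }
    required <- cols[seq_len(n_required)]
    if (cc %in% required && anyNA(val)) {
      abort(paste0("malformed line ", lineno[which(is.na(val))[1]], " in ",
                   basename(path), ": missing required value in column ", cc))
    }
    out[[cc]] <- val
  }
  bad <- which(out$start < 0 | out$end <= out$start)
  if (length(bad) > 0) {
    abort(paste0("invalid interval at line ", lineno[bad[1]], " in ",
                 basename(path), ": start=", out$start[bad[1]], ", end=",
                 out$end[bad[1]], " (need 0 <= start < end)"))
  }
  if (format == "island_table" && !"score" %in% names(out)) out$score <- NA_real_
  out
}

#' Write interval tables
#'
#' Writes a region tibble back to the tab-delimited dialects read by
#' [read_intervals()], without header. `NA` values are written as `.`.
#'
#' @param x A region tibble.
#' @param path Output path.
#' @param format Dialect, as in [read_intervals()].
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("bed", "island_table", "peak_table")) {
  format <- match.arg(format)
  validate_regions(x)
  cols <- switch(format,
    bed = c("chrom", "start", "end", "name", "score", "strand"),
    island_table = c("chrom", "start", "end", "tag_count", "score"),
    peak_table = c("chrom", "start", "end", "summit", "tag_count", "p_value")
  )
  cols <- intersect(cols, names(x))
  out <- x[cols]
  lines <- do.call(paste, c(lapply(out, function(v) {
    s <- ifelse(is.na(v), ".", format(v, scientific = FALSE, trim = TRUE, digits = 15))
    s
  }), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a binned coverage track
#'
#' Writes a binned track (as produced by [extend_and_bin()]) as a bedGraph
#' or fixed-step wiggle file. All bins must have the same size; fixed-step
#' blocks are restarted wherever bins are not contiguous. Values are
#' written with at least four significant digits.
#'
#' @param track A tibble with `chrom`, `start`, `end`, `value` columns and
#'   constant bin width `end - start`.
#' @param path Output path.
#' @param format `"bedgraph"` or `"wig"`.
#' @return `path`, invisibly.
#' @seealso [read_track()]
#' @export
write_track <- function(track, path, format = c("bedgraph", "wig")) {
  format <- match.arg(format)
  if (nrow(track) == 0) {
    writeLines(if (format == "bedgraph") "track type=bedGraph" else
                 "track type=wiggle_0", path)
    return(invisible(path))
  }
  validate_regions(track, what = "track")
  widths <- unique(track$end - track$start)
  if (length(widths) != 1) {
    abort(paste0("mixed bin sizes in track: ", paste(sort(widths), collapse = ", ")))
  }
  bin <- widths
  track <- arrange(track, .data$chrom, .data$start)
  fmt <- function(v) formatC(v, digits = 6, format = "g")
  if (format == "bedgraph") {
    lines <- c("track type=bedGraph",
               paste(track$chrom, format(track$start, scientific = FALSE, trim = TRUE),
                     format(track$end, scientific = FALSE, trim = TRUE),
                     fmt(track$value), sep = "\t"))
  } else {
    lines <- "track type=wiggle_0"
    # new fixedStep declaration at each chromosome change or coverage gap
    new_block <- c(TRUE, track$chrom[-1] != track$chrom[-nrow(track)] |
                     track$start[-1] != track$end[-nrow(track)])
    block <- cumsum(new_block)
    for (b in unique(block)) {
      idx <- which(block == b)
      lines <- c(lines,
                 paste0("fixedStep chrom=", track$chrom[idx[1]],
                        " start=", format(track$start[idx[1]] + 1, scientific = FALSE),
                        " step=", bin, " span=", bin),
                 fmt(track$value[idx]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a coverage track
#'
#' Reads a bedGraph or wiggle track into a binned-track tibble with
#' `chrom`, `start`, `end`, `value` columns (0-based half-open bins).
#' Parsing is delegated to \pkg{rtracklayer}.
#'
#' @param path Path to a bedGraph or wig file.
#' @param format `"bedgraph"` or `"wig"`.
#' @return A tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_track <- function(path, format = c("bedgraph", "wig")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "bedgraph") "bedGraph" else "wig")
  out <- gr_to_regions(gr)
  out$value <- as.numeric(gr$score)
  arrange(out, .data$chrom, .data$start)
}

#' Read and write FASTA sequences
#'
#' `read_fasta()` returns a named character vector of upper-cased
#' sequences; duplicate identifiers are an error. Identifiers are the
#' first whitespace-delimited word of the header. `write_fasta()` writes a
#' named character vector.
#'
#' @param path Path to a FASTA file.
#' @return `read_fasta()`: a named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence identifier in ", basename(path), ": ",
                 ids[anyDuplicated(ids)]))
  }
  setNames(toupper(as.character(ss)), ids)
}

#' @param sequences A named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read and write gene annotation (TSS) tables
#'
#' A minimal tab-delimited gene table with header columns `gene_id`,
#' `chrom`, `tss`, `strand`, `body_end`. `tss` and `body_end` are 0-based
#' bp positions; `body_end` must lie downstream of the TSS in the gene's
#' orientation (`body_end >= tss` on `+`, `body_end <= tss` on `-`).
#'
#' @param path Path to the table.
#' @return `read_tss_table()`: a tibble with the five columns above.
#' @export
read_tss_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    tss = readr::col_double(), strand = readr::col_character(),
    body_end = readr::col_double()))
  if (anyDuplicated(x$gene_id)) {
    abort(paste0("duplicate gene_id in ", basename(path), ": ",
                 x$gene_id[anyDuplicated(x$gene_id)]))
  }
  validate_genes(x)
  x
}

validate_genes <- function(x) {
  need <- c("gene_id", "chrom", "tss", "strand", "body_end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("gene table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(x$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  bad <- which((x$strand == "+" & x$body_end < x$tss) |
                 (x$strand == "-" & x$body_end > x$tss))
  if (length(bad) > 0) {
    abort(paste0("gene ", x$gene_id[bad[1]],
                 ": body_end is on the wrong side of the TSS for its strand"))
  }
  invisible(x)
}

#' @param genes A gene tibble as returned by `read_tss_table()`.
#' @rdname read_tss_table
#' @export
write_tss_table <- function(genes, path) {
  validate_genes(genes)
  readr::write_tsv(genes[c("gene_id", "chrom", "tss", "strand", "body_end")], path)
  invisible(path)
}

#' Read and write expression matrices
#'
#' Tab-delimited probe-set level expression with header columns
#' `probe_set`, `gene_id`, then one numeric column per sample (log2
#' scale by convention). Duplicate probe-set identifiers are an error.
#'
#' @param path Path to the table.
#' @return `read_expression()`: a tibble.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    probe_set = readr::col_character(), gene_id = readr::col_character(),
    .default = readr::col_double()))
  if (!all(c("probe_set", "gene_id") %in% names(x))) {
    abort("expression table needs 'probe_set' and 'gene_id' columns")
  }
  if (anyDuplicated(x$probe_set)) {
    abort(paste0("duplicate probe_set in ", basename(path), ": ",
                 x$probe_set[anyDuplicated(x$probe_set)]))
  }
  x
}

#' @param expression An expression tibble.
#' @rdname read_expression
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}
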