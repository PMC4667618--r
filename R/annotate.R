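#' Annotate regions as promoter, gene body or intergenic
#'
#' Assigns every region exactly one label. A region overlapping a
#' strand-oriented promoter window (10 kb upstream through 1 kb
#' downstream of a TSS, closed bounds) is a `promoter`; otherwise a
#' region overlapping a gene's body (beyond the +1 kb position through
#' the annotated body end) is `gene_body`; everything else is
#' `intergenic`. Promoter takes precedence over gene body, and when a
#' region touches several genes' windows the gene with the nearest TSS
#' wins.
#'
#' @param regions Region tibble.
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`, `strand`,
#'   `body_end`.
#' @param upstream,downstream Promoter window extent (bp) upstream and
#'   downstream of the TSS in the gene's orientation.
#' @return `regions` with `label` and `gene_id` columns appended
#'   (`gene_id` is `NA` for intergenic regions).
#' @export
annotate_regions <- function(regions, genes, upstream = 10000, downstream = 1000) {
  validate_regions(regions)
  validate_genes(genes)
  if (nrow(regions) == 0) {
    regions$label <- character(0); regions$gene_id <- character(0)
    return(regions)
  }
  plus <- genes$strand == "+"
  prom <- tibble(
    chrom = genes$chrom,
    start = pmax(0, ifelse(plus, genes$tss - upstream, genes$tss - downstream)),
    end = ifelse(plus, genes$tss + downstream, genes$tss + upstream) + 1
  )
  body <- tibble(
    chrom = genes$chrom,
    start = ifelse(plus, genes$tss + downstream + 1, genes$body_end),
    end = ifelse(plus, genes$body_end + 1, genes$tss - downstream)
  )
  body_valid <- body$end > body$start & body$start >= 0

  assign_nearest <- function(windows, valid = rep(TRUE, nrow(windows))) {
    out <- rep(NA_integer_, nrow(regions))
    w <- windows[valid, , drop = FALSE]
    if (nrow(w) == 0) return(out)
    gidx <- which(valid)
    hits <- GenomicRanges::findOverlaps(regions_to_gr(regions), regions_to_gr(w))
    if (length(hits) == 0) return(out)
    q <- S4Vectors::queryHits(hits); g <- gidx[S4Vectors::subjectHits(hits)]
    d <- edge_distance(regions$start[q], regions$end[q], genes$tss[g])
    cand <- tibble(q = q, g = g, d = d) %>%
      arrange(.data$q, .data$d, .data$g) %>%
      distinct(.data$q, .keep_all = TRUE)
    out[cand$q] <- cand$g
    out
  }
  prom_gene <- assign_nearest(prom)
  body_gene <- assign_nearest(body, body_valid)
  gene_row <- dplyr::coalesce(prom_gene, body_gene)
  regions$label <- dplyr::case_when(
    !is.na(prom_gene) ~ "promoter",
    !is.na(body_gene) ~ "gene_body",
    TRUE ~ "intergenic"
  )
  regions$gene_id <- ifelse(is.na(gene_row), NA_character_, genes$gene_id[gene_row])
  regions
}

#' Partition merged regions by set membership (Venn logic)
#'
#' Merges all input region sets and assigns each merged region the subset
#' of input sets overlapping it, yielding the cell counts of a Venn
#' diagram over merged genomic regions. Cell counts always sum to the
#' number of merged regions.
#'
#' @param named_region_sets Named list of region tibbles.
#' @return An object of class `venn_partition`: a list with `membership`
#'   (merged regions with one logical column per set and a `cell` label)
#'   and `counts` (tibble of `cell`, `n`).
#' @export
venn_partition <- function(named_region_sets) {
  stopifnot(is.list(named_region_sets), length(named_region_sets) >= 1,
            !is.null(names(named_region_sets)),
            all(nzchar(names(named_region_sets))))
  merged <- merge_regions(named_region_sets)
  membership <- merged
  gr <- regions_to_gr(merged)
  for (nm in names(named_region_sets)) {
    s <- named_region_sets[[nm]]
    membership[[nm]] <- if (nrow(s) == 0) rep(FALSE, nrow(merged)) else
      IRanges::overlapsAny(gr, regions_to_gr(s))
  }
  mm <- as.matrix(membership[names(named_region_sets)])
  membership$cell <- apply(mm, 1, function(r) {
    paste(names(named_region_sets)[r], collapse = "&")
  })
  counts <- membership %>%
    dplyr::count(.data$cell, name = "n") %>%
    arrange(desc(.data$n))
  structure(list(membership = membership, counts = counts,
                 set_names = names(named_region_sets)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> over", nrow(x$membership), "merged regions from sets:",
      paste(x$set_names, collapse = ", "), "\n")
  print(x$counts)
  invisible(x)
}

#' @rdname venn_partition
#' @param x A `venn_partition` object.
#' @param ... Unused.
#' @export
tidy.venn_partition <- function(x, ...) x$counts

#' Overlap percentage, rounded as printed
#'
#' `100 * shared / total`, rounded half-up to `decimals` digits, the way
#' overlap fractions are reported in text (e.g. 4,689 of 5,351 regions
#' is 87.6%).
#'
#' @param shared_count,total_count Non-negative counts, `shared <= total`,
#'   `total > 0`.
#' @param decimals Decimal places to round to.
#' @return The rounded percentage.
#' @examples
#' overlap_percentage(4689, 5351, 1) # 87.6
#' @export
overlap_percentage <- function(shared_count, total_count, decimals = 1) {
  stopifnot(all(total_count > 0), all(shared_count >= 0),
            all(shared_count <= total_count), decimals >= 0)
  x <- 100 * shared_count / total_count
  floor(x * 10^decimals + 0.5) / 10^decimals
}

#' Bivalent chromatin regions
#'
#' Merged regions carrying both a repressive (H3K27me3) and an active
#' (H3K4me3) island, the classic definition of bivalent domains.
#'
#' @param k27_islands,k4_islands Region tibbles of islands for each mark.
#' @return The merged regions overlapped by both marks.
#' @export
call_bivalent <- function(k27_islands, k4_islands) {
  vp <- venn_partition(list(K27 = k27_islands, K4 = k4_islands))
  out <- filter(vp$membership, .data$K27 & .data$K4)
  out[c("chrom", "start", "end", "merged_id")]
}

#' log2 fold change over input
#'
#' `log2((signal + pc) / (input + pc))` on pair-normalized counts, the
#' usual binding-intensity scale for heatmaps.
#'
#' @param signal_count,input_count Non-negative counts.
#' @param pseudocount Added to both before the ratio.
#' @return Numeric vector.
#' @export
log2_fc_over_input <- function(signal_count, input_count, pseudocount = 1) {
  if (any(signal_count < 0) || any(input_count < 0)) {
    abort("counts must be non-negative")
  }
  log2((signal_count + pseudocount) / (input_count + pseudocount))
}
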