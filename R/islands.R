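#' Island eligibility filter (deep, single-stage design)
#'
#' Applies the eligibility rules for islands called on a deeply sequenced
#' single-stage comparison: mark-specific minimum length (800 bp for
#' H3K27me3, 400 bp for H3K4me3), strictly more than 50 tags, and a
#' strictly greater tag-density (tag count / island length) threshold
#' (0.03 for H3K27me3, 0.04 for H3K4me3). Boundary semantics: a 800-bp
#' H3K27me3 island with 51 tags and density 0.031 is kept; 50 tags is not
#' "more than 50" and is removed.
#'
#' @param islands Island tibble with `chrom`, `start`, `end`, `tag_count`
#'   (and optionally a `mark` column).
#' @param mark `"H3K27me3"` or `"H3K4me3"`; defaults to the `mark` column
#'   when present.
#' @return The surviving islands.
#' @export
filter_eligible_dp <- function(islands, mark = NULL) {
  validate_regions(islands, "island")
  stopifnot("tag_count" %in% names(islands))
  if (is.null(mark)) {
    if (!"mark" %in% names(islands)) abort("supply `mark` or a mark column")
    mark <- islands$mark
  }
  if (!all(mark %in% c("H3K27me3", "H3K4me3"))) {
    abort(paste0("unknown mark: ", paste(setdiff(mark, c("H3K27me3", "H3K4me3")),
                                         collapse = ", ")))
  }
  min_len <- ifelse(mark == "H3K27me3", 800, 400)
  min_density <- ifelse(mark == "H3K27me3", 0.03, 0.04)
  len <- islands$end - islands$start
  keep <- len >= min_len & islands$tag_count > 50 &
    islands$tag_count / len > min_density
  islands[keep, ]
}

#' Island eligibility filter (multi-stage subsets design)
#'
#' Applies the eligibility rules used for islands called across
#' developmental-stage subsets: length at least 800 bp, caller island
#' score strictly greater than 45, and tag density (tag count / length)
#' strictly greater than 0.04. When the score is missing (`NA` or no
#' `score` column), the score clause is skipped with a warning rather
#' than failing.
#'
#' @param islands Island tibble with `chrom`, `start`, `end`, `tag_count`
#'   and optionally `score`.
#' @return The surviving islands.
#' @export
filter_eligible_subsets <- function(islands) {
  validate_regions(islands, "island")
  stopifnot("tag_count" %in% names(islands))
  len <- islands$end - islands$start
  keep <- len >= 800 & islands$tag_count / len > 0.04
  score <- if ("score" %in% names(islands)) islands$score else
    rep(NA_real_, nrow(islands))
  have_score <- !is.na(score)
  if (!all(have_score)) {
    warn(paste0("filter_eligible_subsets: score missing for ",
                sum(!have_score), " island(s); score clause skipped for them"))
  }
  keep <- keep & (!have_score | score > 45)
  islands[keep, ]
}

#' Exclude artifact-prone merged regions
#'
#' Removes merged H3K27me3 regions matching any of three artifact rules:
#'
#' * `small_tss_distal`: regions at most 1.2 kb long whose nearest TSS is
#'   strictly more than 5 kb from the region edge (small intergenic
#'   "islands" that likely reflect sequencing noise);
#' * `island_tail`: regions shorter than 2 kb lying strictly within 5 kb
#'   (edge-to-edge gap) of another region at least 3 times longer
#'   (island "tails" split off by the caller). Neighbours are judged
#'   against the full input set, before any exclusion;
#' * `high_input`: regions whose library-size-normalized input tag count
#'   divided by region length exceeds 0.024.
#'
#' TSS distance is edge-to-edge in bp, 0 when the TSS falls inside the
#' region, and ignores strand.
#'
#' @param merged Merged-region tibble (`chrom`, `start`, `end`).
#' @param genes Gene tibble with `chrom` and `tss` columns.
#' @param input_track Binned input-control track (library-size normalized),
#'   or a numeric vector of per-region normalized input counts aligned to
#'   `merged`.
#' @return A list with `kept` (surviving regions) and `excluded` (removed
#'   regions with a `reason` column; a region matching several rules
#'   carries the first in the order above).
#' @export
exclude_artifacts <- function(merged, genes, input_track) {
  validate_regions(merged, "merged region")
  if (nrow(genes) == 0) abort("genes must be non-empty")
  len <- merged$end - merged$start

  # rule 1: small and TSS-distal
  tss_dist <- vapply(seq_len(nrow(merged)), function(i) {
    g <- genes[genes$chrom == merged$chrom[i], ]
    if (nrow(g) == 0) return(Inf)
    min(edge_distance(merged$start[i], merged$end[i], g$tss))
  }, 0)
  rule_tss <- len <= 1200 & tss_dist > 5000

  # rule 2: tail of a >=3x longer island within <5 kb, judged on the
  # unfiltered input set
  gr <- regions_to_gr(merged)
  hits <- GenomicRanges::findOverlaps(gr, gr, maxgap = 4999L)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep_pair <- q != s & len[s] >= 3 * len[q]
  rule_tail <- len < 2000 & seq_len(nrow(merged)) %in% q[keep_pair]

  # rule 3: high input signal density
  input_counts <- if (is.numeric(input_track)) {
    stopifnot(length(input_track) == nrow(merged))
    input_track
  } else {
    region_signal(input_track, merged, fragment_length = NULL)
  }
  rule_input <- input_counts / len > 0.024

  reason <- dplyr::case_when(
    rule_tss ~ "small_tss_distal",
    rule_tail ~ "island_tail",
    rule_input ~ "high_input",
    TRUE ~ NA_character_
  )
  excluded <- merged[!is.na(reason), ]
  excluded$reason <- reason[!is.na(reason)]
  list(kept = merged[is.na(reason), ], excluded = excluded)
}

#' Select the most TSS-proximal island per gene
#'
#' For each gene, picks the island minimizing the edge-to-TSS distance
#' (0 when the island spans the TSS). Ties are broken by larger tag
#' count, then by leftmost start.
#'
#' @param islands Island tibble (`chrom`, `start`, `end`, optionally
#'   `tag_count`).
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`.
#' @return A tibble mapping `gene_id` to its selected island (island
#'   columns plus `tss_distance`); genes with no island on their
#'   chromosome are absent.
#' @export
select_tss_proximal <- function(islands, genes) {
  validate_regions(islands, "island")
  if (nrow(islands) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character()))
  }
  isl <- islands
  isl$.island_row <- seq_len(nrow(isl))
  if (!"tag_count" %in% names(isl)) isl$tag_count <- 0
  pairs <- inner_join(genes[c("gene_id", "chrom", "tss")], isl,
                      by = "chrom", relationship = "many-to-many")
  if (nrow(pairs) == 0) return(tibble(gene_id = character()))
  pairs %>%
    mutate(tss_distance = edge_distance(.data$start, .data$end, .data$tss)) %>%
    group_by(.data$gene_id) %>%
    arrange(.data$tss_distance, desc(.data$tag_count), .data$start,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(-"tss", -".island_row")
}
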