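#' Call differential islands by fold change
#'
#' Classifies regions by the pair-normalized mutant/wild-type fold change:
#' `decreased` when wild type exceeds mutant by strictly more than
#' `threshold` (default 1.8), `increased` when the mutant exceeds wild
#' type by strictly more than `threshold`, otherwise `unchanged`. A
#' fold change of exactly 1.8 is `unchanged` (strict inequality). A
#' pseudocount (default 1) is added to both counts before the ratio so
#' zero-count regions are defined.
#'
#' @param data Region tibble carrying the two count columns, or `NULL` to
#'   pass bare vectors.
#' @param wt,mut Column names (tidy-eval) of the pair-normalized wild-type
#'   and mutant counts in `data`, or numeric vectors when `data` is
#'   `NULL`.
#' @param threshold Fold-change threshold (strict).
#' @param pseudocount Added to both counts before forming the ratio.
#' @return `data` (or a new tibble) with `fc` (mutant/wild-type ratio on
#'   pseudocounted values) and `label` columns.
#' @examples
#' call_differential(tibble::tibble(wt = c(100, 190, 180), mut = 100))
#' @export
call_differential <- function(data = NULL, wt = wt, mut = mut,
                              threshold = 1.8, pseudocount = 1) {
  if (is.null(data)) {
    w <- wt; m <- mut
    data <- tibble(wt = w, mut = m)
  } else {
    w <- dplyr::pull(data, {{ wt }})
    m <- dplyr::pull(data, {{ mut }})
  }
  if (any(w < 0) || any(m < 0)) abort("counts must be non-negative")
  stopifnot(threshold > 0, pseudocount >= 0)
  fc <- (m + pseudocount) / (w + pseudocount)
  data$fc <- fc
  data$label <- dplyr::case_when(
    1 / fc > threshold ~ "decreased",
    fc > threshold ~ "increased",
    TRUE ~ "unchanged"
  )
  data
}

#' Regions decreased in at least one stage
#'
#' Given per-stage differential calls over identical regions (as from
#' [call_differential()] run on each wild-type/mutant stage pair), returns
#' the union of regions labelled `decreased` in at least one stage.
#'
#' @param per_stage_calls A long tibble with `chrom`, `start`, `end`,
#'   `stage` and `label` columns, or a named list of per-stage call
#'   tibbles (names become stages).
#' @return The distinct decreased regions, with a `stages` column listing
#'   the stages in which each was decreased.
#' @export
call_decreased_any_stage <- function(per_stage_calls) {
  if (is.list(per_stage_calls) && !is.data.frame(per_stage_calls)) {
    per_stage_calls <- bind_rows(per_stage_calls, .id = "stage")
  }
  stopifnot(all(c("chrom", "start", "end", "stage", "label") %in%
                  names(per_stage_calls)))
  per_stage_calls %>%
    filter(.data$label == "decreased") %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    summarise(stages = paste(sort(unique(.data$stage)), collapse = ","),
              .groups = "drop")
}

#' Induced islands backed by a binding peak
#'
#' Identifies islands whose signal increased by strictly more than
#' `threshold` between a pre- and post-induction condition and that
#' overlap at least one binding peak in the induced condition.
#'
#' @param islands Island tibble with pre- and post-induction count
#'   columns.
#' @param peaks Region tibble of peaks in the induced condition.
#' @param pre,post Column names (tidy-eval) of the pre- and post-induction
#'   counts.
#' @param threshold Fold-change threshold (strict).
#' @param pseudocount Added to both counts before the ratio.
#' @return The qualifying islands, with an `fc` column.
#' @export
call_induced_islands <- function(islands, peaks, pre = pre, post = post,
                                 threshold = 1.8, pseudocount = 1) {
  validate_regions(islands, "island")
  p <- dplyr::pull(islands, {{ pre }})
  q <- dplyr::pull(islands, {{ post }})
  fc <- (q + pseudocount) / (p + pseudocount)
  has_peak <- if (nrow(peaks) == 0) rep(FALSE, nrow(islands)) else
    IRanges::overlapsAny(regions_to_gr(islands), regions_to_gr(peaks))
  islands$fc <- fc
  islands[fc > threshold & has_peak, ]
}

#' k-means clustering of tag-density matrices
#'
#' Clusters rows of a (typically region-by-sample tag density) matrix with
#' k-means, deterministically under a fixed seed, keeping the best of
#' `n_restarts` random starts. Rows are standardized (centred and scaled;
#' zero-variance rows are centred only) before clustering by default,
#' matching the usual preprocessing of tag-density heatmaps.
#'
#' @param matrix Numeric matrix with finite entries.
#' @param k Number of clusters, `1 <= k <= nrow(matrix)`.
#' @param seed Integer seed.
#' @param n_restarts Number of random starts.
#' @param standardize Standardize rows first.
#' @return An object of class `island_kmeans` with elements `cluster`
#'   (integer assignment), `centers`, `tot_withinss`, `k`, `seed` and the
#'   (standardized) `matrix`.
#' @export
kmeans_cluster <- function(matrix, k, seed = 1L, n_restarts = 25L,
                           standardize = TRUE) {
  stopifnot(is.matrix(matrix), k >= 1)
  if (!all(is.finite(matrix))) abort("matrix must be finite")
  if (k > nrow(matrix)) abort("k exceeds the number of rows")
  m <- matrix
  if (standardize) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- 1
    m <- (m - mu) / s
  }
  set.seed(seed)
  fit <- kmeans(m, centers = k, nstart = n_restarts, iter.max = 100)
  structure(list(cluster = fit$cluster, centers = fit$centers,
                 tot_withinss = fit$tot.withinss, k = k, seed = seed,
                 matrix = m),
            class = "island_kmeans")
}

#' @export
print.island_kmeans <- function(x, ...) {
  cat("<island_kmeans> k =", x$k, "on", nrow(x$matrix), "rows;",
      "total within-cluster SS =", signif(x$tot_withinss, 5), "\n")
  invisible(x)
}

#' @rdname kmeans_cluster
#' @param x An `island_kmeans` object.
#' @param ... Unused.
#' @export
tidy.island_kmeans <- function(x, ...) {
  tibble(row = seq_along(x$cluster), cluster = as.integer(x$cluster))
}

#' @rdname kmeans_cluster
#' @export
glance.island_kmeans <- function(x, ...) {
  tibble(k = x$k, n = nrow(x$matrix), tot_withinss = x$tot_withinss,
         seed = x$seed)
}

#' Select one probe set per gene
#'
#' For genes represented by several probe sets, selects the probe set with
#' the highest product of expression and fold change; ties are broken by
#' probe-set identifier order.
#'
#' @param probes Tibble with `gene_id`, `probe_set` and the two score
#'   ingredients.
#' @param expression,fc Column names (tidy-eval) of the expression and
#'   fold-change values entering the score.
#' @return One row per gene: `gene_id`, `probe_set`, `score`.
#' @export
select_probe_set <- function(probes, expression = expression, fc = fc) {
  stopifnot(all(c("gene_id", "probe_set") %in% names(probes)))
  probes$.score <- dplyr::pull(probes, {{ expression }}) * dplyr::pull(probes, {{ fc }})
  probes %>%
    group_by(.data$gene_id) %>%
    arrange(desc(.data$.score), .data$probe_set, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("gene_id", "probe_set", score = ".score")
}

#' Dynamically regulated genes by expression range
#'
#' Keeps genes whose expression varies by strictly more than `fold`
#' between the lowest and highest value across all samples and probe
#' sets (linear scale; a ratio of exactly 4 does not pass).
#'
#' @param expression Expression tibble with `probe_set`, `gene_id` and one
#'   column per sample.
#' @param fold Dynamic-range threshold on the linear scale (strict).
#' @param log2_input Are the stored values log2? (Then the criterion is
#'   `max - min > log2(fold)`.)
#' @return A tibble of passing genes with their linear `range_fold`.
#' @export
dynamic_expression_filter <- function(expression, fold = 4, log2_input = TRUE) {
  stopifnot(all(c("probe_set", "gene_id") %in% names(expression)), fold > 0)
  long <- tidyr::pivot_longer(expression,
                              cols = -dplyr::all_of(c("probe_set", "gene_id")),
                              names_to = "sample", values_to = "value")
  if (log2_input) long$value <- 2^long$value
  long %>%
    group_by(.data$gene_id) %>%
    summarise(range_fold = max(.data$value) / min(.data$value),
              .groups = "drop") %>%
    filter(.data$range_fold > fold)
}

#' ChIP-qPCR quantification helpers
#'
#' `percent_input()` expresses antibody-enriched qPCR signal relative to a
#' 1% input aliquot after IgG background subtraction,
#' `(ab - igg) / input_1pct`. `h3_normalized()` normalizes an H3K27me3
#' signal to total histone H3 occupancy,
#' `(k27 - igg) / (h3 - igg)`. Negative numerators are clamped to 0 with
#' a warning (background exceeding signal).
#'
#' @param ab,igg,input_1pct,k27_ab,h3_ab Numeric qPCR quantities.
#' @return Numeric vector of fractions (ratios).
#' @examples
#' percent_input(3, 1, 4) # 0.5
#' h3_normalized(5, 1, 9) # 0.5
#' @export
percent_input <- function(ab, igg, input_1pct) {
  if (any(input_1pct <= 0)) abort("input_1pct must be positive")
  num <- ab - igg
  if (any(num < 0)) {
    warn("percent_input: negative (ab - igg) clamped to 0")
    num <- pmax(num, 0)
  }
  num / input_1pct
}

#' @rdname percent_input
#' @export
h3_normalized <- function(k27_ab, igg, h3_ab) {
  den <- h3_ab - igg
  if (any(den == 0)) abort("h3_normalized: (h3 - igg) must be non-zero")
  num <- k27_ab - igg
  if (any(num < 0)) {
    warn("h3_normalized: negative (k27 - igg) clamped to 0")
    num <- pmax(num, 0)
  }
  num / den
}
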