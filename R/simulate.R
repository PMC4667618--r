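#' Simulation configuration
#'
#' Builds the configuration for the synthetic paired ChIP-seq experiment
#' generator. The generator emulates the statistical structure of a paired
#' wild-type/mutant broad-mark experiment: a genome with non-overlapping
#' genes and repeat elements, planted enriched islands with per-island true
#' fold changes between the two conditions, Poisson tag emission, peak
#' summits with planted sequence motifs, and probe-set level expression
#' coupled to decreased-mark genes.
#'
#' Tag emission is per-bp Poisson: rate `background_rate` outside islands
#' and `background_rate * enrichment_fold * fc` inside, where `fc` is 1 for
#' the wild-type sample and the island's `mutant_fc` for the mutant.
#'
#' @param seed Integer seed; all generator functions are deterministic
#'   given the configuration.
#' @param n_chrom,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Total number of genes, spread evenly over chromosomes.
#' @param n_islands Total number of planted islands.
#' @param island_length_range Length range (bp) of planted islands.
#' @param intergenic_island_frac Fraction of islands placed midway between
#'   genes rather than centred on a TSS.
#' @param background_rate Background emission rate, tags per bp.
#' @param enrichment_fold Island enrichment over background (wild type).
#' @param mutant_fc True per-island mutant/wild-type rate ratio; recycled
#'   over islands, so `c(0.3, 1)` alternates decreased and unchanged
#'   islands.
#' @param repeat_density Fraction of the genome covered by repeat elements.
#' @param repeat_length Length (bp) of each repeat element.
#' @param depth_factor Named per-sample sequencing-depth multipliers.
#' @param read_length,fragment_length Read length and fragment extension
#'   length (bp) the libraries emulate.
#' @param motif_plant `NULL`, or a list with elements `motif` (string),
#'   `count` (copies planted per peak) and `window` (half-window, bp,
#'   around each summit within which copies are planted). Planting
#'   replaces bases, so coordinates never shift.
#' @param expr_coupling_prob Probability that a gene under a decreased-mark
#'   island receives a planted expression increase in the mutant.
#' @param expr_shift_fold Linear fold change planted in coupled genes.
#' @param expr_noise_sd Standard deviation (log2) of expression noise.
#' @param probe_sets_per_gene Integer vector sampled from for the number of
#'   probe sets representing each gene.
#' @param with_sequence Generate random genome sequence (needed for motif
#'   work; switch off for large tag-level simulations).
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_islands = 10)
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 1L,
                       chrom_length = 1e6,
                       n_genes = 40L,
                       n_islands = 20L,
                       island_length_range = c(1000, 3000),
                       intergenic_island_frac = 0.2,
                       background_rate = 0.005,
                       enrichment_fold = 20,
                       mutant_fc = 1,
                       repeat_density = 0.05,
                       repeat_length = 300L,
                       depth_factor = c(wt = 1, mut = 1),
                       read_length = 36L,
                       fragment_length = 200L,
                       motif_plant = NULL,
                       expr_coupling_prob = 0.88,
                       expr_shift_fold = 8,
                       expr_noise_sd = 0.2,
                       probe_sets_per_gene = 1:3,
                       with_sequence = TRUE) {
  stopifnot(background_rate > 0, enrichment_fold > 0, all(mutant_fc > 0),
            repeat_density >= 0, repeat_density <= 1,
            expr_coupling_prob >= 0, expr_coupling_prob <= 1,
            intergenic_island_frac >= 0, intergenic_island_frac <= 1,
            length(island_length_range) == 2,
            island_length_range[1] <= island_length_range[2],
            fragment_length >= read_length, all(depth_factor > 0))
  if (any(enrichment_fold * mutant_fc < 1)) {
    abort("enrichment_fold * mutant_fc must be >= 1 so island rates are above background")
  }
  structure(list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length = chrom_length, n_genes = as.integer(n_genes),
    n_islands = as.integer(n_islands),
    island_length_range = island_length_range,
    intergenic_island_frac = intergenic_island_frac,
    background_rate = background_rate, enrichment_fold = enrichment_fold,
    mutant_fc = mutant_fc, repeat_density = repeat_density,
    repeat_length = as.integer(repeat_length), depth_factor = depth_factor,
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    motif_plant = motif_plant, expr_coupling_prob = expr_coupling_prob,
    expr_shift_fold = expr_shift_fold, expr_noise_sd = expr_noise_sd,
    probe_sets_per_gene = probe_sets_per_gene,
    with_sequence = isTRUE(with_sequence)
  ), class = "sim_config")
}

#' Simulate a genome model with planted islands
#'
#' Generates chromosome sizes, non-overlapping genes, repeat-element
#' intervals, planted islands (each assigned to a gene's TSS or to
#' intergenic space) with their true mutant fold changes, peak summits at
#' island centres, and (optionally) random genome sequence with planted
#' motif copies around each summit.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome` with elements `config`,
#'   `chrom_sizes`, `genes`, `repeats`, `islands`, `peaks`, `sequence`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  chrom_sizes <- tibble(chrom = chroms, length = config$chrom_length)

  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  genes <- purrr::map2_dfr(chroms, per_chrom, function(cc, ng) {
    if (ng == 0) return(tibble())
    spacing <- config$chrom_length / ng
    max_island <- config$island_length_range[2]
    if (spacing < 2 * max_island + 12000) {
      abort("infeasible packing: too many genes/islands for the chromosome length")
    }
    anchor <- (seq_len(ng) - 0.5) * spacing
    tss <- round(anchor + runif(ng, -0.05, 0.05) * spacing)
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    gene_len <- round(runif(ng, 2000, 8000))
    body_end <- ifelse(strand == "+", pmin(tss + gene_len, config$chrom_length),
                       pmax(tss - gene_len, 0))
    tibble(chrom = cc, tss = tss, strand = strand, body_end = body_end,
           anchor = anchor, spacing = spacing)
  })
  genes$gene_id <- sprintf("gene%03d", seq_len(nrow(genes)))
  genes <- genes[c("gene_id", "chrom", "tss", "strand", "body_end", "anchor", "spacing")]

  n_intergenic <- round(config$n_islands * config$intergenic_island_frac)
  n_genic <- config$n_islands - n_intergenic
  if (n_genic > nrow(genes)) {
    abort("infeasible packing: more TSS-assigned islands than genes")
  }
  genic_genes <- sort(sample.int(nrow(genes), n_genic))
  len <- round(runif(config$n_islands, config$island_length_range[1],
                     config$island_length_range[2]))
  islands_genic <- tibble(
    chrom = genes$chrom[genic_genes],
    center = genes$tss[genic_genes],
    gene_id = genes$gene_id[genic_genes]
  )
  # intergenic islands sit at gene-slot boundaries, far from every TSS
  islands_inter <- if (n_intergenic > 0) {
    slots <- genes %>%
      group_by(.data$chrom) %>%
      summarise(boundary = list(.data$anchor + .data$spacing / 2), .groups = "drop") %>%
      tidyr::unnest("boundary") %>%
      filter(.data$boundary < config$chrom_length - config$island_length_range[2])
    pick <- slots[sort(sample.int(nrow(slots), min(n_intergenic, nrow(slots)))), ]
    tibble(chrom = pick$chrom, center = round(pick$boundary), gene_id = NA_character_)
  } else tibble()
  islands <- bind_rows(islands_genic, islands_inter)
  islands$length <- len[seq_len(nrow(islands))]
  islands <- islands %>%
    mutate(start = pmax(0, .data$center - floor(.data$length / 2)),
           end = .data$start + .data$length) %>%
    arrange(.data$chrom, .data$start)
  islands$island_id <- sprintf("isl%03d", seq_len(nrow(islands)))
  islands$mutant_fc <- rep_len(config$mutant_fc, nrow(islands))
  islands <- islands[c("island_id", "chrom", "start", "end", "gene_id", "mutant_fc")]
  ovl <- islands %>% group_by(.data$chrom) %>%
    summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()]), .groups = "drop")
  if (any(ovl$bad, na.rm = TRUE)) {
    abort("infeasible packing: planted islands overlap; reduce n_islands or island length")
  }

  repeats <- purrr::map_dfr(chroms, function(cc) {
    n_slots <- floor(config$chrom_length / config$repeat_length)
    n_rep <- round(config$repeat_density * config$chrom_length / config$repeat_length)
    if (n_rep == 0) return(tibble())
    slot <- sort(sample.int(n_slots, n_rep))
    tibble(chrom = cc,
           start = (slot - 1) * config$repeat_length,
           end = (slot - 1) * config$repeat_length + config$repeat_length,
           class = sample(c("SINE", "LINE", "LTR", "satellite"), n_rep, replace = TRUE))
  })

  peaks <- islands %>%
    mutate(summit = floor((.data$start + .data$end) / 2)) %>%
    select("island_id", "chrom", "summit")

  sequence <- NULL
  if (config$with_sequence) {
    sequence <- setNames(vapply(chroms, function(cc) {
      paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
            collapse = "")
    }, ""), chroms)
    if (!is.null(config$motif_plant)) {
      mp <- config$motif_plant
      k <- nchar(mp$motif)
      for (i in seq_len(nrow(peaks))) {
        cc <- peaks$chrom[i]; s <- peaks$summit[i]
        # non-overlapping offsets within the summit window; replacement, not insertion
        slots <- seq(max(0, s - mp$window), min(config$chrom_length - k, s + mp$window - k), by = k)
        at <- sample(slots, min(mp$count, length(slots)))
        for (p in at) {
          substr(sequence[[cc]], p + 1, p + k) <- mp$motif
        }
      }
    }
  }

  structure(list(config = config, chrom_sizes = chrom_sizes,
                 genes = genes[setdiff(names(genes), c("anchor", "spacing"))],
                 repeats = repeats, islands = islands, peaks = peaks,
                 sequence = sequence),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> ", nrow(x$chrom_sizes), " chromosome(s) of ",
      format(x$config$chrom_length, big.mark = ","), " bp; ",
      nrow(x$genes), " genes, ", nrow(x$islands), " planted islands, ",
      nrow(x$repeats), " repeat elements\n", sep = "")
  invisible(x)
}

#' Simulate a tag library for one sample
#'
#' Draws single-position stranded reads under the per-bp Poisson emission
#' model of [sim_config()]: `background_rate * depth` everywhere, times
#' `enrichment_fold * fc` inside planted islands, with `fc = 1` for
#' `"wt"` and the island's `mutant_fc` for `"mut"`. Strands are uniform.
#'
#' @param genome A [simulate_genome()] result.
#' @param sample `"wt"` or `"mut"`.
#' @param seed Integer seed; defaults to a sample-specific offset of the
#'   configuration seed so the two libraries are independent but
#'   reproducible.
#' @return A read tibble with `chrom`, `pos` (0-based 5' position) and
#'   `strand`; the library size is the number of rows.
#' @export
simulate_tags <- function(genome, sample = c("wt", "mut"), seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  sample <- match.arg(sample)
  cfg <- genome$config
  if (is.null(seed)) seed <- cfg$seed + 7919L * match(sample, c("wt", "mut"))
  set.seed(seed)
  depth <- cfg$depth_factor[[sample]] %||% 1
  lambda0 <- cfg$background_rate * depth

  bg <- purrr::map_dfr(seq_len(nrow(genome$chrom_sizes)), function(i) {
    L <- genome$chrom_sizes$length[i]
    n <- rpois(1, lambda0 * L)
    tibble(chrom = genome$chrom_sizes$chrom[i],
           pos = floor(runif(n, 0, L)))
  })
  isl <- genome$islands
  fc <- if (sample == "wt") rep(1, nrow(isl)) else isl$mutant_fc
  extra_rate <- lambda0 * (cfg$enrichment_fold * fc - 1) * (isl$end - isl$start)
  n_extra <- rpois(nrow(isl), extra_rate)
  extra <- tibble(
    chrom = rep(isl$chrom, n_extra),
    pos = floor(runif(sum(n_extra), rep(isl$start, n_extra), rep(isl$end, n_extra)))
  )
  reads <- bind_rows(bg, extra)
  reads$strand <- sample(c("+", "-"), nrow(reads), replace = TRUE)
  reads
}

#' Emit island and peak call fixtures from simulated libraries
#'
#' Stands in for an external island/peak caller on synthetic data: the
#' planted intervals become island calls carrying the realized tag counts
#' (reads whose 5' position falls inside the interval) and a synthetic
#' density score; peak calls carry the planted summits. A ground-truth
#' table records each island's gene assignment, true fold change and the
#' differential label implied by the `> 1.8` fold-change criterion.
#'
#' @param genome A [simulate_genome()] result.
#' @param libraries Named list of read tibbles (e.g. `list(wt = ..., mut = ...)`).
#' @param outdir Optional directory; when given, island tables, peak tables
#'   and the ground-truth sidecar are written as tab-delimited files.
#' @param threshold Fold-change threshold used for the true labels.
#' @return A list with `islands` (named list of island tibbles), `peaks`
#'   (named list of peak tibbles) and `ground_truth`.
#' @export
emit_calls <- function(genome, libraries, outdir = NULL, threshold = 1.8) {
  stopifnot(inherits(genome, "sim_genome"), is.list(libraries),
            !is.null(names(libraries)))
  isl <- genome$islands
  count_in <- function(reads, regions) {
    if (nrow(regions) == 0) return(integer(0))
    hits <- GenomicRanges::countOverlaps(
      regions_to_gr(regions), points_to_gr(reads$chrom, reads$pos))
    as.integer(hits)
  }
  islands <- purrr::imap(libraries, function(reads, nm) {
    out <- isl[c("chrom", "start", "end")]
    out$tag_count <- count_in(reads, out)
    out$score <- round(out$tag_count / (out$end - out$start) * 1000, 1)
    out
  })
  peak_regions <- genome$peaks %>%
    mutate(start = pmax(0, .data$summit - 150), end = .data$summit + 151)
  peaks <- purrr::imap(libraries, function(reads, nm) {
    out <- peak_regions[c("chrom", "start", "end", "summit")]
    out$tag_count <- count_in(reads, out)
    out$p_value <- 1e-9
    out
  })
  truth <- isl %>%
    mutate(true_label = dplyr::case_when(
      1 / .data$mutant_fc > threshold ~ "decreased",
      .data$mutant_fc > threshold ~ "increased",
      TRUE ~ "unchanged"))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(libraries)) {
      write_intervals(islands[[nm]], file.path(outdir, paste0("islands_", nm, ".tsv")),
                      format = "island_table")
      write_intervals(peaks[[nm]], file.path(outdir, paste0("peaks_", nm, ".tsv")),
                      format = "peak_table")
    }
    readr::write_tsv(truth, file.path(outdir, "ground_truth.tsv"))
  }
  list(islands = islands, peaks = peaks, ground_truth = truth)
}

#' Simulate probe-set expression coupled to decreased-mark genes
#'
#' Each gene is represented by 1-3 probe sets with a log2 baseline. Genes
#' assigned to planted islands with `mutant_fc < 1` are flagged "coupled"
#' with probability `expr_coupling_prob`; coupled genes receive a planted
#' mutant expression increase of `log2(expr_shift_fold)` (default 8-fold,
#' comfortably beyond a 4-fold dynamic-range filter), all other genes only
#' noise.
#'
#' @param genome A [simulate_genome()] result.
#' @param seed Integer seed; defaults to an offset of the configuration seed.
#' @return A list with `expression` (tibble: `probe_set`, `gene_id`, `wt`,
#'   `mut`, log2 scale) and `truth` (tibble: `gene_id`, `decreased_mark`,
#'   `coupled`).
#' @export
simulate_expression <- function(genome, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  cfg <- genome$config
  if (is.null(seed)) seed <- cfg$seed + 104729L
  set.seed(seed)
  genes <- genome$genes
  dec_genes <- genome$islands %>%
    filter(!is.na(.data$gene_id), .data$mutant_fc < 1) %>%
    pull("gene_id")
  truth <- tibble(gene_id = genes$gene_id,
                  decreased_mark = genes$gene_id %in% dec_genes)
  truth$coupled <- truth$decreased_mark &
    runif(nrow(truth)) < cfg$expr_coupling_prob
  n_probes <- sample(cfg$probe_sets_per_gene, nrow(genes), replace = TRUE)
  expression <- tibble(
    gene_id = rep(genes$gene_id, n_probes)
  ) %>%
    group_by(.data$gene_id) %>%
    mutate(probe_set = paste0(.data$gene_id, "_ps", row_number())) %>%
    ungroup() %>%
    left_join(truth, by = "gene_id")
  base <- rnorm(nrow(expression), mean = 7, sd = 1)
  shift <- ifelse(expression$coupled,
                  log2(cfg$expr_shift_fold) + rnorm(nrow(expression), 0, cfg$expr_noise_sd),
                  rnorm(nrow(expression), 0, cfg$expr_noise_sd))
  expression$wt <- base
  expression$mut <- base + shift
  list(expression = expression[c("probe_set", "gene_id", "wt", "mut")],
       truth = truth)
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_tags()] for
#' both samples, [emit_calls()] and [simulate_expression()].
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory passed to [emit_calls()].
#' @return A list with `genome`, `libraries`, `calls`, `expression`.
#' @export
simulate_experiment <- function(config, outdir = NULL) {
  genome <- simulate_genome(config)
  libraries <- list(wt = simulate_tags(genome, "wt"),
                    mut = simulate_tags(genome, "mut"))
  calls <- emit_calls(genome, libraries, outdir = outdir)
  expression <- simulate_expression(genome)
  if (!is.null(outdir)) {
    write_tss_table(genome$genes, file.path(outdir, "genes.tsv"))
    write_expression(expression$expression, file.path(outdir, "expression.tsv"))
  }
  list(genome = genome, libraries = libraries, calls = calls,
       expression = expression)
}
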