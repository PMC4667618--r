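#' The GGGA/GGAA motif set with complements
#'
#' The short G-rich motifs bound by Ikaros-family zinc fingers, together
#' with their complements so that one forward-strand scan covers both
#' strands.
#'
#' @return Character vector `c("GGGA", "GGAA", "TCCC", "TTCC")`.
#' @export
ikaros_motifs <- function() c("GGGA", "GGAA", "TCCC", "TTCC")

#' Count motif occurrences in sequences
#'
#' Counts all occurrences of any motif in the set, vectorized over
#' sequences. Overlapping occurrences are counted (e.g. `"GGGAA"`
#' contains both GGGA and GGAA); `N` never matches.
#'
#' @param sequences Character vector of sequences over `A,C,G,T,N`.
#' @param motifs Character vector of motifs.
#' @return Integer vector of counts, one per sequence.
#' @examples
#' count_motifs("GGGAA") # 2
#' @export
count_motifs <- function(sequences, motifs = ikaros_motifs()) {
  stopifnot(length(motifs) >= 1, all(nzchar(motifs)))
  pat <- paste0("(?=", paste(toupper(motifs), collapse = "|"), ")")
  as.integer(stringr::str_count(toupper(sequences), stringr::regex(pat)))
}

# Integer encoding for the fast permutation path: A,C,G,T,N -> 0..4.
# k-mers are coded in base 5, so any k-mer containing N can never equal
# the code of an N-free motif.
encode_seq <- function(x) {
  m <- match(strsplit(x, "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(m)) abort("sequence contains characters outside A,C,G,T,N")
  m
}

kmer_codes <- function(mat_or_vec, k) {
  if (is.matrix(mat_or_vec)) {
    L <- ncol(mat_or_vec)
    v <- mat_or_vec[, 1:(L - k + 1), drop = FALSE]
    for (j in 2:k) v <- v + 5L^(j - 1) * mat_or_vec[, j:(L - k + j), drop = FALSE]
    v
  } else {
    L <- length(mat_or_vec)
    v <- mat_or_vec[1:(L - k + 1)]
    for (j in 2:k) v <- v + 5L^(j - 1) * mat_or_vec[j:(L - k + j)]
    v
  }
}

#' Extract summit-centred sequence windows
#'
#' Cuts a window of `half_window` bp on each side of every peak summit
#' (301 bp total at the default 150) from the chromosome sequences,
#' clipping at chromosome ends (clipped windows are flagged and
#' reported).
#'
#' @param peaks Peak tibble with `chrom` and `summit` (0-based bp).
#' @param sequences Named character vector of chromosome sequences, as
#'   from [read_fasta()].
#' @param half_window Half-window size, bp.
#' @return A tibble with `chrom`, `summit`, `start`, `end`, `offset` (the
#'   summit's 0-based position inside the window), `clipped` and `seq`.
#' @export
extract_windows <- function(peaks, sequences, half_window = 150L) {
  stopifnot(all(c("chrom", "summit") %in% names(peaks)),
            all(peaks$chrom %in% names(sequences)))
  L <- setNames(nchar(sequences), names(sequences))[peaks$chrom]
  start <- pmax(0, peaks$summit - half_window)
  end <- pmin(L, peaks$summit + half_window + 1)
  clipped <- start != peaks$summit - half_window |
    end != peaks$summit + half_window + 1
  if (any(clipped)) {
    inform(paste0("extract_windows: ", sum(clipped),
                  " window(s) clipped at chromosome ends"))
  }
  tibble(chrom = peaks$chrom, summit = peaks$summit,
         start = unname(start), end = as.numeric(unname(end)),
         offset = unname(peaks$summit - start),
         clipped = unname(clipped),
         seq = unname(substring(sequences[peaks$chrom], start + 1, end)))
}

#' Composition-preserving permutation null for motif counts
#'
#' Shuffles each window's bases uniformly (the base composition of every
#' shuffle is exactly the window's own) `n_permutations` times and counts
#' motif-set occurrences in every shuffle. The null mean is the grand
#' mean count per window.
#'
#' @param windows Character vector of window sequences, or the tibble
#'   from [extract_windows()].
#' @param n_permutations Number of shuffles per window (at least 1).
#' @param seed Integer seed (required).
#' @param motifs Motif set; all motifs must share one length.
#' @return A list with `null_counts` (matrix, windows x permutations),
#'   `null_mean` (grand mean per window) and `per_window_mean`.
#' @export
permutation_null <- function(windows, n_permutations = 100L, seed,
                             motifs = ikaros_motifs()) {
  if (is.data.frame(windows)) windows <- windows$seq
  stopifnot(n_permutations >= 1, length(windows) >= 1)
  k <- unique(nchar(motifs))
  if (length(k) != 1) abort("motifs must share one length")
  set.seed(seed)
  codes <- vapply(motifs, function(m) {
    sum(encode_seq(m) * 5^(seq_len(k) - 1))
  }, 0)
  null_counts <- matrix(0L, nrow = length(windows), ncol = n_permutations)
  for (w in seq_along(windows)) {
    wint <- encode_seq(windows[w])
    L <- length(wint)
    if (L < k) next
    perm <- matrix(0L, nrow = n_permutations, ncol = L)
    for (p in seq_len(n_permutations)) perm[p, ] <- wint[sample.int(L)]
    v <- kmer_codes(perm, k)
    hit <- matrix(v %in% codes, nrow = n_permutations)
    null_counts[w, ] <- as.integer(rowSums(hit))
  }
  list(null_counts = null_counts,
       null_mean = mean(null_counts),
       per_window_mean = rowMeans(null_counts))
}

#' One-cell chi-squared goodness of fit
#'
#' The pooled goodness-of-fit statistic `(obs - exp)^2 / exp` on summed
#' motif counts, referred to a chi-squared distribution with 1 degree of
#' freedom (deviations in either direction increase the statistic, so
#' the upper-tail p-value is two-sided in the fold-change sense).
#'
#' @param observed_total,expected_total Summed observed and
#'   null-expected counts; `expected_total > 0`.
#' @return A list with `statistic` and `p_value`.
#' @examples
#' chi2_enrichment(20, 10) # statistic 10
#' @export
chi2_enrichment <- function(observed_total, expected_total) {
  if (expected_total <= 0) {
    abort("expected_total must be positive (observed counts with zero expectation)")
  }
  statistic <- (observed_total - expected_total)^2 / expected_total
  list(statistic = statistic,
       p_value = pchisq(statistic, df = 1, lower.tail = FALSE))
}

#' Summit-centred motif-density enrichment test
#'
#' Counts motif-set occurrences in summit-centred windows, builds a
#' composition-preserving permutation null per window, and tests whether
#' the pooled observed count deviates from the pooled null expectation
#' with a chi-squared statistic (1 df).
#'
#' Two statistic constructions are available. The default,
#' `"perm_var"`, divides the squared deviation by the permutation-
#' estimated null variance (inflated by `1 + 1/n_permutations` for the
#' noise in the estimated expectation); it is calibrated even though
#' overlapping motif occurrences are clumped relative to Poisson.
#' `"gof"` is the classical one-cell goodness of fit of
#' [chi2_enrichment()], which divides by the expectation itself and is
#' mildly anticonservative for clumped counts.
#'
#' @param peaks Peak tibble with `chrom` and `summit`, or a precomputed
#'   window tibble from [extract_windows()] (then `sequences` is ignored).
#' @param sequences Named character vector of chromosome sequences.
#' @param motifs Motif set (equal lengths).
#' @param half_window Half-window around summits, bp.
#' @param n_permutations Shuffles per window.
#' @param seed Integer seed (required).
#' @param method `"perm_var"` or `"gof"` (see above).
#' @return An object of class `motif_enrichment`.
#' @export
motif_enrichment <- function(peaks, sequences = NULL,
                             motifs = ikaros_motifs(), half_window = 150L,
                             n_permutations = 100L, seed,
                             method = c("perm_var", "gof")) {
  method <- match.arg(method)
  windows <- if (is.data.frame(peaks) && "seq" %in% names(peaks)) peaks else
    extract_windows(peaks, sequences, half_window)
  obs <- count_motifs(windows$seq, motifs)
  null <- permutation_null(windows$seq, n_permutations, seed, motifs)
  n <- nrow(windows)
  observed_total <- sum(obs)
  perm_totals <- colSums(null$null_counts)
  expected_total <- mean(perm_totals)
  if (method == "gof") {
    test <- chi2_enrichment(observed_total, expected_total)
  } else {
    v <- var(perm_totals) * (1 + 1 / n_permutations)
    if (v == 0) {
      statistic <- if (observed_total == expected_total) 0 else Inf
    } else {
      statistic <- (observed_total - expected_total)^2 / v
    }
    test <- list(statistic = statistic,
                 p_value = pchisq(statistic, df = 1, lower.tail = FALSE))
  }
  structure(list(
    motifs = motifs, window_bp = half_window, n_windows = n,
    observed_counts = obs, observed_mean = observed_total / n,
    null_mean = null$null_mean, per_window_null_mean = null$per_window_mean,
    observed_total = observed_total, expected_total = expected_total,
    n_permutations = n_permutations, method = method,
    chi2_statistic = test$statistic, p_value = test$p_value, seed = seed
  ), class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat("<motif_enrichment> ", paste(x$motifs, collapse = "/"), " in ",
      x$n_windows, " windows of ", 2 * x$window_bp + 1, " bp\n",
      "  observed mean ", signif(x$observed_mean, 4), " vs null mean ",
      signif(x$null_mean, 4), " per window (", x$n_permutations,
      " permutations)\n  chi-squared = ", signif(x$chi2_statistic, 4),
      " (", x$method, "), p = ", format.pval(x$p_value, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' @rdname motif_enrichment
#' @param x A `motif_enrichment` object.
#' @param ... Unused.
#' @export
tidy.motif_enrichment <- function(x, ...) {
  tibble(window = seq_len(x$n_windows),
         observed = x$observed_counts,
         null_mean = x$per_window_null_mean)
}

#' @rdname motif_enrichment
#' @export
glance.motif_enrichment <- function(x, ...) {
  tibble(n_windows = x$n_windows, window_bp = x$window_bp,
         observed_mean = x$observed_mean, null_mean = x$null_mean,
         n_permutations = x$n_permutations, method = x$method,
         statistic = x$chi2_statistic, p_value = x$p_value, seed = x$seed)
}

#' Scan for a consensus core motif near summits
#'
#' Scans both strands of summit-centred windows for a fixed-length
#' consensus pattern (default the Ikaros core `AGGAA[AG]`), keeping
#' matches whose leftmost base lies within `half_window` bp of the
#' summit. Reverse-strand matches are found by scanning the reverse
#' complement and mapped back to forward-strand offsets.
#'
#' @param windows Window tibble from [extract_windows()] (needs `seq` and
#'   `offset`), or a character vector (summit assumed at the centre).
#' @param pattern Regular-expression consensus of fixed match length.
#' @param half_window Maximum |offset| from the summit, bp.
#' @return A tibble with `window`, `strand`, `offset` (match start
#'   relative to the summit) and `match`.
#' @export
scan_core_motif <- function(windows, pattern = "AGGAA[AG]", half_window = 40L) {
  if (is.character(windows)) {
    windows <- tibble(seq = windows, offset = floor((nchar(windows) - 1) / 2))
  }
  stopifnot(all(c("seq", "offset") %in% names(windows)))
  seqs <- toupper(windows$seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  one_strand <- function(subject, strand) {
    m <- gregexpr(pattern, subject, perl = TRUE)
    purrr::imap_dfr(m, function(mm, i) {
      starts <- as.integer(mm)
      if (length(starts) == 0 || starts[1] == -1) return(tibble())
      lens <- attr(mm, "match.length")
      L <- nchar(subject[i])
      if (strand == "-") {
        # map reverse-complement coordinates back to the forward strand
        starts_fwd <- L - starts - lens + 2L
        match_str <- substring(rc[i], starts, starts + lens - 1)
        starts <- starts_fwd
      } else {
        match_str <- substring(subject[i], starts, starts + lens - 1)
      }
      tibble(window = i, strand = strand, offset = starts - 1L - windows$offset[i],
             match = match_str)
    })
  }
  out <- bind_rows(one_strand(seqs, "+"), one_strand(rc, "-"))
  if (nrow(out) == 0) {
    return(tibble(window = integer(), strand = character(),
                  offset = integer(), match = character()))
  }
  out %>%
    filter(abs(.data$offset) <= half_window) %>%
    arrange(.data$window, .data$offset, .data$strand)
}
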