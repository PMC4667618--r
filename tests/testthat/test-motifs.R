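test_that("motif counting counts overlapping hits and ignores N", {
  expect_equal(count_motifs("GGAA"), 1L)
  expect_equal(count_motifs("GGGAA"), 2L) # GGGA at 0, GGAA at 1
  expect_equal(count_motifs("TTTT"), 0L)
  expect_equal(count_motifs("GGNA"), 0L)
  expect_equal(count_motifs(c("GGAA", "TCCC")), c(1L, 1L))

  # exhaustive substring oracle on random sequences
  set.seed(71)
  seqs <- rand_seq(40, 120)
  expect_equal(count_motifs(seqs),
               vapply(seqs, bf_count_motifs, 0L, motifs = ikaros_motifs(),
                      USE.NAMES = FALSE))

  # complement-closed set is invariant under reverse complement
  rc <- vapply(strsplit(chartr("ACGT", "TGCA", seqs), ""), function(x) {
    paste(rev(x), collapse = "")
  }, "")
  expect_equal(count_motifs(rc), count_motifs(seqs))
})

test_that("summit windows are 2*half+1 bp, clipped at chromosome ends", {
  seqs <- c(chrA = paste(rep("ACGT", 100), collapse = "")) # 400 bp
  peaks <- tibble::tibble(chrom = "chrA", summit = c(200, 10, 390))
  expect_message(w <- extract_windows(peaks, seqs, 150), "clipped")
  expect_equal(nchar(w$seq), c(301, 161, 160)) # right clip loses base 400
  expect_equal(w$clipped, c(FALSE, TRUE, TRUE))
  expect_equal(w$offset, c(150, 10, 150))
  # direct slice oracle
  expect_equal(w$seq[1], substr(seqs[["chrA"]], 51, 351))
  expect_equal(w$seq[2], substr(seqs[["chrA"]], 1, 161))
})

test_that("permutation null preserves composition exactly and is reproducible", {
  # no G -> null count for G motifs is always 0
  null0 <- permutation_null(strrep("A", 50), n_permutations = 20, seed = 3,
                            motifs = c("GGGA", "GGAA"))
  expect_true(all(null0$null_counts == 0))

  set.seed(73)
  wins <- rand_seq(5, 80)
  n1 <- permutation_null(wins, 10, seed = 9)
  n2 <- permutation_null(wins, 10, seed = 9)
  expect_identical(n1$null_counts, n2$null_counts)
  expect_equal(dim(n1$null_counts), c(5, 10))

  # closed-form null mean for iid-uniform windows: (L-3) * sum p(motif)
  set.seed(79)
  uw <- rand_seq(60, 200)
  nn <- permutation_null(uw, 25, seed = 5)
  expected <- (200 - 3) * 4 / 256
  n_total <- length(nn$null_counts)
  se <- sqrt(1.25 * expected / n_total) # ~Poisson scale with clumping slack
  expect_lt(abs(nn$null_mean - expected), 3 * se + 0.05)
})

test_that("one-cell chi-squared goodness of fit follows the closed form", {
  eq <- chi2_enrichment(10, 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  up <- chi2_enrichment(20, 10)
  expect_equal(up$statistic, 10)
  expect_equal(up$p_value, pchisq(10, 1, lower.tail = FALSE))
  expect_error(chi2_enrichment(5, 0), "positive")
})

test_that("planted motifs are detected with the stated effect size and p-value", {
  # one GGAA planted per window over a G-poor background, n = 200 windows
  set.seed(83)
  n <- 200
  wins <- rand_seq(n, 301, alphabet = c(rep(c("A", "C", "T"), 7), "G"))
  at <- sample(100, n, replace = TRUE)
  substr(wins, at, at + 3) <- "GGAA"
  win_tbl <- tibble::tibble(seq = wins, offset = 150)
  res <- motif_enrichment(win_tbl, motifs = c("GGGA", "GGAA"),
                          n_permutations = 30, seed = 17)
  k <- n # one planted motif per window
  expect_gte(res$observed_mean - res$null_mean, 0.9 * k / n)
  expect_lt(res$p_value, 0.01)

  # the goodness-of-fit construction agrees on direction
  res_gof <- motif_enrichment(win_tbl, motifs = c("GGGA", "GGAA"),
                              n_permutations = 30, seed = 17, method = "gof")
  expect_lt(res_gof$p_value, 0.01)
  expect_equal(res_gof$chi2_statistic,
               (res_gof$observed_total - res_gof$expected_total)^2 /
                 res_gof$expected_total)

  expect_equal(nrow(tidy(res)), n)
  expect_equal(glance(res)$n_windows, n)
})

test_that("core-motif scanning finds both strands near the summit", {
  pad <- function(left, core, total = 301) {
    paste0(strrep("C", left), core, strrep("C", total - left - nchar(core)))
  }
  # AGGAAG with leftmost base at the summit (offset 0)
  w1 <- pad(150, "AGGAAG")
  hits1 <- scan_core_motif(w1)
  expect_equal(nrow(hits1), 1)
  expect_equal(hits1$strand, "+")
  expect_equal(hits1$offset, 0)
  expect_equal(hits1$match, "AGGAAG")

  # reverse-strand site: CTTCCT is the reverse complement of AGGAAG
  w2 <- pad(150, "CTTCCT")
  hits2 <- scan_core_motif(w2)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$offset, 0)

  # outside +/-40 bp of the summit -> no hit
  w3 <- pad(90, "AGGAAG")
  expect_equal(nrow(scan_core_motif(w3)), 0)

  # exhaustive regex-free oracle on random windows
  set.seed(89)
  wins <- rand_seq(30, 301)
  got <- scan_core_motif(wins)
  # forward-strand pattern, its strand label, and the match string the
  # scanner reports (the minus-strand sequence for "-" hits)
  pats <- list(c("AGGAAA", "+", "AGGAAA"), c("AGGAAG", "+", "AGGAAG"),
               c("TTTCCT", "-", "AGGAAA"), c("CTTCCT", "-", "AGGAAG"))
  bf <- do.call(rbind, lapply(seq_along(wins), function(i) {
    hits <- NULL
    for (p in pats) {
      for (s in 1:(301 - 5)) {
        if (substr(wins[i], s, s + 5) == p[1] && abs(s - 1 - 150) <= 40) {
          hits <- rbind(hits, data.frame(window = i, strand = p[2],
                                         offset = s - 1 - 150, match = p[3]))
        }
      }
    }
    hits
  }))
  if (is.null(bf)) bf <- data.frame(window = integer(), strand = character(),
                                    offset = integer(), match = character())
  bf <- bf[order(bf$window, bf$offset, bf$strand), ]
  rownames(bf) <- NULL
  got_df <- as.data.frame(got)
  got_df$offset <- as.integer(got_df$offset)
  expect_equal(got_df, bf, ignore_attr = TRUE)
})
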