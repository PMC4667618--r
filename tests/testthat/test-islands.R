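test_that("merging uses >=1 bp overlap with half-open abutment kept separate", {
  two <- tibble::tibble(chrom = "chr1", start = c(100, 150), end = c(200, 250))
  m <- merge_regions(list(two))
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 250))

  abut <- tibble::tibble(chrom = "chr1", start = c(100, 200), end = c(200, 300))
  expect_equal(nrow(merge_regions(list(abut))), 2)
})

test_that("merging equals brute-force union-find on 500 random intervals", {
  set.seed(17)
  sets <- list(rand_regions(250, max_len = 2000), rand_regions(250, max_len = 2000))
  m <- merge_regions(sets)
  bf <- bf_merge_regions(dplyr::bind_rows(sets))
  expect_equal(as.data.frame(m[c("chrom", "start", "end")]), as.data.frame(bf))
  # idempotent and order-independent over input sets
  expect_equal(merge_regions(list(m))[c("chrom", "start", "end")],
               m[c("chrom", "start", "end")])
  expect_equal(merge_regions(rev(sets)), m)
})

test_that("deep-design eligibility respects exact boundary semantics", {
  isl <- tibble::tibble(
    chrom = "chr1",
    start = 0, end = c(800, 800, 799, 400),
    tag_count = c(51, 50, 51, 51))
  # K27: length 800 / 51 tags / density 0.0638 kept; 50 tags removed;
  # 799 bp removed
  kept <- filter_eligible_dp(isl, mark = "H3K27me3")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$tag_count, 51)
  # density exactly at threshold is removed (strict >)
  at_thr <- tibble::tibble(chrom = "chr1", start = 0, end = 2000,
                           tag_count = 60) # density 0.03
  expect_equal(nrow(filter_eligible_dp(at_thr, "H3K27me3")), 0)
  at_thr$tag_count <- 61
  expect_equal(nrow(filter_eligible_dp(at_thr, "H3K27me3")), 1)
  # K4 thresholds: min 400 bp, density > 0.04
  k4 <- tibble::tibble(chrom = "chr1", start = 0, end = 400, tag_count = 51)
  expect_equal(nrow(filter_eligible_dp(k4, "H3K4me3")), 1)
  expect_error(filter_eligible_dp(k4, "H3K9me3"), "unknown mark")
})

test_that("subset eligibility enforces length/score/density and tolerates missing scores", {
  isl <- tibble::tibble(chrom = "chr1", start = 0,
                        end = c(800, 799, 800, 800),
                        tag_count = c(100, 100, 100, 32),
                        score = c(46, 46, 45, 46))
  out <- filter_eligible_subsets(isl)
  expect_equal(nrow(out), 1) # 799 bp fails, score 45 fails, density 33/800 fails
  isl$score <- NA_real_
  expect_warning(out2 <- filter_eligible_subsets(isl), "score")
  expect_equal(nrow(out2), 2) # score clause skipped; length+density still apply
})

test_that("both eligibility filters match a brute-force rule scan on a random fixture", {
  set.seed(23)
  isl <- rand_regions(300, min_len = 200, max_len = 3000)
  isl$tag_count <- floor(runif(300, 0, 200))
  isl$score <- round(runif(300, 0, 100), 1)
  len <- isl$end - isl$start

  dp <- filter_eligible_dp(isl, "H3K27me3")
  bf_dp <- isl[len >= 800 & isl$tag_count > 50 & isl$tag_count / len > 0.03, ]
  expect_equal(as.data.frame(dp), as.data.frame(bf_dp))

  ss <- filter_eligible_subsets(isl)
  bf_ss <- isl[len >= 800 & isl$score > 45 & isl$tag_count / len > 0.04, ]
  expect_equal(as.data.frame(ss), as.data.frame(bf_ss))
})

test_that("artifact exclusion applies the three rules with exact boundaries", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 50000,
                          strand = "+", body_end = 60000)
  # 1,200 bp region exactly 5,000 bp from the TSS: kept (needs > 5 kb)
  r_keep <- tibble::tibble(chrom = "chr1", start = 43801, end = 45001)
  # same size one bp farther: removed
  r_far <- tibble::tibble(chrom = "chr1", start = 43800, end = 45000)
  out <- exclude_artifacts(dplyr::bind_rows(r_keep, r_far), genes,
                           input_track = c(0, 0))
  expect_equal(nrow(out$kept), 1)
  expect_equal(out$kept$start, 43801)
  expect_equal(out$excluded$reason, "small_tss_distal")

  # tail rule: 1,500 bp region 3 kb from a 4,500 bp region -> removed
  tail_fix <- tibble::tibble(chrom = "chr1",
                             start = c(40000, 44500), end = c(41500, 49000))
  out2 <- exclude_artifacts(tail_fix, genes, input_track = c(0, 0))
  expect_equal(out2$excluded$start, 40000)
  expect_equal(out2$excluded$reason, "island_tail")

  # input rule: normalized input density > 0.024
  r <- tibble::tibble(chrom = "chr1", start = 49000, end = 51000)
  out3 <- exclude_artifacts(r, genes, input_track = 49) # 0.0245 > 0.024
  expect_equal(out3$excluded$reason, "high_input")
  out4 <- exclude_artifacts(r, genes, input_track = 48) # 0.024, not strict
  expect_equal(nrow(out4$excluded), 0)
})

test_that("artifact exclusion partitions the input and matches a brute-force scan", {
  set.seed(29)
  merged <- rand_regions(200, chroms = "chr1", max_pos = 2e5, min_len = 300,
                         max_len = 6000)
  merged <- merge_regions(list(merged)) # disjoint, like real merged regions
  genes <- tibble::tibble(gene_id = paste0("g", 1:12), chrom = "chr1",
                          tss = floor(runif(12, 0, 2e5)), strand = "+",
                          body_end = 2e5 + 1000)
  genes$body_end <- genes$tss + 5000
  input <- runif(nrow(merged), 0, 80)
  out <- exclude_artifacts(merged, genes, input)

  len <- merged$end - merged$start
  bf_reason <- vapply(seq_len(nrow(merged)), function(i) {
    d_tss <- min(vapply(seq_len(nrow(genes)), function(j) {
      bf_edge_dist(merged$start[i], merged$end[i], genes$tss[j])
    }, 0))
    if (len[i] <= 1200 && d_tss > 5000) return("small_tss_distal")
    tail <- any(vapply(seq_len(nrow(merged)), function(j) {
      j != i && len[j] >= 3 * len[i] &&
        bf_gap_bp(merged$start[i], merged$end[i],
                  merged$start[j], merged$end[j]) < 5000
    }, TRUE))
    if (len[i] < 2000 && tail) return("island_tail")
    if (input[i] / len[i] > 0.024) return("high_input")
    NA_character_
  }, "")
  expect_equal(out$excluded$reason, bf_reason[!is.na(bf_reason)])
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(merged))
  expect_equal(dplyr::bind_rows(out$kept, out$excluded[names(out$kept)]) %>%
                 dplyr::arrange(start) %>% as.data.frame(),
               as.data.frame(dplyr::arrange(merged, start)))
})

test_that("TSS-proximal island selection minimizes edge distance with stated tie-breaks", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          tss = c(10000, 50000), strand = "+",
                          body_end = c(15000, 55000))
  isl <- tibble::tibble(chrom = "chr1",
                        start = c(9500, 10100, 49000, 48000),
                        end = c(10500, 11000, 49500, 49000),
                        tag_count = c(5, 50, 10, 10))
  sel <- select_tss_proximal(isl, genes)
  # island spanning the TSS (distance 0) beats the closer-scoring one
  expect_equal(sel$start[sel$gene_id == "g1"], 9500)
  expect_equal(sel$tss_distance[sel$gene_id == "g1"], 0)
  expect_equal(sel$start[sel$gene_id == "g2"], 49000)

  # tie on distance (both 500 bp away): larger tag count wins
  tie <- tibble::tibble(chrom = "chr1", start = c(9001, 10500),
                        end = c(9501, 11000), tag_count = c(3, 9))
  sel_tie <- select_tss_proximal(tie, genes[1, ])
  expect_equal(sel_tie$start, 10500)

  set.seed(31)
  risl <- rand_regions(120, chroms = "chr1", max_pos = 1e5)
  risl$tag_count <- floor(runif(120, 0, 100))
  rgenes <- tibble::tibble(gene_id = paste0("g", 1:8), chrom = "chr1",
                           tss = floor(runif(8, 0, 1e5)), strand = "+",
                           body_end = 2e5)
  sel_r <- select_tss_proximal(risl, rgenes)
  for (gi in seq_len(nrow(rgenes))) {
    d <- vapply(seq_len(nrow(risl)), function(i) {
      bf_edge_dist(risl$start[i], risl$end[i], rgenes$tss[gi])
    }, 0)
    expect_equal(sel_r$tss_distance[sel_r$gene_id == rgenes$gene_id[gi]],
                 min(d))
  }
})
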