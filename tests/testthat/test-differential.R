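test_that("fold-change classification uses the strict 1.8x threshold", {
  calls <- call_differential(tibble::tibble(wt = c(100, 190, 180),
                                            mut = c(100, 100, 100)))
  expect_equal(calls$label, c("unchanged", "decreased", "unchanged"))
  expect_equal(calls$fc[1], 1)

  # without pseudocount the boundary is exact: 1.8 is not > 1.8
  raw <- call_differential(tibble::tibble(wt = c(180, 181), mut = 100),
                           pseudocount = 0)
  expect_equal(raw$label, c("unchanged", "decreased"))

  expect_error(call_differential(tibble::tibble(wt = -1, mut = 1)),
               "non-negative")
})

test_that("decreased and increased labels are antisymmetric under pair swap", {
  set.seed(37)
  wt <- rpois(200, 150)
  mut <- rpois(200, 150) * sample(c(0.2, 1, 4), 200, replace = TRUE)
  fwd <- call_differential(NULL, wt = wt, mut = mut)
  rev <- call_differential(NULL, wt = mut, mut = wt)
  expect_equal(fwd$label == "decreased", rev$label == "increased")
  expect_equal(fwd$label == "unchanged", rev$label == "unchanged")
})

test_that("any-stage decrease is the union over stage label matrices", {
  regions <- tibble::tibble(chrom = "chr1", start = c(0, 1000, 2000),
                            end = c(500, 1500, 2500))
  stage_calls <- list(
    dn3 = dplyr::mutate(regions, label = c("unchanged", "unchanged", "unchanged")),
    dn4 = dplyr::mutate(regions, label = c("decreased", "unchanged", "unchanged")),
    dp  = dplyr::mutate(regions, label = c("decreased", "increased", "unchanged"))
  )
  out <- call_decreased_any_stage(stage_calls)
  expect_equal(out$start, 0) # only the region decreased somewhere
  expect_equal(out$stages, "dn4,dp")

  # brute-force union oracle on a random label matrix
  set.seed(41)
  regs <- tibble::tibble(chrom = "chr1", start = seq(0, 99000, 1000))
  regs$end <- regs$start + 800
  labels <- matrix(sample(c("decreased", "increased", "unchanged"), 500,
                          replace = TRUE, prob = c(0.2, 0.1, 0.7)),
                   nrow = 100)
  lst <- lapply(1:5, function(s) dplyr::mutate(regs, label = labels[, s]))
  names(lst) <- paste0("s", 1:5)
  out_r <- call_decreased_any_stage(lst)
  expect_equal(sort(out_r$start),
               sort(regs$start[apply(labels == "decreased", 1, any)]))
})

test_that("induced islands need both >1.8x gain and a peak overlap", {
  isl <- tibble::tibble(chrom = "chr1", start = c(0, 2000, 4000),
                        end = c(1000, 3000, 5000),
                        pre = c(100, 100, 100), post = c(250, 250, 150))
  peaks <- tibble::tibble(chrom = "chr1", start = c(500, 4500), end = c(600, 4600))
  out <- call_induced_islands(isl, peaks)
  expect_equal(out$start, 0) # 2.5x with peak; 2.5x without peak and
                             # 1.5x with peak both excluded
  expect_equal(nrow(call_induced_islands(isl, peaks[0, ])), 0)
})

test_that("k-means clustering separates blobs, is deterministic and near-optimal", {
  set.seed(43)
  m <- rbind(matrix(rnorm(100, 0), ncol = 4), matrix(rnorm(100, 8), ncol = 4))
  km <- kmeans_cluster(m, k = 2, seed = 7, standardize = FALSE)
  expect_equal(length(unique(km$cluster[1:25])), 1)
  expect_equal(length(unique(km$cluster[26:50])), 1)
  expect_true(km$cluster[1] != km$cluster[26])
  km2 <- kmeans_cluster(m, k = 2, seed = 7, standardize = FALSE)
  expect_identical(km$cluster, km2$cluster)

  # k = 1: centroid is the column mean
  km1 <- kmeans_cluster(m, k = 1, standardize = FALSE)
  expect_equal(as.numeric(km1$centers), colMeans(m))
  expect_error(kmeans_cluster(m, k = 51), "exceeds")

  # objective no worse than 1,000 random assignments
  wss_of <- function(assign) {
    sum(vapply(unique(assign), function(g) {
      rows <- m[assign == g, , drop = FALSE]
      sum(scale(rows, scale = FALSE)^2)
    }, 0))
  }
  set.seed(47)
  random_wss <- replicate(1000, wss_of(sample(1:2, 50, replace = TRUE)))
  expect_lte(km$tot_withinss, min(random_wss))

  expect_equal(nrow(tidy(km)), 50)
  expect_equal(glance(km)$k, 2)
})

test_that("probe-set selection maximizes expression x fold-change per gene", {
  probes <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"),
    probe_set = c("a", "b", "c"),
    expression = c(8, 10, 5), fc = c(2, 1, 1))
  sel <- select_probe_set(probes)
  expect_equal(sel$probe_set[sel$gene_id == "g1"], "a") # 16 > 10
  expect_equal(sel$probe_set[sel$gene_id == "g2"], "c") # single probe set

  # tie broken by identifier order
  tie <- tibble::tibble(gene_id = "g", probe_set = c("z", "a"),
                        expression = c(4, 4), fc = c(2, 2))
  expect_equal(select_probe_set(tie)$probe_set, "a")

  set.seed(53)
  rnd <- tibble::tibble(
    gene_id = rep(paste0("g", 1:30), each = 3),
    probe_set = paste0("p", 1:90),
    expression = runif(90, 2, 12), fc = runif(90, 0.2, 5))
  sel_r <- select_probe_set(rnd)
  for (g in unique(rnd$gene_id)) {
    sub <- rnd[rnd$gene_id == g, ]
    expect_equal(sel_r$score[sel_r$gene_id == g],
                 max(sub$expression * sub$fc))
  }
})

test_that("dynamic-range filtering is strict at 4x and matches a range scan", {
  # constant expression excluded; exactly 4x excluded; just over included
  expr <- tibble::tibble(
    probe_set = c("p1", "p2", "p3"), gene_id = c("g1", "g2", "g3"),
    s1 = log2(c(4, 4, 4)), s2 = log2(c(4, 16, 16.1)))
  out <- dynamic_expression_filter(expr, fold = 4)
  expect_equal(out$gene_id, "g3")

  set.seed(59)
  rexpr <- tibble::tibble(probe_set = paste0("p", 1:60),
                          gene_id = rep(paste0("g", 1:20), 3),
                          a = rnorm(60, 6), b = rnorm(60, 6), c = rnorm(60, 6))
  out_r <- dynamic_expression_filter(rexpr, fold = 4)
  bf <- vapply(paste0("g", 1:20), function(g) {
    v <- 2^unlist(rexpr[rexpr$gene_id == g, c("a", "b", "c")])
    max(v) / min(v) > 4
  }, TRUE)
  expect_setequal(out_r$gene_id, names(bf)[bf])
})

test_that("qPCR quantification formulas are exact and clamp negative signal", {
  expect_equal(percent_input(3, 1, 4), 0.5)
  expect_equal(percent_input(1, 1, 4), 0) # ab == igg
  expect_warning(z <- percent_input(0.5, 1, 4), "clamped")
  expect_equal(z, 0)
  expect_error(percent_input(3, 1, 0), "positive")

  expect_equal(h3_normalized(5, 1, 9), 0.5)
  expect_error(h3_normalized(5, 1, 1), "non-zero")
})
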