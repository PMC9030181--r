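test_that("site filter keeps the coverage boundary and drops non-CpG", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L),
    strand = "+", context = c("CpG", "CpG", "CHH"),
    meth_reads = 1L, total_reads = c(5L, 4L, 100L),
    level = 1 / c(5, 4, 100), sample_id = "s1"
  )
  kept <- filter_sites(calls)
  expect_equal(kept$pos, 10L)        # 5 reads kept, 4 removed, CHH removed
})

test_that("adjacency binning follows the gap rule, inclusively", {
  bins <- build_bins(tibble::tibble(chrom = "chr1",
                                    pos = c(100L, 900L, 2100L)))
  expect_equal(bins$n_sites, c(2L, 1L))
  expect_equal(bins$start, c(100L, 2100L))
  expect_equal(bins$end, c(901L, 2101L))

  single <- build_bins(tibble::tibble(chrom = "chr1", pos = 5L))
  expect_equal(single$n_sites, 1L)
  expect_equal(single$region, "chr1:6-6")

  # gaps of exactly max_gap stay in one bin ("no more than" is inclusive)
  exact <- build_bins(tibble::tibble(chrom = "chr1",
                                     pos = c(0L, 1000L, 2000L)))
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$n_sites, 3L)

  # chromosome change always cuts
  two_chr <- build_bins(tibble::tibble(chrom = c("chr1", "chr2"),
                                       pos = c(100L, 150L)))
  expect_equal(nrow(two_chr), 2L)
})

test_that("binning matches brute-force cut enumeration on small instances", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:14, 1)
    pos <- sort(sample(0:5000, n))
    max_gap <- sample(c(200L, 500L, 1000L), 1)
    oracle <- brute_force_bins(pos, max_gap)
    got <- build_bins(tibble::tibble(chrom = "chrX", pos = pos),
                      max_gap = max_gap)
    expect_equal(got$site_pos, oracle)
  }
})

test_that("bins partition the retained sites with the gap property", {
  st <- simulate_methylome(sim_config(seed = 4, n_bins = 150L))
  retained <- filter_sites(st$calls)
  sites <- shared_sites(retained)
  bins <- build_bins(sites)
  expect_equal(sum(bins$n_sites), nrow(sites))
  expect_equal(sort(unlist(bins$site_pos)), sort(sites$pos))
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, ]
    intra <- unlist(purrr::map(b$site_pos, ~ if (length(.x) > 1) diff(.x)))
    expect_true(all(intra <= 1000))
    firsts <- purrr::map_int(b$site_pos, 1)
    lasts <- purrr::map_int(b$site_pos, ~ .x[length(.x)])
    expect_true(all(firsts[-1] - lasts[-length(lasts)] > 1000))
  }
})

test_that("bin and group levels are unweighted means of site levels", {
  sheet <- two_group_sheet(n = 3)
  calls <- tidyr::expand_grid(sample_id = sheet$sample_id,
                              pos = c(10L, 40L)) |>
    dplyr::mutate(chrom = "chr1", strand = "+", context = "CpG",
                  total_reads = 10L)
  # sample a_1 has site levels 0.2 / 0.8 -> bin 0.5; group a bins 0.1/0.2/0.3
  lv <- c(a_1 = 0.5, a_2 = 0.1, a_3 = 0.0, b_1 = 1, b_2 = 1, b_3 = 1)
  site1 <- c(a_1 = 0.2, a_2 = 0.1, a_3 = 0, b_1 = 1, b_2 = 1, b_3 = 1)
  site2 <- c(a_1 = 0.8, a_2 = 0.1, a_3 = 0, b_1 = 1, b_2 = 1, b_3 = 1)
  calls$meth_reads <- as.integer(10 * ifelse(calls$pos == 10L,
                                             site1[calls$sample_id],
                                             site2[calls$sample_id]))
  calls$level <- calls$meth_reads / calls$total_reads
  bins <- build_bins(dplyr::distinct(calls, chrom, pos))
  wide <- bin_levels(bins, calls, sheet)
  expect_equal(wide$a_1, 0.5)
  expect_equal(wide$b_1, 1)          # fully methylated stays 1
  grp <- group_levels(wide, sheet)
  expect_equal(grp$a, mean(c(0.5, 0.1, 0)))
  expect_equal(grp$b, 1)
})

test_that("incomplete site/sample coverage errors unless relaxed", {
  sheet <- two_group_sheet(n = 2)
  calls <- tidyr::expand_grid(sample_id = sheet$sample_id, pos = 10L) |>
    dplyr::mutate(chrom = "chr1", strand = "+", context = "CpG",
                  meth_reads = 5L, total_reads = 10L, level = 0.5)
  calls <- calls[calls$sample_id != "a_1", ]
  bins <- build_bins(tibble::tibble(chrom = "chr1", pos = 10L))
  expect_error(bin_levels(bins, calls, sheet), "missing site/sample")
  relaxed <- bin_levels(bins, calls, sheet, require_complete = FALSE)
  expect_false("a_1" %in% names(relaxed))
})

test_that("default synthetic genome yields ~212 bp mean bins", {
  st <- simulate_methylome(sim_config(seed = 1))
  lv <- bin_methylation(st$calls, st$sample_sheet)
  mean_len <- mean(lv$end - lv$start)
  expect_gt(mean_len, 212 * 0.7)
  expect_lt(mean_len, 212 * 1.3)
  # binning recovers the generator's islands exactly
  expect_equal(lv$region, st$truth$region)
})
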