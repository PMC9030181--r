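dmr_calls <- function(directions) {
  tibble::tibble(feature_id = sprintf("chr1:%d-%d",
                                      seq_along(directions) * 1000,
                                      seq_along(directions) * 1000 + 50),
                 direction = directions, significant = TRUE)
}

test_that("the strict direction rule decides DMR amelioration", {
  dmrs <- dmr_calls(c("hyper", "hyper", "hypo"))
  grp <- tibble::tibble(region = dmrs$feature_id,
                        young = c(0.6, 0.6, 0.4),
                        old = c(0.8, 0.8, 0.2),
                        DR = c(0.7, 0.85, 0.2))
  out <- classify_dmr_amelioration(dmrs, grp, treated = "DR")
  # hyper rescued when DR < old; tie on the hypo bin fails the strict rule
  expect_equal(out$ameliorated, c(TRUE, FALSE, FALSE))
  expect_equal(out$old_value, c(0.8, 0.8, 0.2))
  expect_error(
    classify_dmr_amelioration(dmrs, grp[-1, ], treated = "DR"),
    "missing")
})

test_that("DEG amelioration mirrors the rule on expression means", {
  sheet <- two_group_sheet(n = 3, groups = c("old", "DR"))
  fpkm <- tibble::tibble(
    gene_id = c("gO", "gU1", "gU2"),
    old_1 = c(10, 2, 2), old_2 = c(10, 2, 2), old_3 = c(10, 2, 2),
    DR_1 = c(7, 5, 1), DR_2 = c(7, 5, 1), DR_3 = c(7, 5, 1)
  )
  degs <- tibble::tibble(feature_id = fpkm$gene_id,
                         direction = c("ODEG", "UDEG", "UDEG"),
                         significant = TRUE)
  out <- classify_deg_amelioration(degs, fpkm, sheet, treated = "DR")
  expect_equal(out$ameliorated, c(TRUE, TRUE, FALSE))
})

test_that("ameliorated features are a subset of significant aging calls", {
  st <- simulate_methylome(sim_config(seed = 6, n_bins = 300L))
  lv <- bin_methylation(st$calls, st$sample_sheet)
  dm <- call_dmrs(lv, st$sample_sheet, "young", "old")
  grp <- group_levels(lv, st$sample_sheet)
  out <- classify_dmr_amelioration(dm, grp, treated = "RALL")
  expect_true(all(out$feature_id %in% dm$feature_id[dm$significant]))
  expect_equal(nrow(out), sum(dm$significant))
})

test_that("boundary methylomes bracket the amelioration rate", {
  dmrs <- dmr_calls(rep(c("hyper", "hypo"), 10))
  young <- rep(c(0.3, 0.7), 10)
  old <- young + rep(c(0.2, -0.2), 10)
  grp_old <- tibble::tibble(region = dmrs$feature_id, young = young,
                            old = old, DR = old)
  expect_equal(
    sum(classify_dmr_amelioration(dmrs, grp_old, "DR")$ameliorated), 0L)
  grp_young <- dplyr::mutate(grp_old, DR = young)
  expect_equal(
    mean(classify_dmr_amelioration(dmrs, grp_young, "DR")$ameliorated), 1)
})

test_that("at zero noise the ameliorated fraction equals the rescue rate", {
  bl <- simulate_bin_levels(20000, lambda = 0.565, noise_sd = 0,
                            rescue_prob = 0.835, seed = 14)
  aging <- bl[bl$aging != "null", ]
  dmrs <- tibble::tibble(feature_id = aging$region,
                         direction = aging$aging, significant = TRUE)
  grp <- tibble::tibble(region = aging$region, young = aging$young,
                        old = aging$old, DR = aging$treated)
  out <- classify_dmr_amelioration(dmrs, grp, "DR")
  expect_equal(mean(out$ameliorated), mean(aging$rescued))
  # under noise the strict rule also flips ~half the non-rescued ties
  bln <- simulate_bin_levels(20000, lambda = 0.565, noise_sd = 0.02,
                             rescue_prob = 0.835, seed = 15)
  agn <- bln[bln$aging != "null", ]
  outn <- classify_dmr_amelioration(
    tibble::tibble(feature_id = agn$region, direction = agn$aging,
                   significant = TRUE),
    tibble::tibble(region = agn$region, young = agn$young, old = agn$old,
                   DR = agn$treated), "DR")
  frac <- mean(outn$ameliorated)
  expect_gt(frac, 0.835)
  expect_lt(frac, 0.835 + (1 - 0.835) / 2 + 0.03)
})

test_that("overlap counting reports intersection, union and fraction", {
  mk <- function(ids, dirs, amel) {
    tibble::tibble(feature_id = ids, aging_direction = dirs,
                   treated_group = "x", old_value = 1, treated_value = 0,
                   ameliorated = amel)
  }
  a <- mk(c("g1", "g2", "g3"), "UDEG", TRUE)
  b <- mk(c("g2", "g3", "g4"), "UDEG", TRUE)
  ov <- overlap_sets(a, b)
  all_row <- ov$summary[ov$summary$direction == "all", ]
  expect_equal(all_row$n_intersect, 2L)
  expect_equal(all_row$n_union, 4L)
  expect_equal(all_row$fraction_overlap, 0.5)
  expect_setequal(ov$shared, c("g2", "g3"))

  disjoint <- overlap_sets(mk(paste0("a", 1:3), "ODEG", TRUE),
                           mk(paste0("b", 1:4), "ODEG", TRUE))
  row <- disjoint$summary[disjoint$summary$direction == "all", ]
  expect_equal(row$n_union, 7L)
  expect_equal(row$n_intersect, 0L)
  ident <- overlap_sets(a, a)
  expect_equal(ident$summary$fraction_overlap[
    ident$summary$direction == "all"], 1)
})
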