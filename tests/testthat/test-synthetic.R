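test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 5, n_bins = 60L, n_genes = 80L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$fpkm, b$fpkm)
  expect_identical(a$meth_truth, b$meth_truth)
  expect_identical(a$ontology, b$ontology)
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_study(a, dir_a)
  write_study(b, dir_b)
  for (f in list.files(dir_a)) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)), label = f)
  }
})

test_that("bin methylation is bimodal like the emulated study", {
  st <- simulate_methylome(sim_config(seed = 1))
  lv <- bin_methylation(st$calls, st$sample_sheet)
  grp <- group_levels(lv, st$sample_sheet)
  for (g in c("young", "old", "DR")) {
    frac <- mean(grp[[g]] <= 0.1 | grp[[g]] >= 0.8)
    expect_gt(frac, 0.6)
  }
})

test_that("degenerate treatment parameters collapse to old or young", {
  cfg1 <- sim_config(seed = 3, n_bins = 200L, noise_sd = 0,
                     rescue_prob = c(DR = 1, RALL = 1, RDRL = 1),
                     lambda = c(DR = 1, RALL = 1, RDRL = 1))
  st1 <- simulate_methylome(cfg1)
  expect_equal(st1$truth$level_DR, st1$truth$level_old)
  # downstream: no bin can be ameliorated when treated == old
  aging <- st1$truth[st1$truth$aging != "null", ]
  out <- classify_dmr_amelioration(
    tibble::tibble(feature_id = aging$region, direction = aging$aging,
                   significant = TRUE),
    tibble::tibble(region = aging$region, old = aging$level_old,
                   DR = aging$level_DR), "DR")
  expect_equal(sum(out$ameliorated), 0L)

  cfg0 <- sim_config(seed = 3, n_bins = 200L, noise_sd = 0,
                     rescue_prob = c(DR = 1, RALL = 1, RDRL = 1),
                     lambda = c(DR = 0, RALL = 0, RDRL = 0))
  st0 <- simulate_methylome(cfg0)
  expect_equal(st0$truth$level_DR, st0$truth$level_young)
  aging0 <- st0$truth[st0$truth$aging != "null", ]
  out0 <- classify_dmr_amelioration(
    tibble::tibble(feature_id = aging0$region, direction = aging0$aging,
                   significant = TRUE),
    tibble::tibble(region = aging0$region, old = aging0$level_old,
                   DR = aging0$level_DR), "DR")
  expect_equal(mean(out0$ameliorated), 1)
})

test_that("coverage respects the floor and the low-coverage switch", {
  st <- simulate_methylome(sim_config(seed = 2, n_bins = 40L))
  expect_true(all(st$calls$total_reads >= 5))
  low <- simulate_methylome(sim_config(seed = 2, n_bins = 40L,
                                       low_coverage_fraction = 0.2))
  expect_true(any(low$calls$total_reads < 5))
  kept <- filter_sites(low$calls)
  expect_true(all(kept$total_reads >= 5))
})

test_that("the DMR caller recovers the generator's truth labels", {
  st <- simulate_methylome(sim_config(seed = 7))
  lv <- bin_methylation(st$calls, st$sample_sheet)
  dm <- call_dmrs(lv, st$sample_sheet, "young", "old")
  truth <- st$truth[match(dm$feature_id, st$truth$region), ]
  sens <- mean(dm$significant[truth$aging != "null"])
  fpr <- mean(dm$significant[truth$aging == "null"])
  expect_gte(sens, 0.90)
  expect_lte(fpr, 0.07)
  hit <- dm$significant & truth$aging != "null"
  expect_equal(dm$direction[hit], truth$aging[hit])
})

test_that("expression truth labels drive DEG calls and rescue", {
  ex <- simulate_expression(sim_config(seed = 4, n_genes = 600L))
  degs <- call_degs(ex$fpkm, ex$sample_sheet, "young", "old")
  truth <- ex$truth[match(degs$feature_id, ex$truth$gene_id), ]
  sens <- mean(degs$significant[truth$class != "null"])
  expect_gt(sens, 0.85)
  hit <- degs$significant & truth$class != "null"
  expect_gt(mean(degs$direction[hit] == truth$class[hit]), 0.98)

  flat <- simulate_expression(sim_config(seed = 4, n_genes = 400L,
                                         deg_fraction = 0))
  dflat <- call_degs(flat$fpkm, flat$sample_sheet, "young", "old",
                     shrink = TRUE)
  expect_lt(mean(dflat$significant), 0.08)   # null-rate false calls only
})

test_that("the deterministic expression fixture has exact rescue counts", {
  fx <- make_expression_fixture()
  am <- classify_deg_amelioration(fx$aging_degs, fx$fpkm, fx$sample_sheet,
                                  treated = "DR")
  s <- amelioration_summary(am)
  expect_equal(s$n_ameliorated[s$aging_direction == "ODEG"], 770)
  expect_equal(s$n_ameliorated[s$aging_direction == "UDEG"], 203)
  expect_equal(s$n_aging[s$aging_direction == "all"], 1087)
})

test_that("annotation placement controls promoter/body overlap", {
  cfg <- sim_config(seed = 6, n_bins = 300L, n_genes = 200L)
  st <- simulate_study(cfg)
  dmrs <- tibble::tibble(feature_id = st$bin_gene_map$region)
  mapped <- map_dmrs_to_genes(dmrs, st$genes)
  hit <- mapped |>
    dplyr::inner_join(st$bin_gene_map,
                      by = c(dmr_id = "region", "gene_id")) |>
    dplyr::mutate(ok = (placement == "body" & region == "gene_body") |
                    (placement == "promoter" & region == "promoter"))
  # every placed bin is recovered in its intended region class
  expect_setequal(unique(hit$dmr_id[hit$ok]), st$bin_gene_map$region)

  none <- simulate_annotation(
    sim_config(seed = 6, n_bins = 300L, n_genes = 200L,
               promoter_hit_fraction = 0, body_hit_fraction = 0),
    st$meth_truth, st$expr_truth)
  aging_regions <- st$meth_truth$region[st$meth_truth$aging != "null"]
  unmapped <- map_dmrs_to_genes(tibble::tibble(feature_id = aging_regions),
                                none$genes)
  expect_true(all(is.na(unmapped$gene_id)))
})
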