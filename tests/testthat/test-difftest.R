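test_that("with no shrinkage the moderated test is the classical pooled t", {
  set.seed(1)
  for (rep in 1:20) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1))
    got <- moderated_two_sample_test(a, b)
    ref <- t.test(b, a, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  # worked example against the textbook oracle
  a <- c(0.10, 0.12, 0.11)
  b <- c(0.30, 0.28, 0.29)
  got <- moderated_two_sample_test(a, b)
  ref <- t.test(b, a, var.equal = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_gt(got$statistic, 0)
})

test_that("identical groups give statistic 0 and p 1", {
  x <- c(0.2, 0.4, 0.6)
  got <- moderated_two_sample_test(x, x)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
})

test_that("infinite prior df collapses the variance to s0", {
  a <- c(0.1, 0.2, 0.3)
  b <- c(0.5, 0.55, 0.6)
  prior <- estimate_prior(rep(0.01, 20), df = 4)   # all equal -> d0 = Inf
  expect_equal(prior$d0, Inf)
  expect_equal(prior$s0_sq, 0.01)
  got <- moderated_two_sample_test(a, b, prior)
  delta <- mean(b) - mean(a)
  expect_equal(got$statistic, delta / sqrt(0.01 * (1 / 3 + 1 / 3)))
})

test_that("zero variance with no prior warns and hard-codes p", {
  expect_warning(
    got <- moderated_two_sample_test(c(1, 1, 1), c(2, 2, 2)),
    "zero variance")
  expect_equal(got$p_value, 0)
  expect_warning(
    same <- moderated_two_sample_test(c(1, 1), c(1, 1)))
  expect_equal(same$p_value, 1)
})

test_that("the variance prior is recovered from simulated variances", {
  set.seed(7)
  d0 <- 4; s0 <- 0.02; d <- 4
  sigma2 <- s0 * d0 / rchisq(5000, d0)            # inverse-chi-square prior
  s2 <- sigma2 * rchisq(5000, d) / d              # sample variances
  prior <- estimate_prior(s2, d)
  expect_lt(abs(prior$d0 - d0), 1)
  expect_lt(abs(prior$s0_sq - s0) / s0, 0.20)
})

test_that("too few features fall back to no shrinkage", {
  prior <- estimate_prior(c(0.01, 0.02, 0.03, 0.01, 0.02), df = 4)
  expect_equal(prior$d0, 0)
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(11)
  m <- matrix(rnorm(600 * 6, sd = rep(sqrt(0.02 * 4 / rchisq(600, 4)), 6)),
              600, 6)
  colnames(m) <- paste0("s", 1:6)
  sheet <- tibble::tibble(sample_id = colnames(m),
                          group = rep(c("a", "b"), each = 3))
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(0:1, each = 3))))
  s2 <- fit$sigma^2
  # same prior -> identical statistics (the shrinkage algebra is shared)
  res <- methylrescue:::moderated_t_core(
    rowMeans(m[, 4:6]) - rowMeans(m[, 1:3]), s2, 4, 3, 3,
    methylrescue:::new_prior(fit$df.prior, fit$s2.prior))
  expect_equal(res$statistic, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-10)
  # own prior estimate close to limma's
  prior <- estimate_prior(s2, 4)
  expect_equal(prior$d0, fit$df.prior, tolerance = 0.1)
  expect_equal(prior$s0_sq, fit$s2.prior, tolerance = 0.1)
})

test_that("DMR calls apply both thresholds strictly with direction by sign", {
  sheet <- two_group_sheet(n = 3, groups = c("young", "old"))
  base <- matrix(rep(c(0.30, 0.31, 0.29), 2), nrow = 1)    # sd ~ 0.01
  m <- rbind(
    base + rep(c(0, 0.15), each = 3),    # delta .15, tiny p -> hyper DMR
    base + rep(c(0, 0.08), each = 3),    # delta .08 -> fails |delta| > 0.1
    base - rep(c(0, 0.15), each = 3),    # hypo DMR
    base                                  # null
  )
  lv <- levels_from_matrix(m, sheet)
  calls <- call_dmrs(lv, sheet, "young", "old", shrink = FALSE)
  expect_equal(calls$significant, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(calls$direction[c(1, 3)], c("hyper", "hypo"))
  # p above threshold blocks a large delta
  expect_false(any(calls$significant & calls$p_value >= 0.05))
  expect_error(call_dmrs(lv, sheet, "young", "elderly"), "elderly")
})

test_that("DMR significance is invariant to sample relabeling in a group", {
  st <- simulate_methylome(sim_config(seed = 9, n_bins = 120L))
  lv <- bin_methylation(st$calls, st$sample_sheet)
  ref <- call_dmrs(lv, st$sample_sheet, "young", "old")
  sheet2 <- st$sample_sheet
  swap <- match(c("old_2", "old_1"), sheet2$sample_id)
  sheet2$sample_id[swap] <- c("old_1", "old_2")
  got <- call_dmrs(lv, sheet2, "young", "old")
  expect_equal(got$p_value, ref$p_value)
  expect_equal(got$significant, ref$significant)
})

test_that("|statistic| is monotone in |delta| at fixed variances", {
  sheet <- two_group_sheet(n = 3, groups = c("young", "old"))
  deltas <- seq(0, 0.5, by = 0.05)
  m <- t(vapply(deltas, function(d) {
    c(0.2, 0.22, 0.21, 0.2 + d, 0.22 + d, 0.21 + d)
  }, numeric(6)))
  calls <- call_dmrs(levels_from_matrix(m, sheet), sheet, "young", "old",
                     shrink = FALSE)
  expect_true(all(diff(abs(calls$statistic)) >= 0))
})

test_that("null p-values are calibrated at 10,000 features", {
  set.seed(123)
  sheet <- two_group_sheet(n = 3, groups = c("young", "old"))
  m <- matrix(rnorm(10000 * 6, mean = 0.5, sd = 0.05), ncol = 6)
  colnames(m) <- sheet$sample_id
  res <- methylrescue:::diff_two_group(m, as.character(1:10000), sheet,
                                       "young", "old")
  rate <- mean(res$p_value < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("DEG calls test log FPKM, classify direction, skip silent genes", {
  sheet <- two_group_sheet(n = 3, groups = c("young", "old"))
  fpkm <- tibble::tibble(
    gene_id = c("up", "down", "flat", "silent"),
    young_1 = c(1, 4, 2, 0), young_2 = c(1.1, 4.2, 2, 0),
    young_3 = c(0.9, 3.8, 2, 0),
    old_1 = c(4, 1, 2, 0), old_2 = c(4.2, 1.1, 2, 0),
    old_3 = c(3.8, 0.9, 2, 0)
  )
  expect_message(
    calls <- suppressWarnings(call_degs(fpkm, sheet, "young", "old")),
    "all-zero")
  expect_equal(calls$feature_id, c("up", "down", "flat"))
  expect_equal(calls$direction[1:2], c("ODEG", "UDEG"))
  expect_true(all(calls$significant[1:2]))
  expect_false(calls$significant[3])
})

test_that("expression summary counts expressed genes and MA coordinates", {
  sheet <- two_group_sheet(n = 3, groups = c("young", "old"))
  fpkm <- tibble::tibble(
    gene_id = c("g1", "g2"),
    young_1 = c(0.5, 2), young_2 = c(0.5, 2), young_3 = c(0.5, 2),
    old_1 = c(2, 8), old_2 = c(2, 8), old_3 = c(2, 8)
  )
  s <- expression_summary(fpkm, sheet)
  expect_equal(s$expressed$n_expressed[s$expressed$group == "young"], 1)
  expect_equal(s$expressed$n_expressed[s$expressed$group == "old"], 2)
  expect_equal(s$ma$log2fc, c(2, 2))
  flat <- expression_summary(
    dplyr::mutate(fpkm, dplyr::across(-gene_id, ~2)), sheet)
  expect_equal(flat$ma$log2fc, c(0, 0))
})
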