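#' Simulation configuration for a synthetic methylation-aging study
#'
#' Defaults emulate the structure of the five-group mouse hippocampus design
#' (young, old, dietary restriction DR, long-term rapamycin RALL, and the
#' combination RDRL; three animals per group): a bimodal bin-methylation
#' landscape with most mass near 0 or in 0.8-1.0, CpG islands whose spans
#' average about 212 bp, aging effects of |delta| = 0.2 on 10% of bins with
#' a 43:57 hyper:hypo split, treated methylomes that are convex mixtures
#' lambda*old + (1-lambda)*young on rescued bins (lambda 0.565 for DR and
#' the combination, 0.5585 for RALL; rescue probability 0.835 / 0.79), and
#' expression tables with 10% aging-DEGs, 77% of them over-expressed in old,
#' partially rescued by treatment (90% DR, 72% RALL).
#'
#' @param seed Integer seed; every `simulate_*` consumer derives sub-streams
#'   from it by fixed offsets.
#' @param ... Overrides of any listed default.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # genome / binning
    n_chromosomes = 3L,
    n_bins = 2000L,
    mean_sites_per_bin = 8,      # site count ~ 1 + Poisson(mean - 1)
    mean_site_spacing = 30,      # bp; spacing ~ 2 + Geom, capped below 1 kb
    island_gap_min = 1500L,      # > max_gap so islands map 1:1 onto bins
    island_gap_max = 20000L,
    # design
    groups = c("young", "old", "DR", "RALL", "RDRL"),
    treated_groups = c("DR", "RALL", "RDRL"),
    n_per_group = 3L,
    # baseline bin methylation: bimodal mixture
    w_low = 0.45, w_mid = 0.10, w_high = 0.45,
    beta_low = c(1, 25), beta_mid = c(2, 2), beta_high = c(25, 2),
    # aging effects
    aging_fraction = 0.10,
    hyper_fraction = 0.43,
    delta = 0.2,
    # treatment
    lambda = c(DR = 0.565, RALL = 0.5585, RDRL = 0.565),
    rescue_prob = c(DR = 0.835, RALL = 0.79, RDRL = 0.835),
    noise_sd = 0.02,
    # coverage
    coverage_mu = 25, coverage_size = 5, coverage_floor = 5L,
    low_coverage_fraction = 0,   # extra sub-floor sites to exercise filtering
    # expression
    n_genes = 1500L,
    deg_fraction = 0.10,
    odeg_fraction = 839 / 1087,
    log2fc_min = 0.5, log2fc_rate = 2,  # |log2FC| ~ min + Exp(rate)
    expr_rescue = c(DR = 0.90, RALL = 0.72, RDRL = 0.90),
    expr_meanlog = 1.5, expr_sdlog = 1.2, expr_noise_sdlog = 0.15,
    # annotation
    promoter_hit_fraction = 0.3, body_hit_fraction = 0.3,
    n_go_terms = 25L, genes_per_term = 15L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_config field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  probs <- c(cfg$w_low, cfg$w_mid, cfg$w_high, cfg$aging_fraction,
             cfg$hyper_fraction, cfg$rescue_prob, cfg$expr_rescue,
             cfg$deg_fraction, cfg$odeg_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$delta <= 0.1) abort("aging effect size delta must exceed 0.1")
  if (cfg$noise_sd < 0) abort("noise_sd must be non-negative")
  structure(cfg, class = "sim_config")
}

# Bimodal baseline bin methylation levels.
draw_baseline <- function(n, cfg) {
  comp <- sample(1:3, n, replace = TRUE,
                 prob = c(cfg$w_low, cfg$w_mid, cfg$w_high))
  lv <- numeric(n)
  for (i in 1:3) {
    par <- list(cfg$beta_low, cfg$beta_mid, cfg$beta_high)[[i]]
    idx <- comp == i
    lv[idx] <- rbeta(sum(idx), par[1], par[2])
  }
  lv
}

# Assign aging classes so effects never saturate at 0/1: hyper effects go to
# bins with headroom above, hypo effects to bins with headroom below.
assign_aging <- function(young, cfg) {
  n <- length(young)
  n_aging <- round(cfg$aging_fraction * n)
  n_hyper <- round(cfg$hyper_fraction * n_aging)
  n_hypo <- n_aging - n_hyper
  margin <- cfg$delta + 0.02
  ok_hyper <- which(young <= 1 - margin)
  ok_hypo <- which(young >= margin)
  aging <- rep("null", n)
  hyper <- sample(ok_hyper, min(n_hyper, length(ok_hyper)))
  hypo <- sample(setdiff(ok_hypo, hyper), min(n_hypo, length(ok_hypo)))
  aging[hyper] <- "hyper"
  aging[hypo] <- "hypo"
  aging
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate group-level bin methylation for trajectory analysis
#'
#' The light-weight, genome-wide view of the study: one row per bin with the
#' true young and old group levels and a treated level built as the convex
#' mixture `lambda * old + (1 - lambda) * young` plus truncated Gaussian
#' noise. Here the mixture is applied to every aging bin (`rescue_prob = 1`
#' by default): this is the genome-wide trajectory view in which the whole
#' treated methylome sits between young and old, so the OLS slope of
#' (treated - old) on (old - young) identifies `lambda - 1`. The full study
#' generator [simulate_methylome()] instead keeps binary per-bin rescue for
#' the amelioration analyses.
#'
#' @param n_bins Number of bins, default 5000.
#' @param lambda Mixing coefficient of the treated group, default 0.565.
#' @param noise_sd Truncated-Gaussian noise on the treated level,
#'   default 0.02.
#' @param rescue_prob Probability an aging bin receives the mixture
#'   (others keep the old level), default 1.
#' @param seed Optional integer seed.
#' @param config A [sim_config()] supplying baseline/aging parameters.
#' @return Tibble: `region`, `young`, `old`, `treated`, `aging`, `rescued`.
#' @export
simulate_bin_levels <- function(n_bins = 5000, lambda = 0.565,
                                noise_sd = 0.02, rescue_prob = 1,
                                seed = NULL, config = sim_config()) {
  if (!is.null(seed)) set.seed(seed)
  young <- draw_baseline(n_bins, config)
  aging <- assign_aging(young, config)
  old <- clip01(young + ifelse(aging == "hyper", config$delta,
                               ifelse(aging == "hypo", -config$delta, 0)))
  rescued <- aging != "null" & runif(n_bins) < rescue_prob
  base <- ifelse(rescued, lambda * old + (1 - lambda) * young, old)
  treated <- clip01(base + rnorm(n_bins, 0, noise_sd))
  tibble::tibble(
    region = sprintf("bin%05d", seq_len(n_bins)),
    young = young, old = old, treated = treated,
    aging = aging, rescued = rescued
  )
}

#' Simulate a complete synthetic methylome
#'
#' Generates CpG call tables for every sample of the five-group design with
#' known per-bin ground truth. CpG islands are laid out with intra-island
#' spacing far below the 1 kb adjacency window and inter-island gaps above
#' it, so [bin_methylation()] recovers the islands exactly. Group truth:
#' young from the bimodal baseline; old = young +/- delta on aging bins;
#' each treated group is the lambda mixture on rescued bins and equal to old
#' elsewhere, plus truncated Gaussian noise. Every site in a bin shares the
#' bin's truth level; per-sample reads are binomial draws at negative-
#' binomial coverage with a floor of 5 reads, so the default read filter
#' passes every site (set `low_coverage_fraction` > 0 to inject sub-floor
#' sites). The same site set is emitted for all samples, and output is
#' deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return List: `calls` (long tibble over all samples), `sample_sheet`,
#'   and `truth` (per-bin tibble with `region`, span, `n_sites`, `aging`,
#'   `level_<group>` truth columns and `rescued_<treated>` flags).
#' @export
simulate_methylome <- function(config = sim_config(), seed = config$seed) {
  cfg <- config
  set.seed(seed)
  n <- cfg$n_bins
  # genome layout
  chrom <- sort(rep_len(paste0("chr", seq_len(cfg$n_chromosomes)), n))
  n_sites <- 1L + rpois(n, cfg$mean_sites_per_bin - 1)
  site_pos <- vector("list", n)
  cursor <- setNames(rep(1000L, cfg$n_chromosomes),
                     paste0("chr", seq_len(cfg$n_chromosomes)))
  for (i in seq_len(n)) {
    gaps <- pmin(2L + rgeom(n_sites[i] - 1L, 1 / (cfg$mean_site_spacing - 2)),
                 999L)
    pos <- cursor[chrom[i]] + cumsum(c(0L, gaps))
    site_pos[[i]] <- as.integer(pos)
    cursor[chrom[i]] <- pos[length(pos)] +
      sample(cfg$island_gap_min:cfg$island_gap_max, 1L)
  }
  # group truth
  young <- draw_baseline(n, cfg)
  aging <- assign_aging(young, cfg)
  old <- clip01(young + ifelse(aging == "hyper", cfg$delta,
                               ifelse(aging == "hypo", -cfg$delta, 0)))
  truth <- tibble::tibble(
    region = region_string(chrom, purrr::map_int(site_pos, 1),
                           purrr::map_int(site_pos, ~ .x[length(.x)]) + 1L),
    chrom = chrom,
    start = purrr::map_int(site_pos, 1),
    end = purrr::map_int(site_pos, ~ .x[length(.x)]) + 1L,
    n_sites = n_sites, aging = aging,
    level_young = young, level_old = old
  )
  level_by_group <- list(young = young, old = old)
  for (g in cfg$treated_groups) {
    rescued <- aging != "null" & runif(n) < cfg$rescue_prob[[g]]
    base <- ifelse(rescued, cfg$lambda[[g]] * old +
                     (1 - cfg$lambda[[g]]) * young, old)
    lv <- clip01(base + rnorm(n, 0, cfg$noise_sd))
    level_by_group[[g]] <- lv
    truth[[paste0("level_", g)]] <- lv
    truth[[paste0("rescued_", g)]] <- rescued
  }
  # sample sheet
  sample_sheet <- tibble::tibble(
    sample_id = paste0(rep(cfg$groups, each = cfg$n_per_group),
                       "_", seq_len(cfg$n_per_group)),
    group = rep(cfg$groups, each = cfg$n_per_group)
  )
  # reads
  bin_of_site <- rep(seq_len(n), n_sites)
  all_pos <- unlist(site_pos)
  all_chrom <- chrom[bin_of_site]
  n_sites_total <- length(all_pos)
  calls <- purrr::map(seq_len(nrow(sample_sheet)), function(si) {
    p <- level_by_group[[sample_sheet$group[si]]][bin_of_site]
    cov <- cfg$coverage_floor +
      rnbinom(n_sites_total, mu = cfg$coverage_mu, size = cfg$coverage_size)
    if (cfg$low_coverage_fraction > 0) {
      drop <- runif(n_sites_total) < cfg$low_coverage_fraction
      cov[drop] <- sample(seq_len(cfg$coverage_floor - 1L),
                          sum(drop), replace = TRUE)
    }
    meth <- rbinom(n_sites_total, cov, p)
    tibble::tibble(
      chrom = all_chrom, pos = all_pos, strand = "+", context = "CpG",
      meth_reads = meth, total_reads = cov, level = meth / cov,
      sample_id = sample_sheet$sample_id[si]
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos)
  list(calls = calls, sample_sheet = sample_sheet, truth = truth)
}

#' Simulate a gene-by-sample FPKM table with known aging/rescue labels
#'
#' Baseline gene means are log-normal; aging-DEGs scale the old mean by
#' 2^log2FC (positive for ODEGs, negative for UDEGs); each treated group
#' returns rescued genes to the young mean and keeps the old mean otherwise;
#' replicate values multiply the group mean by log-normal noise.
#'
#' @inheritParams simulate_methylome
#' @return List: `fpkm` (tibble `gene_id` + samples), `sample_sheet`,
#'   `truth` (tibble `gene_id`, `class` ODEG/UDEG/null, `log2fc`,
#'   `rescued_<treated>` flags).
#' @export
simulate_expression <- function(config = sim_config(), seed = config$seed + 1L) {
  cfg <- config
  set.seed(seed)
  n <- cfg$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  n_deg <- round(cfg$deg_fraction * n)
  n_odeg <- round(cfg$odeg_fraction * n_deg)
  class <- rep("null", n)
  deg_idx <- sample(n, n_deg)
  class[deg_idx[seq_len(n_odeg)]] <- "ODEG"
  class[deg_idx[-seq_len(n_odeg)]] <- "UDEG"
  log2fc <- ifelse(class == "null", 0,
                   (cfg$log2fc_min + stats::rexp(n, cfg$log2fc_rate)) *
                     ifelse(class == "ODEG", 1, -1))
  young_mean <- rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
  old_mean <- young_mean * 2^log2fc
  mean_by_group <- list(young = young_mean, old = old_mean)
  truth <- tibble::tibble(gene_id = gene_id, class = class, log2fc = log2fc)
  for (g in cfg$treated_groups) {
    rescued <- class != "null" & runif(n) < cfg$expr_rescue[[g]]
    mean_by_group[[g]] <- ifelse(rescued, young_mean, old_mean)
    truth[[paste0("rescued_", g)]] <- rescued
  }
  sample_sheet <- tibble::tibble(
    sample_id = paste0(rep(cfg$groups, each = cfg$n_per_group),
                       "_", seq_len(cfg$n_per_group)),
    group = rep(cfg$groups, each = cfg$n_per_group)
  )
  fpkm <- tibble::tibble(gene_id = gene_id)
  for (si in seq_len(nrow(sample_sheet))) {
    mu <- mean_by_group[[sample_sheet$group[si]]]
    fpkm[[sample_sheet$sample_id[si]]] <-
      mu * rlnorm(n, 0, cfg$expr_noise_sdlog)
  }
  list(fpkm = fpkm, sample_sheet = sample_sheet, truth = truth)
}

#' Deterministic expression fixture with exact rescue counts
#'
#' A noise-free gene-by-sample table in which aging and rescue labels are
#' assigned by count rather than by coin flip: exactly `n_odeg` over- and
#' `n_udeg` under-expressed aging genes, of which exactly `n_rescued_odeg`
#' and `n_rescued_udeg` are returned to the young level in the treated
#' group (all other treated values equal old exactly, so by the strict
#' amelioration rule the ameliorated set is exactly the rescued set). The
#' defaults encode the emulated design's DR aggregate: 770/839
#' ODEGs and 203/248 UDEGs rescued, i.e. 91.78% and 89.51% overall.
#'
#' @param n_odeg,n_udeg Aging DEG counts per direction.
#' @param n_rescued_odeg,n_rescued_udeg Rescued counts per direction.
#' @param treated Treated group label receiving the rescue pattern; other
#'   treated groups equal old.
#' @param n_null Additional non-aging genes.
#' @param seed Seed for the baseline means.
#' @return List as [simulate_expression()] plus `aging_degs`, a call table
#'   (as from [call_degs()]) of the true aging DEGs.
#' @export
make_expression_fixture <- function(n_odeg = 839, n_udeg = 248,
                                    n_rescued_odeg = 770,
                                    n_rescued_udeg = 203,
                                    treated = "DR", n_null = 100,
                                    seed = 1L) {
  stopifnot(n_rescued_odeg <= n_odeg, n_rescued_udeg <= n_udeg)
  set.seed(seed)
  cfg <- sim_config(seed)
  n <- n_odeg + n_udeg + n_null
  gene_id <- sprintf("gene%05d", seq_len(n))
  class <- c(rep("ODEG", n_odeg), rep("UDEG", n_udeg), rep("null", n_null))
  rescued <- c(rep(c(TRUE, FALSE), c(n_rescued_odeg, n_odeg - n_rescued_odeg)),
               rep(c(TRUE, FALSE), c(n_rescued_udeg, n_udeg - n_rescued_udeg)),
               rep(FALSE, n_null))
  young_mean <- rlnorm(n, cfg$expr_meanlog, cfg$expr_sdlog)
  old_mean <- young_mean * 2^ifelse(class == "ODEG", 1,
                                    ifelse(class == "UDEG", -1, 0))
  treat_mean <- ifelse(rescued, young_mean, old_mean)
  sample_sheet <- tibble::tibble(
    sample_id = paste0(rep(cfg$groups, each = cfg$n_per_group),
                       "_", seq_len(cfg$n_per_group)),
    group = rep(cfg$groups, each = cfg$n_per_group)
  )
  fpkm <- tibble::tibble(gene_id = gene_id)
  for (si in seq_len(nrow(sample_sheet))) {
    g <- sample_sheet$group[si]
    mu <- if (g == "young") young_mean
          else if (g == treated) treat_mean
          else old_mean
    fpkm[[sample_sheet$sample_id[si]]] <- mu
  }
  truth <- tibble::tibble(gene_id = gene_id, class = class)
  truth[[paste0("rescued_", treated)]] <- rescued
  aging_degs <- tibble::tibble(
    feature_id = gene_id[class != "null"],
    direction = class[class != "null"],
    significant = TRUE
  )
  list(fpkm = fpkm, sample_sheet = sample_sheet, truth = truth,
       aging_degs = aging_degs)
}

#' Simulate gene models, GO annotations and a small ontology
#'
#' Places genes so that configurable fractions of the aging bins fall inside
#' promoters and gene bodies: for a "body" assignment the gene's
#' transcription span covers the bin; for a "promoter" assignment a + strand
#' gene starts just downstream so the bin sits in its 2 kb upstream window.
#' Annotated genes reuse the expression generator's gene ids, so the mapped
#' differentially methylated genes carry expression values. Remaining genes
#' are placed on a separate gene-only chromosome. The ontology is a small
#' is_a DAG -- one root, three depth-1 and six depth-2 terms, and
#' `n_go_terms` leaf terms at depth 3 -- with each leaf annotating
#' `genes_per_term` genes; the first leaf is biased toward aging genes so
#' enrichment has signal.
#'
#' @param config A [sim_config()].
#' @param meth_truth Bin truth tibble from [simulate_methylome()].
#' @param expr_truth Gene truth tibble from [simulate_expression()].
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return List: `genes` (gene models), `bin_gene_map` (tibble `region`,
#'   `gene_id`, `placement`), `annotations` (gene-term tibble), `ontology`
#'   (as [read_obo()]).
#' @export
simulate_annotation <- function(config = sim_config(), meth_truth,
                                expr_truth, seed = config$seed + 2L) {
  cfg <- config
  set.seed(seed)
  gene_id <- expr_truth$gene_id
  aging_bins <- meth_truth[meth_truth$aging != "null", ]
  n_a <- nrow(aging_bins)
  placement <- sample(c("body", "promoter", "none"), n_a, replace = TRUE,
                      prob = c(cfg$body_hit_fraction,
                               cfg$promoter_hit_fraction,
                               max(0, 1 - cfg$body_hit_fraction -
                                     cfg$promoter_hit_fraction)))
  # pair aging bins preferentially with aging genes
  aging_genes <- expr_truth$gene_id[expr_truth$class != "null"]
  other_genes <- setdiff(gene_id, aging_genes)
  assigned <- c(head(aging_genes, n_a),
                head(other_genes, max(0, n_a - length(aging_genes))))[1:n_a]
  placed <- placement != "none" & !is.na(assigned)
  genes_placed <- tibble::tibble(
    gene_id = assigned[placed],
    chrom = aging_bins$chrom[placed],
    strand = "+",
    tx_start = ifelse(placement[placed] == "body",
                      pmax(aging_bins$start[placed] - 100L, 0L),
                      aging_bins$end[placed] + 100L),
    tx_end = ifelse(placement[placed] == "body",
                    aging_bins$end[placed] + 500L,
                    aging_bins$end[placed] + 1200L)
  )
  rest <- setdiff(gene_id, genes_placed$gene_id)
  genes_rest <- tibble::tibble(
    gene_id = rest, chrom = "chrGenes",
    strand = sample(c("+", "-"), length(rest), replace = TRUE),
    tx_start = seq(10000L, by = 10000L, length.out = length(rest))
  )
  genes_rest$tx_end <- genes_rest$tx_start + 2000L
  genes <- dplyr::bind_rows(genes_placed, genes_rest)
  # ontology: root -> 3 -> 6 -> n_go_terms leaves
  d1 <- sprintf("GO:000001%d", 1:3)
  d2 <- sprintf("GO:00002%02d", 1:6)
  leaves <- sprintf("GO:10000%02d", seq_len(cfg$n_go_terms))
  ontology <- tibble::tibble(
    term_id = c("GO:0000001", d1, d2, leaves),
    name = c("biological_process", paste0("branch_", 1:3),
             paste0("process_", 1:6), paste0("leaf_process_",
                                             seq_len(cfg$n_go_terms))),
    namespace = "biological_process",
    parents = c(list(character()),
                purrr::map(1:3, ~"GO:0000001"),
                purrr::map(d2, ~ sample(d1, 1)),
                purrr::map(leaves, ~ sample(d2, 1)))
  )
  ontology$min_depth <- compute_min_depth(ontology$term_id, ontology$parents)
  anno <- purrr::imap(leaves, function(term, i) {
    pool <- if (i == 1) {
      c(aging_genes, sample(gene_id, 5))
    } else {
      gene_id
    }
    tibble::tibble(gene_id = sample(pool, min(cfg$genes_per_term,
                                              length(pool))),
                   term_id = term)
  }) |>
    dplyr::bind_rows() |>
    dplyr::distinct()
  list(genes = genes,
       bin_gene_map = tibble::tibble(region = aging_bins$region[placed],
                                     gene_id = assigned[placed],
                                     placement = placement[placed]),
       annotations = anno, ontology = ontology)
}

#' Simulate a complete study
#'
#' Runs [simulate_methylome()], [simulate_expression()] and
#' [simulate_annotation()] with sub-seeds derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `sample_sheet`, `calls`, `meth_truth`,
#'   `fpkm`, `expr_truth`, `genes`, `bin_gene_map`, `annotations`,
#'   `ontology`.
#' @export
simulate_study <- function(config = sim_config()) {
  meth <- simulate_methylome(config, seed = config$seed)
  expr <- simulate_expression(config, seed = config$seed + 1L)
  anno <- simulate_annotation(config, meth$truth, expr$truth,
                              seed = config$seed + 2L)
  list(config = config, sample_sheet = meth$sample_sheet,
       calls = meth$calls, meth_truth = meth$truth,
       fpkm = expr$fpkm, expr_truth = expr$truth,
       genes = anno$genes, bin_gene_map = anno$bin_gene_map,
       annotations = anno$annotations, ontology = anno$ontology)
}

#' Write a simulated study to disk in the pipeline's input dialects
#'
#' One CpG call TSV per sample, a sample sheet, the FPKM table, gene models
#' as BED6, gene-to-GO annotations as 2-column TSV, and the ontology as OBO.
#'
#' @param study List from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in study$sample_sheet$sample_id) {
    write_cpg_table(dplyr::filter(study$calls, .data$sample_id == s),
                    file.path(dir, paste0("calls_", s, ".tsv")))
  }
  write_tsv_commented(study$sample_sheet, file.path(dir, "samples.tsv"))
  write_expression_table(study$fpkm, file.path(dir, "fpkm.tsv"))
  bed <- tibble::tibble(study$genes$chrom, study$genes$tx_start,
                        study$genes$tx_end, study$genes$gene_id, 0L,
                        study$genes$strand)
  readr::write_tsv(bed, file.path(dir, "genes.bed"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(study$annotations, file.path(dir, "gene2go.tsv"),
                   col_names = FALSE, progress = FALSE)
  write_obo(study$ontology, file.path(dir, "go.obo"))
  invisible(dir)
}
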