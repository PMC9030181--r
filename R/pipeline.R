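#' Run the full analysis on a (synthetic or supplied) study
#'
#' Chains every stage: binning, young-vs-old DMR and DEG calling, trajectory
#' fits for each treated group on both axes, DMR and DEG amelioration with
#' DR/RALL overlap, DMR-to-gene annotation, methylation-expression
#' correlation over the ameliorated DMGs, and GO over-representation of the
#' DR-ameliorated under-expressed genes. With `out_dir` set, every stage's
#' table is written as a commented TSV together with a `summary.tsv`.
#'
#' @param config A [sim_config()]; used to generate a synthetic study when
#'   `study` is not supplied.
#' @param study Optional study list shaped like [simulate_study()] output
#'   (fields `calls`, `sample_sheet`, `fpkm`, `genes`, `annotations`,
#'   `ontology`).
#' @param out_dir Optional run directory for TSV outputs.
#' @param p_threshold,delta_threshold DMR/DEG thresholds (defaults 0.05, 0.1).
#' @param upstream Promoter span for annotation, bp.
#' @param alpha GO significance threshold on raw p.
#' @return A `methylrescue_run` list: `bin_levels`, `group_level`,
#'   `aging_dmrs`, `trajectories` (named list of `trajectory_fit`),
#'   `dmr_amelioration`, `deg_calls`, `deg_amelioration`, `deg_overlap`,
#'   `dmg_records`, `correlations`, `enrichment`, `summary`.
#' @export
run_pipeline <- function(config = sim_config(), study = NULL, out_dir = NULL,
                         p_threshold = 0.05, delta_threshold = 0.1,
                         upstream = 2000, alpha = 0.01) {
  study <- study %||% simulate_study(config)
  needed <- c("calls", "sample_sheet", "fpkm")
  miss <- needed[!needed %in% names(study)]
  if (length(miss) > 0) {
    abort(paste0("study is missing component(s): ",
                 paste(miss, collapse = ", ")))
  }
  sheet <- study$sample_sheet
  treated_groups <- intersect(c("DR", "RALL"), unique(sheet$group))

  levels <- bin_methylation(study$calls, sheet)
  grp <- group_levels(levels, sheet)

  aging_dmrs <- call_dmrs(levels, sheet, "young", "old",
                          p_threshold = p_threshold,
                          delta_threshold = delta_threshold)

  trajectories <- list()
  for (g in treated_groups) {
    for (resp in c("treated_minus_old", "treated_minus_young")) {
      trajectories[[paste(g, resp, sep = ".")]] <-
        fit_trajectory(grp, treated = g, response = resp)
    }
  }

  dmr_amelio <- purrr::map(
    setNames(treated_groups, treated_groups),
    ~ classify_dmr_amelioration(aging_dmrs, grp, treated = .x)
  )

  degs <- call_degs(study$fpkm, sheet, "young", "old",
                    p_threshold = p_threshold)
  deg_amelio <- purrr::map(
    setNames(treated_groups, treated_groups),
    ~ classify_deg_amelioration(degs, study$fpkm, sheet, treated = .x)
  )
  deg_overlap <- if (length(treated_groups) == 2) {
    overlap_sets(deg_amelio[[1]], deg_amelio[[2]])
  }

  dmg_records <- correlations <- enrichment <- NULL
  if (!is.null(study$genes)) {
    amelio_dr <- dplyr::filter(dmr_amelio[[1]], .data$ameliorated)
    dmg_records <- map_dmrs_to_genes(amelio_dr, study$genes,
                                     upstream = upstream)
    pairs <- dmg_records |>
      dplyr::filter(!is.na(.data$gene_id),
                    .data$gene_id %in% study$fpkm$gene_id) |>
      dplyr::distinct(gene_id = .data$gene_id, region = .data$dmr_id)
    if (nrow(pairs) > 0) {
      correlations <- correlate_pairs(study$fpkm, levels, pairs)
    }
  }
  if (!is.null(study$annotations) && !is.null(study$ontology)) {
    study_set <- deg_amelio[[1]] |>
      dplyr::filter(.data$ameliorated, .data$aging_direction == "UDEG") |>
      dplyr::pull("feature_id")
    if (length(study_set) > 0) {
      enrichment <- go_enrich(study_set, study$fpkm$gene_id,
                              study$annotations, study$ontology,
                              alpha = alpha)
    }
  }

  summarise_amelio <- function(lst) {
    purrr::imap(lst, ~ dplyr::mutate(amelioration_summary(.x),
                                     treated_group = .y)) |>
      dplyr::bind_rows()
  }
  summary <- dplyr::bind_rows(
    tibble::tibble(metric = "n_bins", value = nrow(levels)),
    tibble::tibble(metric = "n_aging_dmrs", value = sum(aging_dmrs$significant)),
    tibble::tibble(metric = "n_aging_degs", value = sum(degs$significant)),
    purrr::imap(trajectories,
                ~ tibble::tibble(metric = paste0("slope.", .y),
                                 value = .x$slope)) |> dplyr::bind_rows(),
    purrr::imap(dmr_amelio, ~ tibble::tibble(
      metric = paste0("pct_dmr_ameliorated.", .y),
      value = amelioration_summary(.x)$percent_ameliorated[
        amelioration_summary(.x)$aging_direction == "all"])) |>
      dplyr::bind_rows(),
    purrr::imap(deg_amelio, ~ tibble::tibble(
      metric = paste0("pct_deg_ameliorated.", .y),
      value = amelioration_summary(.x)$percent_ameliorated[
        amelioration_summary(.x)$aging_direction == "all"])) |>
      dplyr::bind_rows(),
    tibble::tibble(metric = "n_significant_correlations",
                   value = if (is.null(correlations)) NA_real_ else
                     sum(correlations$significant)),
    tibble::tibble(metric = "n_enriched_terms",
                   value = if (is.null(enrichment)) NA_real_ else
                     sum(enrichment$significant))
  )

  run <- structure(list(
    bin_levels = levels, group_level = grp, aging_dmrs = aging_dmrs,
    trajectories = trajectories, dmr_amelioration = dmr_amelio,
    deg_calls = degs, deg_amelioration = deg_amelio,
    deg_overlap = deg_overlap, dmg_records = dmg_records,
    correlations = correlations, enrichment = enrichment,
    summary = summary, sample_sheet = sheet
  ), class = "methylrescue_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Serialise a run directory of commented TSVs.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name, comments = character()) {
    if (!is.null(x)) write_tsv_commented(x, file.path(out_dir, name), comments)
  }
  w(run$bin_levels, "bins.tsv", "bin-by-sample methylation levels")
  w(run$aging_dmrs, "aging_dmrs.tsv", "young vs old moderated-t calls")
  w(run$deg_calls, "aging_degs.tsv",
    c("young vs old expression calls on log2(FPKM+1)",
      "test=moderated-t stand-in"))
  for (nm in names(run$trajectories)) {
    w(glance(run$trajectories[[nm]]), paste0("trajectory_", nm, ".tsv"))
    w(run$trajectories[[nm]]$data, paste0("scatter_", nm, ".tsv"),
      "one row per bin: x = old - young, y per response")
  }
  for (nm in names(run$dmr_amelioration)) {
    w(run$dmr_amelioration[[nm]], paste0("dmr_amelioration_", nm, ".tsv"))
  }
  for (nm in names(run$deg_amelioration)) {
    w(run$deg_amelioration[[nm]], paste0("deg_amelioration_", nm, ".tsv"))
  }
  if (!is.null(run$deg_overlap)) w(run$deg_overlap$summary, "deg_overlap.tsv")
  w(run$dmg_records, "dmgs.tsv")
  w(run$correlations, "correlations.tsv")
  w(run$enrichment, "enrichment.tsv")
  w(run$summary, "summary.tsv")
  invisible(out_dir)
}

#' @export
print.methylrescue_run <- function(x, ...) {
  cat("methylrescue pipeline run\n")
  print(x$summary, n = Inf)
  invisible(x)
}
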