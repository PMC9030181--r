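#' Classify amelioration of aging DMRs by a treated group
#'
#' An aging-related hyper DMR (methylation gained from young to old) is
#' ameliorated when the treated group's mean methylation is strictly lower
#' than the old group's; an aging hypo DMR is ameliorated when the treated
#' mean is strictly higher. Ties are not ameliorated. Only direction is
#' required -- no significance test on the treated-vs-old contrast -- unless
#' `require_significance` is set, in which case a moderated test on the
#' per-sample levels must also pass `p_threshold`.
#'
#' @param aging_dmrs DMR call tibble from [call_dmrs()] (young vs old); rows
#'   with `significant = FALSE` are dropped if the column is present.
#' @param group_level Tibble with a `region` column and one mean-methylation
#'   column per group (see [group_levels()]).
#' @param treated Treated group column name (e.g. `"DR"`).
#' @param old Old group column name.
#' @param require_significance Optional extra moderated-test filter on the
#'   treated-vs-old contrast; needs `bin_levels` and `sample_sheet`.
#' @param bin_levels,sample_sheet,p_threshold Used only when
#'   `require_significance = TRUE`.
#' @return Tibble: `feature_id`, `aging_direction`, `treated_group`,
#'   `old_value`, `treated_value`, `ameliorated`.
#' @export
classify_dmr_amelioration <- function(aging_dmrs, group_level, treated,
                                      old = "old",
                                      require_significance = FALSE,
                                      bin_levels = NULL, sample_sheet = NULL,
                                      p_threshold = 0.05) {
  if ("significant" %in% names(aging_dmrs)) {
    aging_dmrs <- dplyr::filter(aging_dmrs, .data$significant)
  }
  missing <- setdiff(aging_dmrs$feature_id, group_level$region)
  if (length(missing) > 0) {
    abort(paste0("treated group levels missing for bin(s): ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  lv <- group_level[match(aging_dmrs$feature_id, group_level$region), ]
  out <- tibble::tibble(
    feature_id = aging_dmrs$feature_id,
    aging_direction = aging_dmrs$direction,
    treated_group = treated,
    old_value = lv[[old]],
    treated_value = lv[[treated]],
    ameliorated = ifelse(aging_dmrs$direction == "hyper",
                         lv[[treated]] < lv[[old]],
                         lv[[treated]] > lv[[old]])
  )
  if (require_significance) {
    if (is.null(bin_levels) || is.null(sample_sheet)) {
      abort("require_significance needs bin_levels and sample_sheet")
    }
    contrast <- call_dmrs(bin_levels, sample_sheet, old, treated,
                          p_threshold = p_threshold, delta_threshold = 0)
    keep <- contrast$feature_id[contrast$p_value < p_threshold]
    out$ameliorated <- out$ameliorated & out$feature_id %in% keep
  }
  out
}

#' Classify amelioration of aging DEGs by a treated group
#'
#' Mirror of [classify_dmr_amelioration()] for expression: an aging-ODEG
#' (over-expressed in old) is treated-ameliorated when the treated group's
#' mean FPKM is strictly lower than old's; an aging-UDEG when it is strictly
#' higher.
#'
#' @param aging_degs DEG call tibble from [call_degs()] (young vs old);
#'   non-significant rows are dropped if flagged.
#' @param fpkm Tibble `gene_id` plus sample FPKM columns.
#' @param sample_sheet Sample sheet.
#' @param treated,old Group labels.
#' @return Tibble as [classify_dmr_amelioration()] with `aging_direction` in
#'   ODEG/UDEG and FPKM group means in the value columns.
#' @export
classify_deg_amelioration <- function(aging_degs, fpkm, sample_sheet,
                                      treated, old = "old") {
  if ("significant" %in% names(aging_degs)) {
    aging_degs <- dplyr::filter(aging_degs, .data$significant)
  }
  check_groups(sample_sheet, c(treated, old))
  cols <- sample_cols(fpkm, sample_sheet)
  gm <- tibble::tibble(
    gene_id = fpkm$gene_id,
    old_value = rowMeans(fpkm[intersect(samples_of(sample_sheet, old), cols)]),
    treated_value = rowMeans(fpkm[intersect(samples_of(sample_sheet, treated),
                                            cols)])
  )
  missing <- setdiff(aging_degs$feature_id, gm$gene_id)
  if (length(missing) > 0) {
    abort(paste0("expression missing for gene(s): ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  lv <- gm[match(aging_degs$feature_id, gm$gene_id), ]
  tibble::tibble(
    feature_id = aging_degs$feature_id,
    aging_direction = aging_degs$direction,
    treated_group = treated,
    old_value = lv$old_value,
    treated_value = lv$treated_value,
    ameliorated = ifelse(aging_degs$direction == "ODEG",
                         lv$treated_value < lv$old_value,
                         lv$treated_value > lv$old_value)
  )
}

#' Summarise amelioration calls
#'
#' @param calls Tibble from one of the classifiers.
#' @return Per-direction and overall counts with ameliorated fractions (in
#'   percent, as conventionally reported).
#' @export
amelioration_summary <- function(calls) {
  per_dir <- calls |>
    dplyr::summarise(n_aging = dplyr::n(),
                     n_ameliorated = sum(.data$ameliorated),
                     .by = "aging_direction")
  overall <- tibble::tibble(aging_direction = "all",
                            n_aging = nrow(calls),
                            n_ameliorated = sum(calls$ameliorated))
  out <- dplyr::bind_rows(per_dir, overall)
  out$percent_ameliorated <- 100 * out$n_ameliorated / out$n_aging
  out
}

#' Overlap between two treated groups' ameliorated feature sets
#'
#' @param calls_a,calls_b Amelioration tibbles over the same feature
#'   universe (e.g. DR and RALL).
#' @return List with `summary` (per-direction and overall intersection,
#'   union and union-fraction overlap of the ameliorated sets) and `shared`
#'   (character vector of overall shared ameliorated features).
#' @export
overlap_sets <- function(calls_a, calls_b) {
  amel <- function(x, dir = NULL) {
    x <- dplyr::filter(x, .data$ameliorated)
    if (!is.null(dir)) x <- dplyr::filter(x, .data$aging_direction == dir)
    unique(x$feature_id)
  }
  dirs <- union(unique(calls_a$aging_direction),
                unique(calls_b$aging_direction))
  rows <- purrr::map(c(as.list(dirs), list(NULL)), function(d) {
    a <- amel(calls_a, d)
    b <- amel(calls_b, d)
    u <- union(a, b)
    tibble::tibble(
      direction = d %||% "all",
      n_a = length(a), n_b = length(b),
      n_intersect = length(intersect(a, b)), n_union = length(u),
      fraction_overlap = if (length(u) == 0) NA_real_ else
        length(intersect(a, b)) / length(u)
    )
  })
  list(summary = dplyr::bind_rows(rows),
       shared = intersect(amel(calls_a), amel(calls_b)))
}
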