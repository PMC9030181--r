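#' Filter CpG calls by context and coverage
#'
#' Keeps CpG-context sites with at least `min_reads` total reads; the
#' boundary is inclusive (a site with exactly `min_reads` reads is retained,
#' i.e. sites with read numbers below the floor are removed).
#'
#' @param calls Call tibble (any number of samples) from [read_cpg_table()]
#'   or [simulate_methylome()].
#' @param min_reads Coverage floor, default 5.
#' @param context Context class to retain, default `"CpG"`.
#' @return The retained calls, same columns.
#' @export
filter_sites <- function(calls, min_reads = 5, context = "CpG") {
  dplyr::filter(calls, .data$context == !!context,
                .data$total_reads >= min_reads)
}

#' Positions retained in enough samples
#'
#' Bins are built on one shared site set so that the bin-by-sample level
#' matrix is complete. By default a site must survive filtering in every
#' sample (intersection); `min_samples` relaxes this to "present in at least
#' k samples", in which case bin levels for a sample are computed from the
#' member sites that sample does have.
#'
#' @param calls Filtered multi-sample call tibble.
#' @param min_samples Minimum number of samples a site must be called in;
#'   default all samples present in `calls`.
#' @return Tibble `chrom`, `pos`, sorted.
#' @export
shared_sites <- function(calls, min_samples = NULL) {
  n_total <- dplyr::n_distinct(calls$sample_id)
  min_samples <- min_samples %||% n_total
  calls |>
    dplyr::distinct(.data$chrom, .data$pos, .data$sample_id) |>
    dplyr::count(.data$chrom, .data$pos) |>
    dplyr::filter(.data$n >= min_samples) |>
    dplyr::select("chrom", "pos") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Group adjacent CpG sites into bins
#'
#' Greedy left-to-right partition: a new bin starts whenever the distance to
#' the previous site exceeds `max_gap` or the chromosome changes. "No more
#' than" is inclusive: a gap of exactly `max_gap` stays inside one bin. The
#' bin span runs from the first member site to one past the last, so every
#' retained site belongs to exactly one bin and bins on a chromosome are
#' disjoint and ordered.
#'
#' @param sites Tibble `chrom`, `pos` (0-based), e.g. from [shared_sites()].
#' @param max_gap Maximum adjacent-site distance inside a bin (bp),
#'   default 1000.
#' @return Tibble with columns `region` (1-based inclusive display string),
#'   `chrom`, `start`, `end` (0-based half-open), `n_sites`, and `site_pos`
#'   (list column of member positions).
#' @export
build_bins <- function(sites, max_gap = 1000) {
  stopifnot(max_gap > 0)
  if (nrow(sites) == 0) {
    return(tibble::tibble(region = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_sites = integer(), site_pos = list()))
  }
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos)
  bins <- sites |>
    dplyr::mutate(
      gap = .data$pos - dplyr::lag(.data$pos),
      new_bin = is.na(.data$gap) | .data$gap > max_gap,
      .by = "chrom"
    ) |>
    dplyr::mutate(bin = cumsum(.data$new_bin)) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos) + 1L,
      n_sites = dplyr::n(), site_pos = list(.data$pos),
      .by = c("chrom", "bin")
    ) |>
    dplyr::select(-"bin")
  bins$region <- region_string(bins$chrom, bins$start, bins$end)
  dplyr::relocate(bins, "region")
}

#' Per-sample and per-group bin methylation
#'
#' The methylation level of a bin in a sample is the unweighted mean of the
#' member sites' levels (each site's level being methylated/total reads);
#' coverage does not weight the mean. `group_levels()` then averages the
#' member samples of each group.
#'
#' @param bins Bin tibble from [build_bins()].
#' @param calls Filtered multi-sample call tibble covering the bin sites.
#' @param sample_sheet Sample sheet tibble (`sample_id`, `group`).
#' @param require_complete Error if some sample lacks a call at some member
#'   site (default `TRUE`; set `FALSE` under a `min_samples` site policy, in
#'   which case the sample's bin level averages its available member sites).
#' @return A wide tibble: `region`, `chrom`, `start`, `end`, `n_sites`, then
#'   one level column per sample, all levels in \[0, 1\].
#' @export
bin_levels <- function(bins, calls, sample_sheet, require_complete = TRUE) {
  check_groups(sample_sheet, character())
  membership <- bins |>
    dplyr::select("region", "chrom", "site_pos") |>
    tidyr::unnest_longer("site_pos", values_to = "pos")
  per_sample <- membership |>
    dplyr::inner_join(calls, by = c("chrom", "pos"),
                      relationship = "many-to-many") |>
    dplyr::summarise(level = mean(.data$level), n_obs = dplyr::n(),
                     .by = c("region", "sample_id"))
  if (require_complete) {
    expected <- nrow(sample_sheet) * nrow(bins)
    full <- sum(per_sample$n_obs)
    need <- sum(bins$n_sites) * nrow(sample_sheet)
    if (nrow(per_sample) < expected || full < need) {
      abort("missing site/sample combination in bin levels; build bins on the intersection site set or pass require_complete = FALSE")
    }
  }
  wide <- per_sample |>
    dplyr::select(-"n_obs") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "level")
  bins |>
    dplyr::select("region", "chrom", "start", "end", "n_sites") |>
    dplyr::inner_join(wide, by = "region")
}

#' @rdname bin_levels
#' @param levels Wide feature-by-sample tibble (bin levels or any table whose
#'   sample columns match the sheet).
#' @param groups Groups to aggregate; default every group in the sheet.
#' @return `group_levels()`: the non-sample columns of `levels` plus one mean
#'   column per group.
#' @export
group_levels <- function(levels, sample_sheet, groups = NULL) {
  groups <- groups %||% unique(sample_sheet$group)
  check_groups(sample_sheet, groups)
  out <- dplyr::select(levels, -dplyr::any_of(sample_sheet$sample_id))
  for (g in groups) {
    cols <- intersect(samples_of(sample_sheet, g), names(levels))
    if (length(cols) == 0) abort(paste0("no sample columns for group ", g))
    out[[g]] <- rowMeans(levels[cols])
  }
  out
}

#' One-call binning pipeline
#'
#' Chains [filter_sites()], [shared_sites()], [build_bins()] and
#' [bin_levels()] with the study defaults: CpG context, coverage floor 5,
#' adjacency window 1 kb, intersection site policy.
#'
#' @inheritParams filter_sites
#' @inheritParams build_bins
#' @inheritParams shared_sites
#' @param sample_sheet Sample sheet tibble.
#' @return Wide bin-by-sample level tibble (see [bin_levels()]).
#' @export
bin_methylation <- function(calls, sample_sheet, min_reads = 5,
                            max_gap = 1000, context = "CpG",
                            min_samples = NULL) {
  retained <- filter_sites(calls, min_reads = min_reads, context = context)
  sites <- shared_sites(retained, min_samples = min_samples)
  bins <- build_bins(sites, max_gap = max_gap)
  bin_levels(bins, retained, sample_sheet,
             require_complete = is.null(min_samples))
}
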