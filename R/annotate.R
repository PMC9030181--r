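#' Promoter intervals of gene models
#'
#' The promoter is the `upstream` bp immediately 5' of the transcription
#' start site: `[tx_start - upstream, tx_start)` on the + strand and
#' `[tx_end, tx_end + upstream)` on the - strand, clipped at position 0. The
#' span is a convention, not something the data pin down, and differentially
#' methylated gene counts depend on it -- vary `upstream` to see how much.
#'
#' @param genes Gene model tibble from [read_gene_models()].
#' @param upstream Promoter length in bp, default 2000.
#' @return `genes` with added `prom_start`, `prom_end` (0-based half-open).
#' @export
promoter_of <- function(genes, upstream = 2000) {
  stopifnot(upstream > 0)
  plus <- genes$strand == "+"
  genes$prom_start <- ifelse(plus, pmax(genes$tx_start - upstream, 0L),
                             genes$tx_end)
  genes$prom_end <- ifelse(plus, genes$tx_start, genes$tx_end + upstream)
  genes
}

# 0-based half-open overlap of two interval sets on shared chromosomes,
# via IRanges; returns tibble(query_idx, subject_idx).
overlap_pairs <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- list(tibble::tibble(query_idx = integer(), subject_idx = integer()))
  for (chr in intersect(unique(q_chrom), unique(s_chrom))) {
    qi <- which(q_chrom == chr)
    si <- which(s_chrom == chr)
    # half-open [s, e) -> 1-based closed [s+1, e] for IRanges
    q <- IRanges::IRanges(start = q_start[qi] + 1L, end = q_end[qi])
    s <- IRanges::IRanges(start = s_start[si] + 1L, end = s_end[si])
    hits <- IRanges::findOverlaps(q, s)
    out[[chr]] <- tibble::tibble(
      query_idx = qi[S4Vectors::queryHits(hits)],
      subject_idx = si[S4Vectors::subjectHits(hits)]
    )
  }
  dplyr::bind_rows(out)
}

#' Map DMRs onto promoters and gene bodies
#'
#' Every DMR overlapping (by at least 1 bp, half-open intersection) a gene's
#' promoter or transcription span yields one record per (gene, region class,
#' DMR); a DMR hitting both the promoter and the body of one gene therefore
#' yields two records. DMRs touching no gene are retained with an empty gene
#' field. Genes whose promoter or body overlaps a DMR are the differentially
#' methylated genes (DMGs).
#'
#' @param dmrs Tibble with a `feature_id` region-string column (e.g. an
#'   amelioration or DMR call table); coordinates are parsed from it unless
#'   `chrom`/`start`/`end` columns are present. `aging_direction` (or
#'   `direction`) and `ameliorated` columns are carried through when present.
#' @param genes Gene model tibble.
#' @param upstream Promoter length passed to [promoter_of()].
#' @return Tibble: `dmr_id`, `gene_id` (NA if unannotated), `region`
#'   (promoter/gene_body/NA), plus carried direction/amelioration columns.
#' @export
map_dmrs_to_genes <- function(dmrs, genes, upstream = 2000) {
  if (!all(c("chrom", "start", "end") %in% names(dmrs))) {
    coords <- parse_region(dmrs$feature_id)
    dmrs <- dplyr::bind_cols(dmrs, coords)
  }
  genes <- promoter_of(genes, upstream = upstream)
  carried <- intersect(c("aging_direction", "direction", "ameliorated"),
                       names(dmrs))
  hit_tbl <- function(s_start, s_end, label) {
    h <- overlap_pairs(dmrs$chrom, dmrs$start, dmrs$end,
                       genes$chrom, s_start, s_end)
    tibble::tibble(
      dmr_idx = h$query_idx,
      gene_id = genes$gene_id[h$subject_idx],
      region = label
    )
  }
  hits <- dplyr::bind_rows(
    hit_tbl(genes$prom_start, genes$prom_end, "promoter"),
    hit_tbl(genes$tx_start, genes$tx_end, "gene_body")
  ) |>
    dplyr::distinct()
  unhit <- setdiff(seq_len(nrow(dmrs)), hits$dmr_idx)
  all_rows <- dplyr::bind_rows(
    hits,
    tibble::tibble(dmr_idx = unhit, gene_id = NA_character_,
                   region = NA_character_)
  )
  out <- tibble::tibble(
    dmr_id = dmrs$feature_id[all_rows$dmr_idx],
    gene_id = all_rows$gene_id,
    region = all_rows$region
  )
  for (cc in carried) out[[cc]] <- dmrs[[cc]][all_rows$dmr_idx]
  dplyr::arrange(out, match(.data$dmr_id, dmrs$feature_id))
}

#' Summarise DMG counts by direction
#'
#' Deduplicates genes within each aging direction (a gene hit by several
#' DMRs, or in both promoter and body, counts once per direction).
#'
#' @param dmg_records Tibble from [map_dmrs_to_genes()].
#' @return Tibble `aging_direction`, `n_genes`.
#' @export
dmg_summary <- function(dmg_records) {
  dir_col <- intersect(c("aging_direction", "direction"),
                       names(dmg_records))[1]
  if (is.na(dir_col)) abort("no direction column to summarise by")
  dmg_records |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::distinct(.data$gene_id, dir = .data[[dir_col]]) |>
    dplyr::count(.data$dir, name = "n_genes") |>
    dplyr::rename(aging_direction = "dir")
}
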