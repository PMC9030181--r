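#' Upper-tail hypergeometric over-representation probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance that a random
#' `n`-gene study set drawn from an `N`-gene background containing `K`
#' term-annotated genes would hit the term `k` or more times.
#'
#' @param k Observed study genes annotated to the term.
#' @param n Study-set size.
#' @param K Background genes annotated to the term.
#' @param N Background size.
#' @return The tail probability, in (0, 1].
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (any(k < 0 | k > pmin(n, K)) || any(n > N) || any(K > N)) {
    abort("hypergeometric bounds violated: need 0 <= k <= min(n, K), n, K <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO over-representation of a study gene set
#'
#' One hypergeometric test per GO term carrying at least one study gene.
#' Counts are direct annotations only -- no propagation to ancestors, so
#' annotating a parent never changes a child's counts. Bonferroni correction
#' multiplies by m, the number of terms tested (terms with >= 1 study gene).
#' A term is reported significant when its raw p-value is below `alpha` and
#' the term is deep enough: terms in the top three levels of the ontology
#' (`min_depth` < `min_depth_keep`, i.e. shortest is_a path to the root of
#' 0, 1 or 2) are generic and are excluded from the significant set, though
#' they remain in the full table.
#'
#' @param study_genes Character vector; must be a subset of the background.
#' @param background_genes Character vector, the test universe.
#' @param annotations Tibble `gene_id`, `term_id` (direct annotations).
#' @param ontology Tibble from [read_obo()] (`term_id`, `name`, `min_depth`).
#' @param alpha Significance threshold on the raw p-value, default 0.01.
#' @param min_depth_keep Minimum ontology depth for a significant call,
#'   default 3.
#' @return Tibble sorted by p-value: `term_id`, `name`, `min_depth`,
#'   `study_count`, `study_size`, `pop_count`, `pop_size`, `p_value`,
#'   `bonferroni`, `significant`.
#' @export
go_enrich <- function(study_genes, background_genes, annotations, ontology,
                      alpha = 0.01, min_depth_keep = 3) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  stray <- setdiff(study_genes, background_genes)
  if (length(stray) > 0) {
    abort(paste0("study gene(s) absent from background: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  anno <- annotations |>
    dplyr::filter(.data$gene_id %in% background_genes) |>
    dplyr::distinct(.data$gene_id, .data$term_id)
  counts <- anno |>
    dplyr::summarise(
      pop_count = dplyr::n_distinct(.data$gene_id),
      study_count = dplyr::n_distinct(
        .data$gene_id[.data$gene_id %in% study_genes]),
      .by = "term_id"
    ) |>
    dplyr::filter(.data$study_count >= 1)
  m <- nrow(counts)
  if (m == 0) {
    return(tibble::tibble(term_id = character(), name = character(),
                          min_depth = integer(), study_count = integer(),
                          study_size = integer(), pop_count = integer(),
                          pop_size = integer(), p_value = numeric(),
                          bonferroni = numeric(), significant = logical()))
  }
  N <- length(background_genes)
  n <- length(study_genes)
  counts$p_value <- hypergeom_tail(counts$study_count, n, counts$pop_count, N)
  counts$bonferroni <- pmin(1, counts$p_value * m)
  oi <- match(counts$term_id, ontology$term_id)
  counts$name <- ontology$name[oi]
  counts$min_depth <- ontology$min_depth[oi]
  counts$study_size <- n
  counts$pop_size <- N
  counts$significant <- !is.na(counts$min_depth) &
    counts$p_value < alpha & counts$min_depth >= min_depth_keep
  counts |>
    dplyr::select("term_id", "name", "min_depth", "study_count",
                  "study_size", "pop_count", "pop_size", "p_value",
                  "bonferroni", "significant") |>
    dplyr::arrange(.data$p_value)
}
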