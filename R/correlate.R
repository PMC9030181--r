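#' Pearson correlation and its t-distribution p-value
#'
#' `pearson_r()` is the product-moment coefficient; `pearson_pvalue()` refers
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) to a Student t with n - 2 degrees of
#' freedom, two-sided. With the study's 15 samples (five groups of three)
#' the test has 13 df, which reproduces the reported methylation-expression
#' pairs, e.g. r = 0.714 at n = 15 gives p = 2.8e-3.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-constant.
#' @return `pearson_r()`: the coefficient. `pearson_pvalue()`: the two-sided
#'   p-value.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: correlation undefined")
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

#' @rdname pearson_r
#' @param r Pearson coefficient, |r| <= 1.
#' @param n Number of paired samples, n >= 3.
#' @export
pearson_pvalue <- function(r, n) {
  stopifnot(n >= 3, all(abs(r) <= 1))
  p <- rep(0, length(r))
  at_one <- abs(r) == 1
  if (any(at_one)) warn("|r| = 1: p-value set to 0")
  ok <- !at_one
  t <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-abs(t), df = n - 2)
  p
}

#' Correlate gene expression with bin methylation across samples
#'
#' For each (gene, bin) pair -- typically every differentially methylated
#' gene with the DMR bins that hit it -- computes the Pearson correlation of
#' the gene's FPKM with the bin's methylation level across all shared
#' samples. A pair is significant when |r| > 0.5 and p < 0.05 (two-sided
#' t-test, no multiple-testing correction). Pairs where either vector is
#' constant are skipped with a message.
#'
#' @param fpkm Tibble `gene_id` plus sample columns.
#' @param bin_levels Wide bin-by-sample tibble ([bin_methylation()]).
#' @param pairs Tibble with columns `gene_id` and `region`.
#' @return Tibble: `gene_id`, `region`, `r`, `n`, `p_value`, `significant`.
#' @export
correlate_pairs <- function(fpkm, bin_levels, pairs) {
  esamp <- setdiff(names(fpkm), "gene_id")
  bsamp <- setdiff(names(bin_levels),
                   c("region", "chrom", "start", "end", "n_sites"))
  if (!setequal(esamp, bsamp)) {
    off <- c(setdiff(esamp, bsamp), setdiff(bsamp, esamp))
    abort(paste0("sample sets differ between expression and methylation: ",
                 paste(off, collapse = ", ")))
  }
  if (length(esamp) < 3) {
    abort("expression and bin matrices share fewer than 3 sample columns")
  }
  samp <- sort(esamp)
  gi <- match(pairs$gene_id, fpkm$gene_id)
  bi <- match(pairs$region, bin_levels$region)
  if (anyNA(gi)) abort(paste0("gene not in expression table: ",
                              pairs$gene_id[which(is.na(gi))[1]]))
  if (anyNA(bi)) abort(paste0("bin not in level table: ",
                              pairs$region[which(is.na(bi))[1]]))
  em <- as.matrix(fpkm[samp])
  bm <- as.matrix(bin_levels[samp])
  res <- purrr::map2(gi, bi, function(g, b) {
    x <- em[g, ]
    y <- bm[b, ]
    if (sd(x) == 0 || sd(y) == 0) return(NULL)
    r <- pearson_r(x, y)
    tibble::tibble(r = r, n = length(x),
                   p_value = pearson_pvalue(r, length(x)))
  })
  skipped <- purrr::map_lgl(res, is.null)
  if (any(skipped)) {
    inform(paste0("skipped ", sum(skipped),
                  " constant expression/methylation pair(s)"))
  }
  out <- dplyr::bind_cols(pairs[!skipped, c("gene_id", "region")],
                          dplyr::bind_rows(res[!skipped]))
  out$significant <- abs(out$r) > 0.5 & out$p_value < 0.05
  out
}
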