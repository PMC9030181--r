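#' Read a per-CpG methylation call table
#'
#' The canonical dialect is a 6-column TSV with columns `chrom`, `pos`
#' (1-based), `strand`, `context` (`CpG`/`CHG`/`CHH`), `methylated_reads`,
#' `total_reads`, optionally preceded by `#` comment lines. `dialect =
#' "cgmap"` accepts the 8-column CGmap layout written by bisulfite callers
#' (chrom, nucleotide, pos, context, dinucleotide, level, methylated, total)
#' and maps it onto the same fields: strand is `+` for a C record and `-` for
#' a G record, and context `CG` becomes `CpG`.
#'
#' Positions are converted to 0-based internally; records are returned sorted
#' by (chrom, pos).
#'
#' @param path Path to the call table.
#' @param sample_id Sample label attached to every record.
#' @param dialect `"tsv"` (canonical) or `"cgmap"`.
#' @return A tibble with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `meth_reads`, `total_reads`, `level`, `sample_id`.
#' @export
read_cpg_table <- function(path, sample_id, dialect = c("tsv", "cgmap")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  want <- if (dialect == "tsv") 6L else 8L
  nf <- vapply(fields, length, 1L)
  if (any(nf != want)) {
    i <- which(nf != want)[1]
    abort(paste0("malformed row at line ", line_no[i], " of ", path,
                 ": expected ", want, " fields, found ", nf[i]))
  }
  col <- function(j) vapply(fields, `[`, "", j)
  if (dialect == "tsv") {
    x <- tibble::tibble(
      chrom = col(1), pos = as.integer(col(2)) - 1L, strand = col(3),
      context = col(4),
      meth_reads = as.integer(col(5)), total_reads = as.integer(col(6))
    )
  } else {
    ctx <- col(4)
    ctx[ctx == "CG"] <- "CpG"
    x <- tibble::tibble(
      chrom = col(1),
      pos = as.integer(col(3)) - 1L,
      strand = ifelse(col(2) == "C", "+", "-"),
      context = ctx,
      meth_reads = as.integer(col(7)), total_reads = as.integer(col(8))
    )
  }
  bad <- which(is.na(x$pos) | is.na(x$meth_reads) | is.na(x$total_reads))
  if (length(bad) > 0) {
    abort(paste0("malformed row at line ", line_no[bad[1]], " of ", path,
                 ": non-numeric field"))
  }
  if (any(x$total_reads <= 0)) {
    i <- which(x$total_reads <= 0)[1]
    abort(paste0("invalid call at line ", line_no[i],
                 ": total_reads must be positive"))
  }
  if (any(x$meth_reads > x$total_reads | x$meth_reads < 0)) {
    i <- which(x$meth_reads > x$total_reads | x$meth_reads < 0)[1]
    abort(paste0("invalid call at line ", line_no[i],
                 ": methylated_reads must be in [0, total_reads]"))
  }
  x$level <- x$meth_reads / x$total_reads
  x$sample_id <- sample_id
  dplyr::arrange(x, .data$chrom, .data$pos)
}

#' Write a call table in the canonical 6-column dialect
#'
#' Inverse of [read_cpg_table()]: re-reading the written file reproduces the
#' records (positions re-rendered 1-based on disk).
#'
#' @param calls Tibble as returned by [read_cpg_table()] (one sample).
#' @param path Output path.
#' @export
write_cpg_table <- function(calls, path) {
  out <- tibble::tibble(
    chrom = calls$chrom, pos = calls$pos + 1L, strand = calls$strand,
    context = calls$context, methylated_reads = calls$meth_reads,
    total_reads = calls$total_reads
  )
  writeLines(paste("# CpG call table:",
                   "chrom pos(1-based) strand context meth_reads total_reads"),
             path)
  readr::write_tsv(out, path, append = TRUE, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Two-column TSV `sample_id`, `group`. Groups are free labels; the five-group
#' aging-intervention design uses young, old, DR, RALL and RDRL with three
#' samples each.
#'
#' @param path Path to the sheet.
#' @return Tibble with columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  x <- read_tsv_commented(path, col_types = "cc")
  names(x)[1:2] <- c("sample_id", "group")
  if (anyDuplicated(x$sample_id)) {
    abort("duplicate sample_id in sample sheet")
  }
  x
}

#' Read a gene-by-sample FPKM expression table
#'
#' @param path TSV with a `gene_id` column plus one numeric column per sample.
#' @param sample_sheet Optional sample sheet; every sample column must appear
#'   in it.
#' @return Tibble `gene_id` plus sample columns; all values non-negative.
#' @export
read_expression_table <- function(path, sample_sheet = NULL) {
  x <- read_tsv_commented(path)
  names(x)[1] <- "gene_id"
  if (anyDuplicated(x$gene_id)) {
    dup <- x$gene_id[duplicated(x$gene_id)][1]
    abort(paste0("duplicate gene_id in expression table: ", dup))
  }
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) abort("non-numeric expression column")
  if (any(vals < 0)) abort("negative FPKM value in expression table")
  if (!is.null(sample_sheet)) {
    extra <- setdiff(names(x)[-1], sample_sheet$sample_id)
    if (length(extra) > 0) {
      abort(paste0("expression sample(s) absent from sample sheet: ",
                   paste(extra, collapse = ", ")))
    }
  }
  x
}

#' @rdname read_expression_table
#' @param fpkm Tibble as returned by `read_expression_table()`.
#' @export
write_expression_table <- function(fpkm, path) {
  write_tsv_commented(fpkm, path, comments = "FPKM expression table")
}

#' Read gene models from BED6 or a knownGene-like TSV
#'
#' BED6 is consumed natively (0-based half-open). A knownGene-like table is
#' recognised by a header containing `txStart`/`txEnd` (UCSC also stores
#' 0-based starts, so both dialects normalise to the same internal
#' coordinates). Strand is required: promoters cannot be placed without it.
#'
#' @param path Path to the gene file.
#' @param collapse_by_name If `TRUE`, rows sharing a gene_id are collapsed to
#'   the union of their spans (per chromosome/strand); default keeps one
#'   interval per input row.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` (0-based half-open).
#' @export
read_gene_models <- function(path, collapse_by_name = FALSE) {
  first <- readLines(path, n = 1L)
  known <- grepl("txStart", first)
  if (known) {
    x <- read_tsv_commented(path)
    genes <- tibble::tibble(
      gene_id = as.character(x[[grep("^(name|gene)", names(x))[1]]]),
      chrom = as.character(x$chrom), strand = as.character(x$strand),
      tx_start = as.integer(x$txStart), tx_end = as.integer(x$txEnd)
    )
  } else {
    x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
    if (ncol(x) < 6) abort("BED input needs 6 columns (strand required)")
    genes <- tibble::tibble(
      gene_id = as.character(x[[4]]), chrom = as.character(x[[1]]),
      strand = as.character(x[[6]]),
      tx_start = as.integer(x[[2]]), tx_end = as.integer(x[[3]])
    )
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (any(genes$tx_start >= genes$tx_end)) {
    abort("gene with tx_start >= tx_end")
  }
  if (collapse_by_name) {
    genes <- genes |>
      dplyr::summarise(tx_start = min(.data$tx_start),
                       tx_end = max(.data$tx_end),
                       .by = c("gene_id", "chrom", "strand"))
  }
  genes
}

#' Read gene-to-GO annotations
#'
#' Accepts either a two-column TSV (`gene_id`, `term_id`) or GAF 2.x, from
#' which only the DB object symbol (column 3) and GO id (column 5) are
#' consumed.
#'
#' @param path Annotation file.
#' @return Tibble with columns `gene_id`, `term_id`, one row per distinct
#'   direct annotation.
#' @export
read_gene2go <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & !startsWith(lines, "#") &
                   nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (all(nf >= 15L)) {           # GAF
    out <- tibble::tibble(
      gene_id = vapply(fields, `[`, "", 3L),
      term_id = vapply(fields, `[`, "", 5L)
    )
  } else if (all(nf == 2L)) {
    out <- tibble::tibble(
      gene_id = vapply(fields, `[`, "", 1L),
      term_id = vapply(fields, `[`, "", 2L)
    )
  } else {
    abort("annotation file is neither 2-column TSV nor GAF")
  }
  dplyr::distinct(out)
}
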