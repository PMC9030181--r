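#' Render and parse genomic region strings
#'
#' Intervals are stored 0-based half-open internally; region strings shown to
#' users are 1-based inclusive, e.g. an internal `[135502251, 135502293)` on
#' chr9 renders as `"chr9:135502252-135502293"`.
#'
#' @param chrom Chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @return `region_string()`: a character vector. `parse_region()`: a tibble
#'   with columns `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' region_string("chr1", 99L, 200L)
#' parse_region("chr1:100-200")
#' @export
region_string <- function(chrom, start, end) {
  stopifnot(all(start < end))
  paste0(chrom, ":", format(start + 1L, scientific = FALSE, trim = TRUE),
         "-", format(end, scientific = FALSE, trim = TRUE))
}

#' @rdname region_string
#' @param region Character vector of region strings (`chrom:first-last`,
#'   1-based inclusive; an en-dash is accepted in place of `-`).
#' @export
parse_region <- function(region) {
  region <- gsub("–", "-", region)
  m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    abort(paste0("malformed region string: ", region[bad][1]))
  }
  tibble::tibble(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)) - 1L,
    end   = as.integer(vapply(m, `[`, "", 4L))
  )
}

# Write a tibble as TSV preceded by '#'-prefixed header lines.
write_tsv_commented <- function(x, path, comments = character()) {
  writeLines(if (length(comments)) paste0("# ", comments) else character(),
             path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

# Read a TSV, skipping '#'-prefixed header lines.
read_tsv_commented <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, ...)
}

# Shared argument checks -------------------------------------------------

check_groups <- function(sample_sheet, groups) {
  missing <- setdiff(groups, unique(sample_sheet$group))
  if (length(missing) > 0) {
    abort(paste0("group(s) not in sample sheet: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

samples_of <- function(sample_sheet, group) {
  sample_sheet$sample_id[sample_sheet$group == group]
}

# Columns of a wide feature-by-sample tibble that are sample levels.
sample_cols <- function(x, sample_sheet) {
  intersect(names(x), sample_sheet$sample_id)
}
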