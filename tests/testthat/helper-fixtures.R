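# Small fixture builders shared across test files.

# Write lines to a temp file, return path.
tmp_file <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

cpg_lines <- function(rows) {
  vapply(rows, function(r) paste(r, collapse = "\t"), "")
}

# A two-group sheet: samples a_1..a_n, b_1..b_n.
two_group_sheet <- function(n = 3, groups = c("a", "b")) {
  tibble::tibble(
    sample_id = paste0(rep(groups, each = n), "_", seq_len(n)),
    group = rep(groups, each = n)
  )
}

# Wide bin-level tibble from a matrix of per-sample levels.
levels_from_matrix <- function(m, sheet, chrom = "chr1") {
  start <- seq(0L, by = 2000L, length.out = nrow(m))
  out <- tibble::tibble(
    region = region_string(chrom, start, start + 100L),
    chrom = chrom, start = start, end = start + 100L,
    n_sites = 1L
  )
  colnames(m) <- sheet$sample_id
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

# Brute-force binning oracle: enumerate all cut-point subsets and keep the
# partitions where every intra-bin gap <= max_gap and every inter-bin
# boundary gap > max_gap; there is exactly one such partition.
brute_force_bins <- function(pos, max_gap) {
  pos <- sort(pos)
  n <- length(pos)
  if (n == 1) return(list(pos))
  valid <- list()
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
    bounds <- c(0, cuts, n)
    ok <- TRUE
    for (b in seq_len(length(bounds) - 1)) {
      seg <- pos[(bounds[b] + 1):bounds[b + 1]]
      if (length(seg) > 1 && any(diff(seg) > max_gap)) ok <- FALSE
    }
    if (ok && length(cuts) > 0) {
      if (any(pos[cuts + 1] - pos[cuts] <= max_gap)) ok <- FALSE
    }
    if (ok) {
      valid[[length(valid) + 1]] <-
        lapply(seq_len(length(bounds) - 1),
               function(b) pos[(bounds[b] + 1):bounds[b + 1]])
    }
  }
  stopifnot(length(valid) == 1)
  valid[[1]]
}
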