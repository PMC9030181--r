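#' Read a Gene Ontology OBO file
#'
#' Parses OBO 1.2 `[Term]` stanzas, consuming only `id`, `name`, `namespace`,
#' `is_a` and `is_obsolete`. Obsolete terms are dropped. For every term the
#' minimum depth -- the shortest `is_a` path from its namespace root (a term
#' with no parents) -- is computed by breadth-first traversal; roots have
#' depth 0. The "top three locus levels" filter of the enrichment step removes
#' terms with `min_depth` < 3.
#'
#' @param path Path to an OBO file.
#' @return A tibble with columns `term_id`, `name`, `namespace`, `parents`
#'   (list column of `is_a` parent ids) and `min_depth`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) abort("no [Term] stanzas in OBO file")
  stanza_ends <- c(term_starts[-1] - 1L, length(lines))
  other_stanzas <- which(startsWith(lines, "[") & lines != "[Term]")

  parse_stanza <- function(from, to) {
    block <- lines[from:to]
    cut <- other_stanzas[other_stanzas > from & other_stanzas <= to]
    if (length(cut) > 0) block <- lines[from:(min(cut) - 1L)]
    grab <- function(key) {
      v <- block[startsWith(block, paste0(key, ": "))]
      sub(paste0("^", key, ": "), "", v)
    }
    if (any(grepl("^is_obsolete: true", block))) return(NULL)
    id <- grab("id")
    if (length(id) == 0) return(NULL)
    parents <- sub(" !.*$", "", grab("is_a"))
    list(term_id = id[1],
         name = (grab("name") %||% NA_character_)[1] %||% NA_character_,
         namespace = (grab("namespace"))[1] %||% NA_character_,
         parents = parents)
  }

  terms <- purrr::map2(term_starts, stanza_ends, parse_stanza)
  terms <- purrr::compact(terms)
  onto <- tibble::tibble(
    term_id = purrr::map_chr(terms, "term_id"),
    name = purrr::map_chr(terms, ~ .x$name %||% NA_character_),
    namespace = purrr::map_chr(terms, ~ .x$namespace %||% NA_character_),
    parents = purrr::map(terms, ~ intersect(.x$parents,
                                            purrr::map_chr(terms, "term_id")))
  )
  onto$min_depth <- compute_min_depth(onto$term_id, onto$parents)
  onto
}

# BFS shortest is_a path from roots; errors on cycles (nodes never reached
# because every path to them loops).
compute_min_depth <- function(ids, parents) {
  idx <- setNames(seq_along(ids), ids)
  children <- vector("list", length(ids))
  n_parents <- integer(length(ids))
  for (i in seq_along(ids)) {
    p <- idx[parents[[i]]]
    n_parents[i] <- length(p)
    for (j in p) children[[j]] <- c(children[[j]], i)
  }
  depth <- rep(NA_integer_, length(ids))
  frontier <- which(n_parents == 0L)
  depth[frontier] <- 0L
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier]))
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(depth)) {
    cyc <- ids[is.na(depth)]
    abort(paste0("is_a cycle involving term(s): ",
                 paste(head(cyc, 5), collapse = ", ")))
  }
  depth
}

#' Write an ontology as OBO 1.2
#'
#' Inverse of [read_obo()] for the fields the package consumes; used by the
#' synthetic-study generator.
#'
#' @param ontology Tibble as returned by [read_obo()].
#' @param path Output path.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ontology))) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", ontology$term_id[i]), con)
    writeLines(paste0("name: ", ontology$name[i]), con)
    writeLines(paste0("namespace: ", ontology$namespace[i]), con)
    for (p in ontology$parents[[i]]) {
      writeLines(paste0("is_a: ", p), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
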