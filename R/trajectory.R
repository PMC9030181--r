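#' Fit the genome-wide aging-trajectory regression
#'
#' Each bin contributes one point: x is the old - young group methylation
#' difference (the normal-aging baseline) and y is either treated - old or
#' treated - young. If the treated methylome is a convex mixture
#' treated = lambda * old + (1 - lambda) * young, then y = (lambda - 1) x on
#' the treated - old axis and y = lambda x on the treated - young axis, so
#' the OLS slope identifies the mixing coefficient: lambda = 1 + slope and
#' lambda = slope respectively. The fit is ordinary least squares with an
#' unconstrained intercept; the Pearson correlation is computed on the same
#' (x, y) pairs, and bins are counted per quadrant (points on an axis are
#' excluded).
#'
#' @param group_levels Tibble with one row per bin and one methylation column
#'   per group (see [group_levels()]); a `region` column, if present, labels
#'   the scatter rows.
#' @param young,old,treated Column names of the three groups.
#' @param response `"treated_minus_old"` (default) or `"treated_minus_young"`.
#' @return A `trajectory_fit` object: slope, intercept, `pcc`, `lambda_hat`,
#'   `quadrant_counts` (named Q1-Q4), `n`, and the per-bin scatter `data`
#'   (tibble `region`, `x`, `y`). Has [tidy()], [glance()], `autoplot()` and
#'   print methods.
#' @export
fit_trajectory <- function(group_levels, young = "young", old = "old",
                           treated = "DR",
                           response = c("treated_minus_old",
                                        "treated_minus_young")) {
  response <- match.arg(response)
  for (g in c(young, old, treated)) {
    if (!g %in% names(group_levels)) {
      abort(paste0("group column not found: ", g))
    }
  }
  if (nrow(group_levels) < 3) abort("need at least 3 bins")
  x <- group_levels[[old]] - group_levels[[young]]
  y <- if (response == "treated_minus_old") {
    group_levels[[treated]] - group_levels[[old]]
  } else {
    group_levels[[treated]] - group_levels[[young]]
  }
  if (var(x) == 0) abort("degenerate baseline: old - young differences have zero variance")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  pcc <- if (var(y) == 0) 0 else cor(x, y)
  lambda_hat <- if (response == "treated_minus_old") 1 + slope else slope
  quadrant <- dplyr::case_when(
    x > 0 & y > 0 ~ "Q1", x < 0 & y > 0 ~ "Q2",
    x < 0 & y < 0 ~ "Q3", x > 0 & y < 0 ~ "Q4",
    .default = NA_character_
  )
  counts <- table(factor(quadrant, levels = paste0("Q", 1:4)))
  structure(list(
    x_def = paste0(old, " - ", young),
    y_def = if (response == "treated_minus_old") {
      paste0(treated, " - ", old)
    } else {
      paste0(treated, " - ", young)
    },
    response = response, treated = treated,
    slope = slope, intercept = intercept, pcc = pcc,
    lambda_hat = lambda_hat,
    quadrant_counts = setNames(as.integer(counts), names(counts)),
    n = length(x),
    data = tibble::tibble(
      region = group_levels[["region"]] %||% as.character(seq_along(x)),
      x = x, y = y, quadrant = quadrant
    )
  ), class = "trajectory_fit")
}

#' Quadrant summary of a treated-minus-old trajectory fit
#'
#' On the treated - old axis, bins in the second quadrant lost methylation
#' with normal aging (x < 0) but sit higher in the treated group than in old
#' (y > 0), and fourth-quadrant bins mirror that for hypermethylating bins;
#' together Q2 + Q4 are the bins where the treatment retains a younger
#' methylation state. `offdiagonal_dominant` reports whether
#' Q2 + Q4 > Q1 + Q3.
#'
#' @param fit A `trajectory_fit` with `response = "treated_minus_old"`.
#' @return Tibble with `quadrant`, `n`, `interpretation`, plus attribute-free
#'   columns `offdiagonal_dominant` repeated for convenience.
#' @export
quadrant_summary <- function(fit) {
  stopifnot(inherits(fit, "trajectory_fit"))
  if (fit$response != "treated_minus_old") {
    abort("quadrant_summary interprets the treated_minus_old response")
  }
  q <- fit$quadrant_counts
  dominant <- (q[["Q2"]] + q[["Q4"]]) > (q[["Q1"]] + q[["Q3"]])
  tibble::tibble(
    quadrant = names(q),
    n = unname(q),
    interpretation = c(
      "hyper in aging, further gain under treatment",
      "hypo in aging, retained higher (younger) level",
      "hypo in aging, further loss under treatment",
      "hyper in aging, retained lower (younger) level"
    ),
    offdiagonal_dominant = dominant
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("aging-trajectory fit (", x$n, " bins)\n", sep = "")
  cat("  y =", x$y_def, " on x =", x$x_def, "\n")
  cat(sprintf("  slope %.4f  intercept %.4f  PCC %.4f\n",
              x$slope, x$intercept, x$pcc))
  cat(sprintf("  implied mixing coefficient lambda = %.4f (%s = %.3f*old + %.3f*young)\n",
              x$lambda_hat, x$treated, x$lambda_hat, 1 - x$lambda_hat))
  cat("  quadrants:", paste(names(x$quadrant_counts),
                            x$quadrant_counts, collapse = "  "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return One row per fitted quantity (`term`, `estimate`).
#' @method tidy trajectory_fit
#' @export
tidy.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept", "pcc", "lambda_hat"),
    estimate = c(x$slope, x$intercept, x$pcc, x$lambda_hat)
  )
}

#' One-row summary of a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @method glance trajectory_fit
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response, slope = x$slope, intercept = x$intercept,
    pcc = x$pcc, lambda_hat = x$lambda_hat, n = x$n,
    q1 = x$quadrant_counts[["Q1"]], q2 = x$quadrant_counts[["Q2"]],
    q3 = x$quadrant_counts[["Q3"]], q4 = x$quadrant_counts[["Q4"]]
  )
}
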