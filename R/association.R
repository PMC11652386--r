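#' Haldane-Anscombe continuity correction
#'
#' Adds 0.5 to all four cells of a 2x2 table that contains at least one
#' zero, so that the odds ratio and the Woolf standard error stay finite.
#' A table with no zero cell is returned unchanged with a warning; an
#' all-zero table is a domain error.
#'
#' @param table A `model_table` (see [build_model_table()]).
#' @return The corrected `model_table`, with attribute `corrected = TRUE`
#'   when the correction was applied.
#' @examples
#' t0 <- structure(list(model = "additive2", snp_id = "rs0",
#'                      a = 5, b = 0, c = 3, d = 7,
#'                      exposed_label = "AA", baseline_label = "GG"),
#'                 class = "model_table")
#' haldane_anscombe(t0)
#' @export
haldane_anscombe <- function(table) {
  stopifnot(inherits(table, "model_table"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (all(cells == 0)) {
    stop("all four cells are zero; no association is estimable",
         call. = FALSE)
  }
  if (!any(cells == 0)) {
    warning("no zero cell; Haldane-Anscombe correction not applied",
            call. = FALSE)
    attr(table, "corrected") <- FALSE
    return(table)
  }
  table$a <- table$a + 0.5
  table$b <- table$b + 0.5
  table$c <- table$c + 0.5
  table$d <- table$d + 0.5
  attr(table, "corrected") <- TRUE
  table
}

#' Odds ratio with Woolf confidence interval and Wald z-test
#'
#' For a 2x2 table with cells `a` (case exposed), `b` (case baseline),
#' `c` (control exposed), `d` (control baseline):
#' `OR = ad / bc`, `SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)` (Woolf),
#' `CI = exp(log OR -/+ z * SE)`, and a two-sided p-value from the Wald
#' statistic `z = log OR / SE` referred to the standard normal. Tables
#' with a zero cell go through [haldane_anscombe()] first (with a
#' warning); the result is marked `corrected`. p-values are floored at
#' 1e-300.
#'
#' @param table A `model_table` from [build_model_table()].
#' @param conf.level Confidence level of the interval, in (0, 1).
#' @return An object of class `or_test` with components `estimate`,
#'   `conf.int`, `log_or`, `se_log_or`, `z`, `p.value`, `corrected`,
#'   `model`, `table`.
#' @examples
#' pairs <- read_counts_table(scz_example_counts())
#' odds_ratio_test(build_model_table(pairs[[2]], "additive2"))
#' @export
odds_ratio_test <- function(table, conf.level = 0.95) {
  stopifnot(inherits(table, "model_table"))
  if (!is.numeric(conf.level) || length(conf.level) != 1L ||
      conf.level <= 0 || conf.level >= 1) {
    stop("'conf.level' must be a single number in (0, 1)", call. = FALSE)
  }
  corrected <- FALSE
  cells <- c(table$a, table$b, table$c, table$d)
  if (all(cells == 0)) {
    stop("all four cells are zero; no association is estimable",
         call. = FALSE)
  }
  if (any(cells == 0)) {
    warning("zero cell in ", table$snp_id, " ", table$model,
            " table; applying Haldane-Anscombe correction", call. = FALSE)
    table <- suppressWarnings(haldane_anscombe(table))
    corrected <- TRUE
  }
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  or <- (a * d) / (b * c)
  log_or <- log(or)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log_or / se
  crit <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- exp(log_or + c(-1, 1) * crit * se)
  p <- max(2 * stats::pnorm(-abs(z)), 1e-300)
  structure(
    list(model = table$model, snp_id = table$snp_id,
         estimate = or, conf.int = ci, conf.level = conf.level,
         log_or = log_or, se_log_or = se, z = z, p.value = p,
         corrected = corrected, table = table),
    class = "or_test"
  )
}

#' @export
print.or_test <- function(x, digits = 4, ...) {
  cat(sprintf("<or_test> %s, %s (%s vs. %s)%s\n", x$snp_id, x$model,
              x$table$exposed_label, x$table$baseline_label,
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  cat(sprintf("  OR = %.*g, %d%% CI %.*g-%.*g, z = %.*g, p = %.4g\n",
              digits, x$estimate, round(100 * x$conf.level),
              digits, x$conf.int[1L], digits, x$conf.int[2L],
              digits, x$z, x$p.value))
  invisible(x)
}
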