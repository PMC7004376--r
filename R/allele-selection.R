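# Control-allele selection from case/control/healthy frequency tables,
# plus odds-ratio reporting support.

#' Read an allele frequency table
#'
#' Expected CSV columns: `allele`, `case_freq`, `study_control_freq`,
#' `case_n`, `control_n`. Any additional numeric column is treated as a
#' healthy-population frequency (column name = population name), as
#' exported from population allele-frequency databases.
#'
#' @param path CSV file path.
#' @return Data frame with an attribute `healthy_cols` naming the
#'   population frequency columns.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_frequency_table(tab)
}

validate_frequency_table <- function(tab) {
  required <- c("allele", "case_freq", "study_control_freq",
                "case_n", "control_n")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("frequency table lacks columns: ", paste(missing, collapse = ", "))
  }
  healthy <- setdiff(names(tab), required)
  healthy <- healthy[vapply(tab[healthy], is.numeric, logical(1L))]
  for (col in c("case_freq", "study_control_freq", healthy)) {
    v <- tab[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("frequencies in column '", col, "' must lie in [0, 1]")
    }
  }
  if (any(tab$case_n < 0) || any(tab$control_n < 0)) {
    stop("cohort counts must be non-negative")
  }
  attr(tab, "healthy_cols") <- healthy
  tab
}

#' Screen candidate alleles by study-control frequency
#'
#' Keeps alleles whose study-control frequency exceeds a threshold
#' (strictly greater; default over 3%), the screen applied before control
#' selection so that only alleles common enough to be informative are
#' considered.
#'
#' @param tab Frequency table (see [read_frequency_table()]).
#' @param min_control_freq Threshold proportion, default `0.03`.
#' @return Character vector of allele names, input order preserved.
#' @export
screen_candidates <- function(tab, min_control_freq = 0.03) {
  tab <- validate_frequency_table(tab)
  stopifnot(min_control_freq >= 0, min_control_freq <= 1)
  tab$allele[tab$study_control_freq > min_control_freq]
}

#' Select non-associated control alleles
#'
#' An allele passes as a control when its study-control frequency or any
#' healthy-population frequency is similar to or greater than its case
#' frequency, i.e. the allele shows no enrichment in cases. "Similar to"
#' is a relative tolerance on the case frequency: the best available
#' control-side frequency must reach `case_freq * (1 - tolerance)`.
#' Only alleles passing the [screen_candidates()] frequency screen are
#' considered, so the result is always a subset of that screen.
#'
#' @param tab Frequency table.
#' @param tolerance Relative margin for "similar to"; default `0.1`.
#' @param min_control_freq Passed to [screen_candidates()].
#' @param details If `TRUE`, return a data frame with the deciding
#'   frequency and rule branch per selected allele.
#' @return Character vector of selected control alleles (or a detail
#'   data frame).
#' @export
select_controls <- function(tab, tolerance = 0.1, min_control_freq = 0.03,
                            details = FALSE) {
  tab <- validate_frequency_table(tab)
  stopifnot(tolerance >= 0)
  healthy <- attr(tab, "healthy_cols")
  keep <- tab$allele %in% screen_candidates(tab, min_control_freq)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    return(if (details) empty_control_details() else character())
  }
  best_healthy <- if (length(healthy) > 0L) {
    suppressWarnings(apply(as.matrix(tab[healthy]), 1L, max, na.rm = TRUE))
  } else {
    rep(-Inf, nrow(tab))
  }
  best_healthy[!is.finite(best_healthy)] <- -Inf
  deciding <- pmax(tab$study_control_freq, best_healthy)
  branch <- ifelse(best_healthy > tab$study_control_freq,
                   "healthy_population", "study_control")
  sel <- deciding >= tab$case_freq * (1 - tolerance)
  if (!details) {
    return(tab$allele[sel])
  }
  data.frame(allele = tab$allele[sel],
             case_freq = tab$case_freq[sel],
             deciding_freq = deciding[sel],
             rule_branch = branch[sel],
             stringsAsFactors = FALSE)
}

empty_control_details <- function() {
  data.frame(allele = character(), case_freq = numeric(),
             deciding_freq = numeric(), rule_branch = character(),
             stringsAsFactors = FALSE)
}

#' Odds ratio with 95% confidence interval from a 2x2 table
#'
#' Cells follow the carrier layout `a` = carrier cases, `b` = carrier
#' controls, `c` = non-carrier cases, `d` = non-carrier controls. When any
#' cell is zero the Haldane-Anscombe correction (add 0.5 to every cell) is
#' applied before computing `OR = (a d)/(b c)`; the 95% CI uses the
#' log-OR normal approximation with `SE = sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return List with elements `or`, `ci95` (length-2 numeric) and
#'   `corrected` (logical).
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("contingency cells must be non-negative")
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0)) {
    stop("odds ratio undefined: two zero cells in the same margin")
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  list(or = unname(or), ci95 = unname(ci), corrected = corrected)
}
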