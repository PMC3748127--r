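#' Assemble a cohort table
#'
#' Long-format container of per-animal results: one value per animal and
#' variable.
#'
#' @param animal animal identifiers.
#' @param group group labels (e.g. "WT", "Tg").
#' @param variable variable names.
#' @param value numeric values.
#' @param units optional units per row.
#' @return a `cohort_table` data.frame.
#' @export
cohort_table <- function(animal, group, variable, value, units = NA_character_) {
  df <- data.frame(animal = animal, group = group, variable = variable,
                   value = value, units = units, stringsAsFactors = FALSE)
  key <- paste(df$animal, df$variable)
  if (anyDuplicated(key)) stopf("duplicate animal-variable entries")
  class(df) <- c("cohort_table", class(df))
  df
}

#' Group mean and SEM for one variable
#'
#' @param table a [cohort_table()].
#' @param variable variable name.
#' @return data.frame: group, n, mean, sem (sd/sqrt(n)).
#' @export
group_summary <- function(table, variable) {
  d <- table[table$variable == variable, ]
  if (!nrow(d)) stopf("variable '%s' not found", variable)
  gs <- split(d$value, d$group)
  if (any(vapply(gs, length, 0L) < 2L)) stopf("need >= 2 animals per group")
  data.frame(group = names(gs),
             n = vapply(gs, length, 0L),
             mean = vapply(gs, mean, 0),
             sem = vapply(gs, function(x) stats::sd(x) / sqrt(length(x)), 0),
             row.names = NULL)
}

#' Percent difference between group means
#'
#' `100 * (b - a) / a` with `a` the reference (e.g. WT) mean; also returned
#' rounded to the nearest integer for reporting.
#'
#' @param mean_ref reference group mean (nonzero).
#' @param mean_other comparison group mean.
#' @return list: `percent`, `rounded`.
#' @export
percent_difference <- function(mean_ref, mean_other) {
  if (mean_ref == 0) stopf("reference mean is zero")
  p <- 100 * (mean_other - mean_ref) / mean_ref
  list(percent = p, rounded = round(p))
}

#' Pearson correlation
#'
#' @param x,y numeric vectors (n >= 3, finite, nonzero variance).
#' @return list: `r`, `r_squared`, `sign`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stopf("need >= 3 paired values")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("zero variance")
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2, sign = sign(r))
}

#' Two-sided unpaired Student t-test (equal variance)
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list: `t`, `p`, `df`.
#' @export
unpaired_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stopf("need >= 2 values per group")
  if (stats::sd(c(a, b)) == 0) {
    # identical constant groups: no evidence of difference
    return(list(t = 0, p = 1, df = length(a) + length(b) - 2L))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}
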