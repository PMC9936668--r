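#' Sum-of-squares variance partition across stimulation factors
#'
#' Sequential (Type I) sum-of-squares decomposition of a response over
#' categorical stimulation factors and their interactions, on the balanced
#' factorial design (where Type I, II and III coincide).  Each term's share
#' is its SS divided by the corrected total SS (deviations from the grand
#' mean); the residual share is reported as unaccounted variance, so the
#' percentages sum to 100.
#'
#' @param table data.frame with one row per trial.
#' @param response name of the response column (e.g. `"hr_norm"`).
#' @param terms character vector of model terms over the columns
#'   `amplitude`, `frequency`, `mpr`, `animal` (interactions as
#'   `"amplitude:mpr"` etc.).  Terms whose factor has a single level are
#'   dropped with a warning.
#' @return data.frame with `term`, `ss`, `pct` (the last row is the
#'   residual, labeled `"unaccounted"`).
#' @export
variance_partition <- function(table, response = "hr_norm",
                               terms = c("amplitude", "frequency", "mpr",
                                         "amplitude:frequency",
                                         "amplitude:mpr", "frequency:mpr",
                                         "animal")) {
  stopifnot(response %in% names(table))
  dat <- table[is.finite(table[[response]]), , drop = FALSE]
  base_vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in base_vars) {
    if (!v %in% names(dat)) stop("missing factor column: ", v)
    dat[[v]] <- factor(dat[[v]])
  }
  single <- base_vars[vapply(dat[base_vars], nlevels, integer(1)) < 2]
  if (length(single)) {
    warning("dropping single-level terms: ", paste(single, collapse = ", "))
    terms <- terms[!vapply(strsplit(terms, ":", fixed = TRUE),
                           function(p) any(p %in% single), logical(1))]
  }
  if (!length(terms)) stop("no usable terms")
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = "+")))
  fit <- stats::lm(fml, data = dat)
  av <- stats::anova(fit)
  ss <- av[["Sum Sq"]]
  labels <- rownames(av)
  total <- sum(ss)  # corrected total SS
  out <- data.frame(term = c(labels[-length(labels)], "unaccounted"),
                    ss = ss, pct = 100 * ss / total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit of a response against a pattern statistic
#'
#' Simple linear regression with the coefficient of determination and the
#' p-value of the slope's F test against the constant model.
#'
#' @param x,y finite numeric vectors (>= 3 points; `x` must vary).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                 lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p_value = unname(p))
}
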