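#' Odds ratio and two-sided Fisher exact test for a 2x2 table
#'
#' The odds ratio is the cross-product `(a*d)/(b*c)`; the p-value is the
#' exact two-sided Fisher probability (hypergeometric tail summation, as
#' implemented by [stats::fisher.test()]). Zero cells give an infinite or
#' zero OR and are flagged.
#'
#' @param a,b,c,d Cell counts: `a` exposed/immunogenic, `b`
#'   exposed/nonimmunogenic, `c` unexposed/immunogenic, `d`
#'   unexposed/nonimmunogenic. Alternatively pass a 2x2 matrix as `a`.
#' @return Tibble with `odds_ratio` (cross-product), `p_value`,
#'   `degenerate` (any zero cell).
#' @examples
#' fisher_or(10, 5, 5, 10)  # OR = 4
#' @export
fisher_or <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), 2, 2)
  }
  if (any(m < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (sum(m) == 0) stop("table total must be positive", call. = FALSE)
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  p <- stats::fisher.test(m)$p.value
  tibble::tibble(
    odds_ratio = or,
    p_value = p,
    degenerate = any(m == 0)
  )
}

#' Wilcoxon rank-sum / signed-rank test with direction
#'
#' Two-sided unpaired rank-sum or paired signed-rank test, reporting the
#' sign of the (paired) median difference as the effect direction. Exact
#' p-values at small n, normal approximation with tie correction above
#' n = 50.
#'
#' @param x,y Numeric samples (equal length when `paired`).
#' @param paired Paired signed-rank instead of unpaired rank-sum.
#' @return Tibble with `p_value`, `direction` (-1, 0, 1), `statistic`.
#' @export
ranksum_test <- function(x, y, paired = FALSE) {
  diffs <- if (paired) x - y else NULL
  if (paired && all(diffs == 0)) {
    warning("all paired differences are zero")
    return(tibble::tibble(p_value = 1, direction = 0, statistic = NA_real_))
  }
  exact <- length(x) <= 50 && length(y) <= 50
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact, correct = TRUE)
  )
  direction <- if (paired) {
    sign(stats::median(diffs))
  } else {
    sign(stats::median(x) - stats::median(y))
  }
  tibble::tibble(
    p_value = wt$p.value,
    direction = direction,
    statistic = unname(wt$statistic)
  )
}

#' Lowess curve of immunogenicity probability against a covariate
#'
#' Locally weighted regression of a binary immunogenicity indicator on a
#' covariate (typically the expression percentile rank), with the classic
#' lowess defaults (span 2/3, 3 robustness iterations).
#'
#' @param x Covariate values.
#' @param y Binary (0/1 or logical) response.
#' @param span Smoother span.
#' @param iter Robustness iterations.
#' @return Tibble with `x`, `fitted`, ordered by `x`.
#' @export
lowess_curve <- function(x, y, span = 2 / 3, iter = 3L) {
  if (length(unique(x)) < 2) stop("x must not be constant", call. = FALSE)
  if (length(x) < 30) stop("need at least 30 observations", call. = FALSE)
  fit <- stats::lowess(x, as.numeric(y), f = span, iter = iter)
  tibble::tibble(x = fit$x, fitted = fit$y)
}

#' Multivariate logistic model of immunogenicity
#'
#' Maximum-likelihood logistic regression of the immunogenicity indicator
#' on TCEM attribute groups (and optional hydrophobicity), with Wald
#' two-sided p-values. Complete or quasi-complete separation is detected
#' and aborts the fit with a diagnostic rather than returning divergent
#' coefficients.
#'
#' @param data Data frame holding the response and covariates.
#' @param formula Model formula, response must be binary.
#' @return Object of class `tcem_logistic` wrapping the [stats::glm()]
#'   fit; `tidy()` gives the coefficient table, `glance()` the model
#'   summary.
#' @export
fit_logistic <- function(data, formula) {
  fit <- stats::glm(formula, family = stats::binomial(), data = data)
  if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop("separation suspected: coefficient magnitude > 15 on the logit scale",
      call. = FALSE
    )
  }
  structure(list(fit = fit, formula = formula), class = "tcem_logistic")
}

#' @describeIn fit_logistic Coefficient estimates, standard errors and
#'   Wald two-sided p-values.
#' @param x A `tcem_logistic`.
#' @param ... Unused.
#' @method tidy tcem_logistic
#' @export
tidy.tcem_logistic <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p_value = s[, "Pr(>|z|)"]
  )
}

#' @describeIn fit_logistic One-row model summary.
#' @method glance tcem_logistic
#' @export
glance.tcem_logistic <- function(x, ...) {
  tibble::tibble(
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = x$fit$aic,
    n = stats::nobs(x$fit),
    converged = x$fit$converged
  )
}

#' @export
print.tcem_logistic <- function(x, ...) {
  cat("<tcem_logistic>\n")
  print(tidy.tcem_logistic(x))
  invisible(x)
}

#' Immunogenic fraction by number of low TCEM attributes
#'
#' Counts, per peptide, how many of the three repertoire-depleting
#' attributes its TCEM has (rare frequency, low cTEC expression, low
#' thymoproteasomal cleavage) and reports the immunogenic fraction per
#' stratum 0-3 plus a Cochran-Armitage-style trend test (score test of the
#' logistic slope on the attribute count).
#'
#' @param data Tibble with logical columns `low_freq`, `low_expr`,
#'   `low_cleav` and a `label` column
#'   (`immunogenic`/`nonimmunogenic`).
#' @return List with `strata` (tibble `n_low`, `n`, `n_immunogenic`,
#'   `fraction`) and `trend_p`.
#' @export
attribute_additivity <- function(data) {
  data <- dplyr::mutate(
    data,
    n_low = as.integer(.data$low_freq) + as.integer(.data$low_expr) +
      as.integer(.data$low_cleav),
    imm = .data$label == "immunogenic"
  )
  strata <- data |>
    dplyr::summarise(
      n = dplyr::n(),
      n_immunogenic = sum(.data$imm),
      fraction = mean(.data$imm),
      .by = "n_low"
    ) |>
    dplyr::arrange(.data$n_low)
  trend_p <- if (dplyr::n_distinct(data$n_low) > 1) {
    fit <- stats::glm(imm ~ n_low, family = stats::binomial(), data = data)
    summary(fit)$coefficients["n_low", "Pr(>|z|)"]
  } else {
    NA_real_
  }
  list(strata = strata, trend_p = trend_p)
}

#' Amino-acid enrichment and leave-one-out robustness
#'
#' For each standard amino acid, tests (Fisher exact) whether motifs
#' containing it are enriched among immunogenic vs nonimmunogenic records,
#' then re-runs a caller-supplied headline test on the dataset restricted
#' to motifs *not* containing that amino acid — showing whether any single
#' residue drives the associations.
#'
#' @param data Tibble with `motif` and `label` columns.
#' @param headline A function `function(data) -> p-value` re-run on each
#'   restricted dataset; defaults to the frequency rank-sum test when the
#'   data has a `count` column, else skipped (`NA`).
#' @return Tibble with one row per amino acid: `amino_acid`, `n_with`,
#'   `odds_ratio`, `p_enrichment`, `n_without`, `p_headline`.
#' @export
aa_enrichment_and_leave_one_out <- function(data, headline = NULL) {
  if (is.null(headline) && "count" %in% names(data)) {
    headline <- function(d) {
      ranksum_test(
        d$count[d$label == "immunogenic"],
        d$count[d$label == "nonimmunogenic"]
      )$p_value
    }
  }
  imm <- data$label == "immunogenic"
  purrr::map(AA_STANDARD, function(aa) {
    has <- stringr::str_detect(data$motif, stringr::fixed(aa))
    if (!any(has)) {
      return(tibble::tibble(
        amino_acid = aa, n_with = 0L, odds_ratio = NA_real_,
        p_enrichment = NA_real_, n_without = sum(!has), p_headline = NA_real_
      ))
    }
    enr <- fisher_or(
      sum(has & imm), sum(has & !imm),
      sum(!has & imm), sum(!has & !imm)
    )
    rest <- data[!has, , drop = FALSE]
    p_head <- if (!is.null(headline) && nrow(rest) > 5 &&
      dplyr::n_distinct(rest$label) == 2) {
      headline(rest)
    } else {
      NA_real_
    }
    tibble::tibble(
      amino_acid = aa, n_with = sum(has), odds_ratio = enr$odds_ratio,
      p_enrichment = enr$p_value, n_without = sum(!has), p_headline = p_head
    )
  }) |>
    dplyr::bind_rows()
}
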