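#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' Adaptive false-discovery-rate control in two linear step-up passes.
#' Stage 1 applies Benjamini-Hochberg at level `alpha' = alpha / (1 + alpha)`
#' and rejects `r1` hypotheses; if `r1 = 0` nothing is rejected, if `r1 = m`
#' everything is. Otherwise the number of true nulls is estimated as
#' `m0 = m - r1` and stage 2 applies Benjamini-Hochberg at level
#' `alpha' * m / m0`. Whenever stage 1 rejects anything, the procedure
#' rejects a superset of the plain BH rejections at the same level.
#'
#' q-values are defined operationally as the smallest level `alpha` at which
#' each p-value is rejected by the full two-stage procedure (computed by
#' bisection; the rejection set is monotone in `alpha`).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param alpha Target FDR level (default 0.05).
#' @return A list with `q` (q-values, same order as input) and `reject`
#'   (logical rejections at `alpha`). Empty input gives empty output.
#' @export
bky_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) {
    return(list(q = numeric(0), reject = logical(0)))
  }
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")

  reject_at <- function(p, a) {
    m <- length(p)
    a1 <- a / (1 + a)
    r1 <- bh_reject_count(p, a1)
    if (r1 == 0) return(rep(FALSE, m))
    if (r1 == m) return(rep(TRUE, m))
    m0 <- m - r1
    a2 <- a1 * m / m0
    bh_reject(p, a2)
  }

  q <- vapply(seq_along(pvalues), function(i) {
    lo <- 0
    hi <- 1
    if (!reject_at(pvalues, hi)[i]) return(1)
    for (iter in 1:60) {
      mid <- (lo + hi) / 2
      if (reject_at(pvalues, mid)[i]) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))

  list(q = q, reject = reject_at(pvalues, alpha))
}

# number of BH rejections of p at level a (linear step-up)
bh_reject_count <- function(p, a) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= (seq_len(m) / m) * a)
  if (length(ok) == 0) 0L else max(ok)
}

# logical BH rejection vector in the input order
bh_reject <- function(p, a) {
  k <- bh_reject_count(p, a)
  if (k == 0) return(rep(FALSE, length(p)))
  thr <- sort(p)[k]
  p <= thr
}

#' Per-day group comparison of CRP with FDR correction
#'
#' For each calendar day (relative to surgery) with at least two
#' observations in each group, compares the two groups' CRP values with
#' Welch's t-test, then adjusts the family of daily p-values with the
#' two-stage Benjamini-Krieger-Yekutieli procedure ([bky_fdr()]).
#'
#' @param cohort A [crp_cohort()].
#' @param grouping `"infection"` (infected vs not), `"approach"`
#'   (anterolateral code 1 vs posterior code 2; other approaches excluded),
#'   or `"indication"` (trauma vs non-trauma).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return A tibble with one row per tested day: `day`, `n0`, `n1`, `mean0`,
#'   `mean1`, `p`, `q`, `significant`. Days skipped for insufficient data
#'   are listed in the `skipped_days` attribute.
#' @export
per_day_comparison <- function(cohort, grouping = c("infection", "approach", "indication"),
                               alpha = 0.05) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(cohort, "crp_cohort"))
  pats <- cohort$patients
  grp <- switch(grouping,
    infection = stats::setNames(pats$infection, pats$patient_id),
    indication = stats::setNames(pats$indication_trauma, pats$patient_id),
    approach = {
      keep <- pats$approach %in% c(1, 2)
      stats::setNames(pats$approach[keep] == 2, pats$patient_id[keep])
    }
  )
  ser <- cohort$series[cohort$series$patient_id %in% names(grp), , drop = FALSE]
  ser$group1 <- grp[ser$patient_id]

  days <- sort(unique(ser$day))
  rows <- list()
  skipped <- integer(0)
  for (d in days) {
    sd <- ser[ser$day == d, ]
    v0 <- sd$crp_mg_L[!sd$group1]
    v1 <- sd$crp_mg_L[sd$group1]
    if (length(v0) < 2 || length(v1) < 2) {
      skipped <- c(skipped, d)
      next
    }
    p <- if (stats::var(v0) == 0 && stats::var(v1) == 0) {
      if (mean(v0) == mean(v1)) 1 else 0
    } else {
      stats::t.test(v1, v0)$p.value # Welch by default
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      day = d, n0 = length(v0), n1 = length(v1),
      mean0 = mean(v0), mean1 = mean(v1), p = p
    )
  }
  if (length(rows) == 0) stop("no day has >= 2 observations per group")
  out <- dplyr::bind_rows(rows)
  fdr <- bky_fdr(out$p, alpha = alpha)
  out$q <- fdr$q
  out$significant <- fdr$reject
  attr(out, "skipped_days") <- skipped
  out
}

#' Standard two-group test for a cohort variable
#'
#' Dispatches on the variable type the way the cohort summaries are
#' analysed: continuous variables by the Mann-Whitney (Wilcoxon rank-sum)
#' test, exact when both groups are small and tie-free, otherwise the
#' normal approximation with tie correction; dichotomous variables by
#' Fisher's exact test (two-sided, point-probability method); categorical
#' variables with more than two levels by the chi-square test.
#'
#' @param cohort A [crp_cohort()].
#' @param variable Name of a column of the patient table (e.g. `"age"`,
#'   `"bmi"`, `"sex"`, `"approach"`, `"indication_trauma"`).
#' @param grouping As in [per_day_comparison()].
#' @return A list: `test` (label), `p_value`, and `statistic` or `table`.
#' @export
two_group_tests <- function(cohort, variable, grouping = c("infection", "approach", "indication")) {
  grouping <- match.arg(grouping)
  stopifnot(inherits(cohort, "crp_cohort"))
  pats <- cohort$patients
  if (!variable %in% names(pats)) stop("unknown variable: ", variable)
  g <- switch(grouping,
    infection = pats$infection,
    indication = pats$indication_trauma,
    approach = {
      pats <- pats[pats$approach %in% c(1, 2), ]
      pats$approach == 2
    }
  )
  v <- pats[[variable]]
  if (length(unique(g)) < 2) stop("grouping is degenerate (single group)")

  is_cat <- is.logical(v) || length(unique(v)) <= 6 && all(v == round(as.numeric(v)))
  if (is.numeric(v) && !is_cat) {
    v0 <- v[!g]
    v1 <- v[g]
    exact <- length(v0) * length(v1) <= 400 && !any(duplicated(c(v0, v1)))
    ht <- suppressWarnings(stats::wilcox.test(v1, v0, exact = exact, correct = TRUE))
    list(test = "Mann-Whitney", p_value = ht$p.value, statistic = unname(ht$statistic))
  } else {
    tab <- table(factor(v), factor(g))
    if (any(dim(tab) < 2)) stop("degenerate contingency table for ", variable)
    if (nrow(tab) == 2) {
      ht <- stats::fisher.test(tab)
      list(test = "Fisher exact", p_value = ht$p.value, table = tab)
    } else {
      ht <- suppressWarnings(stats::chisq.test(tab))
      list(test = "Chi-square", p_value = ht$p.value, table = tab)
    }
  }
}

#' Power specification for a point-biserial correlation test
#'
#' @param rho Point-biserial correlation effect size, in (0, 1).
#' @param alpha Type-I error level, in (0, 1).
#' @param power Target power, in (0, 1).
#' @param tails `"one"` or `"two"`.
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(rho, alpha = 0.05, power = 0.95, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (!(rho > 0 && rho < 1)) stop("rho must lie in (0, 1)")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(power > 0 && power < 1)) stop("power must lie in (0, 1)")
  structure(list(rho = rho, alpha = alpha, power = power, tails = tails), class = "power_spec")
}

#' A-priori sample size for a point-biserial correlation
#'
#' Smallest total `n` such that the t-test of `rho = 0` under the
#' point-biserial model attains the requested power: the test statistic has
#' `n - 2` degrees of freedom and noncentrality
#' `delta = rho / sqrt(1 - rho^2) * sqrt(n)` under the alternative. With
#' `rho = 0.15`, `alpha = 0.05`, power 0.95 and a one-tailed test this gives
#' `n = 472`. The tail count is an explicit argument because it changes the
#' answer materially (the two-tailed requirement is 567).
#'
#' @param spec A [power_spec()], or `rho` directly with the remaining
#'   arguments.
#' @param ... Passed to [power_spec()] when `spec` is numeric.
#' @param n_max Search ceiling (error beyond it).
#' @return Integer sample size.
#' @export
sample_size_point_biserial <- function(spec, ..., n_max = 1e7) {
  if (!inherits(spec, "power_spec")) spec <- power_spec(spec, ...)
  a <- if (spec$tails == "one") spec$alpha else spec$alpha / 2
  pow <- function(n) {
    d <- spec$rho / sqrt(1 - spec$rho^2) * sqrt(n)
    stats::pt(stats::qt(1 - a, df = n - 2), df = n - 2, ncp = d, lower.tail = FALSE)
  }
  lo <- 4
  if (pow(lo) >= spec$power) return(as.integer(lo))
  hi <- 8
  while (pow(hi) < spec$power) {
    hi <- hi * 2
    if (hi > n_max) stop("requested power unattainable below n_max")
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pow(mid) >= spec$power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
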