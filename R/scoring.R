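#' Linear risk score
#'
#' A linear combination of encoded patient features plus an intercept, with
#' a decision cut-off. Orientation is fixed throughout the package: a score
#' strictly greater than the cut-off classifies as infection.
#'
#' @param coefficients Named numeric vector of feature weights. Allowed
#'   feature names: `second_peak` (0/1), `crp_max` (mg/L), `crp_max_day`
#'   (postoperative day of the maximum), `bmi` (kg/m^2), `sex` (1 = male,
#'   2 = female), `crp_preop_mean` (mg/L), `approach` (code 1-6),
#'   `failure_to_decline_d4` (0/1).
#' @param intercept Scalar intercept.
#' @param cutoff Decision cut-off; `score > cutoff` means infection.
#' @return An object of class `linear_score`.
#' @export
linear_score <- function(coefficients, intercept, cutoff) {
  allowed <- c(
    "second_peak", "crp_max", "crp_max_day", "bmi", "sex",
    "crp_preop_mean", "approach", "failure_to_decline_d4"
  )
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    stop("coefficients must be a named numeric vector")
  }
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad) > 0) stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  structure(
    list(coefficients = coefficients, intercept = intercept, cutoff = cutoff),
    class = "linear_score"
  )
}

#' @export
print.linear_score <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*%s", x$coefficients, names(x$coefficients)), collapse = " ")
  cat("<linear_score> ", terms, sprintf(" %+.4g ; infection if score > %.4g\n", x$intercept, x$cutoff), sep = "")
  invisible(x)
}

#' Evaluate a linear score on one or more feature sets
#'
#' @param model A [linear_score()].
#' @param features A named list or data frame providing every feature the
#'   model uses, with the encodings documented in [linear_score()].
#' @return Numeric score(s).
#' @export
score_linear <- function(model, features) {
  stopifnot(inherits(model, "linear_score"))
  features <- as.list(features)
  needed <- names(model$coefficients)
  miss <- needed[!vapply(needed, function(nm) !is.null(features[[nm]]), logical(1))]
  if (length(miss) > 0) stop("missing feature(s): ", paste(miss, collapse = ", "))
  vals <- do.call(cbind, features[needed])
  drop(vals %*% model$coefficients + model$intercept)
}

#' Classify by a linear score
#'
#' @param model A [linear_score()].
#' @param score Numeric score(s) from [score_linear()].
#' @return Logical: `TRUE` (infection) iff `score > model$cutoff` (strict).
#' @export
classify_score <- function(model, score) {
  score > model$cutoff
}

#' The published binary logistic risk score
#'
#' Six-feature score from a binary logistic regression of infection:
#' \deqn{-2.447\,\mathrm{2nd peak} + 0.004\,\mathrm{CRPmax} +
#'   0.029\,\mathrm{BMI} - 1.504\,\mathrm{sex} +
#'   0.381\,\mathrm{CRPmax\,day} + 0.024\,\mathrm{CRPpreop\,mean} - 5.85}
#' with cut-off -4.725 (score above it classifies as infection; at that
#' cut-off the original cohort gave 75% sensitivity, 80.03% specificity).
#'
#' @return A [linear_score()].
#' @export
published_binary_score_model <- function() {
  linear_score(
    coefficients = c(
      second_peak = -2.447, crp_max = 0.004, bmi = 0.029,
      sex = -1.504, crp_max_day = 0.381, crp_preop_mean = 0.024
    ),
    intercept = -5.85,
    cutoff = -4.725
  )
}

#' The published multinomial-regression risk score
#'
#' Five-feature score fit as a multinomial logistic regression (with a
#' binary outcome this reduces to a single linear score):
#' \deqn{1.957\,\mathrm{approach} + 0.0041\,\mathrm{CRPpreop\,mean} +
#'   0.611\,\mathrm{CRPmax\,day} - 18.57\,\mathrm{sex} +
#'   1.965\,\mathrm{failure\ to\ decline} + 4.988}
#' with cut-off -8.566 (87.5% sensitivity, 78.85% specificity on the
#' original cohort). The failure-to-decline feature is the rule's later
#' assessment day (4 days after the peak). Note the large sex coefficient
#' (-18.57) makes sex nearly decisive between codes 1 and 2; it is applied
#' exactly as published.
#'
#' @return A [linear_score()].
#' @export
published_multinomial_score_model <- function() {
  linear_score(
    coefficients = c(
      approach = 1.957, crp_preop_mean = 0.0041, crp_max_day = 0.611,
      sex = -18.57, failure_to_decline_d4 = 1.965
    ),
    intercept = 4.988,
    cutoff = -8.566
  )
}

#' Published binary-regression score of one feature set
#'
#' @param features Named list/data frame with `second_peak`, `crp_max`,
#'   `bmi`, `sex`, `crp_max_day`, `crp_preop_mean`.
#' @return Numeric score(s); infection is called when the score exceeds
#'   -4.725.
#' @export
published_binary_score <- function(features) {
  score_linear(published_binary_score_model(), features)
}

#' Published multinomial-regression score of one feature set
#'
#' @param features Named list/data frame with `approach`, `crp_preop_mean`,
#'   `crp_max_day`, `sex`, `failure_to_decline_d4`.
#' @return Numeric score(s); infection is called when the score exceeds
#'   -8.566.
#' @export
published_multinomial_score <- function(features) {
  score_linear(published_multinomial_score_model(), features)
}

#' Single-variable classifier on the maximum postoperative CRP
#'
#' @param crp_max Maximum postoperative CRP (mg/L), >= 0.
#' @param cutoff Cut-off in mg/L; the published value is 91.20 (75%
#'   sensitivity, 56.86% specificity on the original cohort).
#' @return Logical: infection iff `crp_max > cutoff` (strict).
#' @export
crp_max_classifier <- function(crp_max, cutoff = 91.20) {
  if (any(crp_max < 0)) stop("crp_max must be >= 0")
  crp_max > cutoff
}

#' ROC analysis of a score against infection labels
#'
#' Sweeps thresholds over the midpoints between consecutive sorted unique
#' scores, plus -Inf and +Inf endpoints, with orientation "score above
#' threshold means positive". The AUC is the trapezoid area over
#' `(1 - specificity, sensitivity)`; it equals the Mann-Whitney U statistic
#' divided by `n1 * n0` (the rank form, see [auc_rank()]).
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) infection labels; both classes required.
#' @return A list of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need at least one positive and one negative label")

  u <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  sens <- vapply(thresholds, function(t) sum(scores > t & labels) / n1, numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores <= t & !labels) / n0, numeric(1))

  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)
  structure(
    list(thresholds = thresholds, sensitivity = sens, specificity = spec, auc = auc),
    class = "roc_result"
  )
}

#' AUC by the rank (Mann-Whitney U) form
#'
#' `U / (n1 * n0)` with the midrank convention for ties; equals the
#' trapezoid AUC of [roc_analysis()].
#'
#' @inheritParams roc_analysis
#' @return The AUC as a scalar.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need at least one positive and one negative label")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a fixed cut-off
#'
#' @inheritParams roc_analysis
#' @param cutoff Decision cut-off; `score > cutoff` is called positive.
#' @return Named numeric vector `c(sensitivity = ..., specificity = ...)`.
#' @export
sens_spec_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need at least one positive and one negative label")
  pos <- scores > cutoff
  c(
    sensitivity = sum(pos & labels) / n1,
    specificity = sum(!pos & !labels) / n0
  )
}

#' Fit a logistic regression risk score
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]), optionally with backward elimination: the
#' term with the largest likelihood-ratio p-value is dropped until every
#' remaining term has p < `stay_p`. Reports Cox-Snell and Nagelkerke
#' pseudo-R^2.
#'
#' @param features A data frame of numeric predictors (no constant columns).
#' @param labels Logical (or 0/1) outcome; `n` must exceed the number of
#'   predictors.
#' @param selection `"none"` or `"backward"`.
#' @param stay_p Backward-elimination stay threshold on the LRT p-value
#'   (default 0.10).
#' @return A list of class `logistic_fit`: `model` (a [linear_score()] with
#'   cut-off 0 on the log-odds scale, i.e. probability 0.5), `log_lik`,
#'   `cox_snell_r2`, `nagelkerke_r2`, `dropped` (features removed by
#'   selection), and `glm` (the underlying fit).
#' @export
fit_logistic <- function(features, labels, selection = c("none", "backward"), stay_p = 0.10) {
  selection <- match.arg(selection)
  features <- as.data.frame(features)
  labels <- as.logical(labels)
  if (nrow(features) != length(labels)) stop("features and labels differ in length")
  if (nrow(features) <= ncol(features)) stop("need n > number of features")
  const <- vapply(features, function(v) stats::var(v) == 0, logical(1))
  if (any(const)) stop("constant feature column(s): ", paste(names(features)[const], collapse = ", "))

  fit_once <- function(dat) {
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(..y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    if (sep) stop("perfect (or quasi-) separation detected; consider a penalized fit")
    if (!fit$converged) stop("logistic regression did not converge")
    fit
  }

  dat <- cbind(features, ..y = labels)
  fit <- fit_once(dat)
  dropped <- character(0)

  if (selection == "backward") {
    repeat {
      vars <- setdiff(names(dat), "..y")
      if (length(vars) == 0) break
      ll_full <- as.numeric(stats::logLik(fit))
      pvals <- vapply(vars, function(v) {
        red <- dat[, setdiff(names(dat), v), drop = FALSE]
        f_red <- if (length(vars) == 1) {
          stats::glm(..y ~ 1, data = red, family = stats::binomial())
        } else {
          fit_once(red)
        }
        lr <- 2 * (ll_full - as.numeric(stats::logLik(f_red)))
        stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(pvals)
      if (pvals[worst] < stay_p) break
      dropped <- c(dropped, vars[worst])
      dat <- dat[, setdiff(names(dat), vars[worst]), drop = FALSE]
      if (ncol(dat) == 1) { # only the outcome left
        fit <- stats::glm(..y ~ 1, data = dat, family = stats::binomial())
        break
      }
      fit <- fit_once(dat)
    }
  }

  cf <- stats::coef(fit)
  n <- nrow(dat)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(labels ~ 1, family = stats::binomial())))
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  nagelkerke <- cox_snell / (1 - exp(2 * ll0 / n))

  coefs <- cf[setdiff(names(cf), "(Intercept)")]
  model <- if (length(coefs) > 0 && all(names(coefs) %in% c(
    "second_peak", "crp_max", "crp_max_day", "bmi", "sex",
    "crp_preop_mean", "approach", "failure_to_decline_d4"
  ))) {
    linear_score(coefs, intercept = unname(cf["(Intercept)"]), cutoff = 0)
  } else {
    structure(
      list(coefficients = coefs, intercept = unname(cf["(Intercept)"]), cutoff = 0),
      class = "linear_score"
    )
  }
  structure(
    list(
      model = model, log_lik = ll1, cox_snell_r2 = cox_snell,
      nagelkerke_r2 = nagelkerke, dropped = dropped, glm = fit
    ),
    class = "logistic_fit"
  )
}

#' Serialize a linear score to JSON
#'
#' @param model A [linear_score()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_linear_score <- function(model, path) {
  jsonlite::write_json(
    list(
      coefficients = as.list(model$coefficients),
      intercept = model$intercept, cutoff = model$cutoff
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a linear score from JSON
#'
#' @param path File written by [write_linear_score()].
#' @return A [linear_score()].
#' @export
read_linear_score <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_score(unlist(x$coefficients), x$intercept, x$cutoff)
}
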