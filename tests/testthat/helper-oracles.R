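# Independent oracles kept deliberately naive: each re-derives the quantity
# from its definition, not from the package implementation.

# literal two-stage Benjamini-Krieger-Yekutieli rejection set:
# stage 1 = BH step-up at a' = a/(1+a); r1 = 0 -> none, r1 = m -> all;
# otherwise stage 2 = BH step-up at a'' = a' * m / (m - r1).
oracle_bky_reject <- function(p, alpha = 0.05) {
  bh <- function(p, a) {
    m <- length(p)
    o <- order(p)
    rej <- rep(FALSE, m)
    k <- 0
    for (i in m:1) {
      if (p[o[i]] <= i / m * a) {
        k <- i
        break
      }
    }
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    rej
  }
  m <- length(p)
  a1 <- alpha / (1 + alpha)
  stage1 <- bh(p, a1)
  r1 <- sum(stage1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, a1 * m / (m - r1))
}

# AUC as the proportion of positive-negative pairs ranked concordantly
# (ties count 1/2), by explicit double loop
oracle_auc_pairs <- function(scores, labels) {
  s1 <- scores[as.logical(labels)]
  s0 <- scores[!as.logical(labels)]
  tot <- 0
  for (a in s1) {
    for (b in s0) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(s1) * length(s0))
}

# brute-force local-peak scan: every interior triple
oracle_local_peaks <- function(day, val, min_rise = 0) {
  n <- length(val)
  keep <- logical(n)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      keep[i] <- val[i] > val[i - 1] && val[i] > val[i + 1] &&
        (val[i] - val[i - 1]) >= min_rise && (val[i] - val[i + 1]) >= min_rise
    }
  }
  data.frame(day = day[keep], value = val[keep])
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# sample-size oracle via the Fisher-z normal approximation
oracle_n_fisher_z <- function(rho, alpha, power, tails = "one") {
  a <- if (tails == "one") alpha else alpha / 2
  ((stats::qnorm(1 - a) + stats::qnorm(power)) / atanh(rho))^2 + 3
}

# a small two-patient cohort used by several file-format tests
make_tiny_cohort <- function() {
  patients <- tibble::tibble(
    patient_id = c("a", "b"),
    age = c(70, 65),
    sex = c(1, 2),
    bmi = c(26.5, 31.2),
    approach = c(1, 2),
    indication_trauma = c(FALSE, TRUE),
    days_until_surgery = c(1, 3),
    postop_days_in_hospital = c(10, 12),
    infection = c(FALSE, TRUE),
    organism = c(NA_character_, "S. aureus")
  )
  series <- tibble::tibble(
    patient_id = c("a", "a", "a", "b", "b", "b", "b"),
    day = c(-1, 1, 3, -2, 1, 4, 8),
    crp_mg_L = c(4.2, 80, 120, 10, 95, 140, 60)
  )
  crp_cohort(patients, series)
}

# random postoperative series with strictly increasing integer days
random_series <- function(len) {
  days <- sort(sample(1:20, len))
  tibble::tibble(day = days, crp_mg_L = round(stats::runif(len, 1, 200), 1))
}
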