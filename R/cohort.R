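# Cohort-level statistics: category proportions, 2x2 association tests,
# Kaplan-Meier estimates and the log-rank (Mantel-Cox) test.
#
# The association and survival tests are standard procedures and delegate to
# base R (fisher.test, chisq.test) and the survival package (survfit,
# survdiff) behind a uniform interface; the test suite checks them against
# hand-computed and enumeration oracles.

#' Counts and percentages of TSR categories
#'
#' @param categories Vector (character or factor) of `"low"` / `"high"`
#'   labels, one per patient.
#' @param digits Decimal places for the percentages. The default (1) matches
#'   the precision at which clinical cohort tables conventionally report
#'   category percentages.
#' @return `data.frame` with columns `category`, `n`, `percent`
#'   (`100 * n / total`, rounded to `digits` decimals).
#' @examples
#' cohort_proportions(rep(c("low", "high"), c(31, 41)))
#' @export
cohort_proportions <- function(categories, digits = 1) {
  if (length(categories) == 0) stop("empty category list", call. = FALSE)
  f <- factor(as.character(categories), levels = c("low", "high"))
  if (anyNA(f)) stop("categories must be 'low' or 'high'", call. = FALSE)
  n <- as.vector(table(f))
  data.frame(category = levels(f),
             n = n,
             percent = round(100 * n / length(f), digits),
             stringsAsFactors = FALSE)
}

as_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  stopifnot(is.numeric(x), all(x >= 0), all(x == round(x)))
  if (sum(x) == 0) stop("empty contingency table", call. = FALSE)
  matrix(x, 2, 2, byrow = TRUE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed table. A table with a zero margin is degenerate
#' and returns p = 1 by convention.
#'
#' @param a,b,c,d Cell counts, row-wise (`a b` / `c d`).
#' @return List with `p_value` and `method`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  m <- as_2x2(a, b, c, d)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p_value = 1, method = "Fisher's exact test (degenerate margin)"))
  }
  list(p_value = stats::fisher.test(m)$p.value,
       method = "Fisher's exact test")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic without continuity correction, with the p-value from the
#' chi-square distribution on 1 degree of freedom. Errors when any expected
#' count is zero (use [fisher_exact_2x2()] instead).
#'
#' @param a,b,c,d Cell counts, row-wise.
#' @return List with `statistic`, `p_value`, `expected` and `method`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  m <- as_2x2(a, b, c, d)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    stop("zero expected count: use fisher_exact_2x2()", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       expected = expected,
       method = "Pearson chi-square, no continuity correction")
}

check_survival <- function(time, event) {
  stopifnot(is.numeric(time), length(time) == length(event))
  keep <- !is.na(time)
  time <- time[keep]; event <- as.integer(event[keep])
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  stopifnot(all(event %in% c(0L, 1L)))
  list(time = time, event = event, n_excluded = sum(!keep))
}

#' Kaplan-Meier product-limit estimate
#'
#' Records with missing time are excluded (patients without a documented
#' recurrence timepoint). Survival is 1 before the first event; censored
#' records shrink the risk set without a probability drop.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return `data.frame` with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, one row per distinct observed time, with an implicit
#'   `survival = 1` at time 0.
#' @export
km_estimate <- function(time, event) {
  s <- check_survival(time, event)
  if (length(s$time) == 0) stop("no usable records", call. = FALSE)
  fit <- survival::survfit(survival::Surv(s$time, s$event) ~ 1)
  data.frame(time = fit$time,
             n_risk = fit$n.risk,
             n_event = fit$n.event,
             n_censor = fit$n.censor,
             survival = fit$surv)
}

#' Log-rank (Mantel-Cox) test for two groups
#'
#' Mantel-Cox statistic `(O - E)^2 / V` summed over distinct event times,
#' with the p-value from the chi-square distribution on 1 degree of freedom.
#' Records with missing time are excluded.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping vector (e.g. the TSR category).
#' @return List with `statistic`, `p_value`, `n`, `n_events` and `method`.
#' @export
logrank_test <- function(time, event, group) {
  s <- check_survival(time, event)
  group <- factor(group[!is.na(time)])
  if (nlevels(group) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(tabulate(group, 2) == 0)) stop("both groups must be non-empty", call. = FALSE)
  if (sum(s$event) == 0) {
    stop("log-rank test undefined: no events observed", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(s$time, s$event) ~ group)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = length(s$time),
       n_events = sum(s$event),
       method = "Log-rank (Mantel-Cox) test")
}

#' Cohort survival report for dichotomized TSR
#'
#' Joins per-patient TSR categories with follow-up records, computes
#' Kaplan-Meier step coordinates per category and the log-rank test between
#' the low- and high-TSR groups. Patients present in only one of the two
#' tables, or lacking a usable time, are dropped (with counts reported).
#'
#' @param patients `data.frame` with `patient_id` and `category`
#'   (from [aggregate_patients()]).
#' @param followup `data.frame` with `patient_id`, `time_months`, `event`.
#' @return List with `n_matched`, `n_dropped`, per-group `km` tables,
#'   `logrank` and the group sizes; serializable to JSON.
#' @export
survival_report <- function(patients, followup) {
  stopifnot(all(c("patient_id", "category") %in% names(patients)),
            all(c("patient_id", "time_months", "event") %in% names(followup)))
  m <- merge(patients[, c("patient_id", "category")], followup,
             by = "patient_id")
  usable <- !is.na(m$time_months)
  n_dropped <- (length(unique(patients$patient_id)) - nrow(m)) + sum(!usable)
  m <- m[usable, , drop = FALSE]
  if (nrow(m) == 0) stop("no patients with usable follow-up", call. = FALSE)
  km <- lapply(split(m, factor(m$category, levels = c("low", "high"))),
               function(g) {
                 if (nrow(g) == 0) return(NULL)
                 km_estimate(g$time_months, g$event)
               })
  lr <- if (length(unique(m$category)) == 2) {
    logrank_test(m$time_months, m$event, m$category)
  } else NULL
  list(n_matched = nrow(m),
       n_dropped = n_dropped,
       group_sizes = as.list(table(factor(m$category, c("low", "high")))),
       km = km,
       logrank = lr)
}
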