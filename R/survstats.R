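# Survival and clinical association statistics: Kaplan-Meier, log-rank, Cox
# proportional hazards, and the contingency/group tests.

# Coerce to the canonical survival tibble; optionally apply administrative
# censoring at `follow_up` months (e.g. 24 for a 2-year analysis window).
as_survival_data <- function(data, follow_up = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("os_months", "event")
  if (!all(need %in% names(data))) {
    abort("survival data needs columns os_months and event")
  }
  if (any(!is.finite(data$os_months)) || any(data$os_months <= 0)) {
    abort("survival times must be positive and finite")
  }
  if (!all(data$event %in% c(0, 1))) abort("event must be 0 (censored) or 1 (death)")
  out <- as_tibble(data)
  if (!is.null(follow_up)) {
    over <- out$os_months > follow_up
    out$event[over] <- 0L
    out$os_months[over] <- follow_up
  }
  out
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per group, with the median defined as the smallest
#' time at which the survival curve drops to or below 0.5 (`NA` when never
#' reached).
#'
#' @param data Data frame with `os_months`, `event` (1 = death, 0 =
#'   censored) and optionally `group`.
#' @param follow_up Optional administrative censoring horizon in months.
#'
#' @return A `km_estimate`: list with `curve` (tibble `group`, `time`,
#'   `n_risk`, `n_event`, `surv`) and `medians` (tibble `group`, `n`,
#'   `events`, `median`).
#' @export
km_estimate <- function(data, follow_up = NULL) {
  data <- as_survival_data(data, follow_up)
  grp <-if ("group" %in% names(data)) as.character(data$group) else rep("all", nrow(data))
  fit <- survival::survfit(
    survival::Surv(os_months, event) ~ strata,
    data = data.frame(os_months = data$os_months, event = data$event, strata = grp)
  )
  sm <- summary(fit)
  groups <- if (is.null(sm$strata)) rep(unique(grp), length(sm$time)) else
    sub("^strata=", "", as.character(sm$strata))
  curve <- tibble(group = as.character(groups),
                  time = as.numeric(sm$time),
                  n_risk = as.numeric(sm$n.risk),
                  n_event = as.numeric(sm$n.event),
                  surv = if (length(sm$time)) as.numeric(sm$surv) else numeric(0))
  medians <- curve |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      median = if (any(.data$surv <= 0.5)) min(.data$time[.data$surv <= 0.5]) else NA_real_
    )
  medians <- dplyr::left_join(
    tibble(group = unique(grp)) |>
      dplyr::mutate(n = vapply(.data$group, function(g) sum(grp == g), numeric(1)),
                    events = vapply(.data$group, function(g) sum(data$event[grp == g]), numeric(1))),
    medians, by = "group"
  )
  structure(list(curve = curve, medians = medians), class = "km_estimate")
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) log-rank chi-square over the distinct event times,
#' with `df = groups - 1`.
#'
#' @inheritParams km_estimate
#' @return A tibble `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, follow_up = NULL) {
  data <- as_survival_data(data, follow_up)
  if (!"group" %in% names(data)) abort("survival data needs a `group` column")
  grp <- factor(as.character(data$group))
  if (nlevels(grp) < 2) abort("need at least 2 groups")
  if (any(table(grp) == 0)) abort("a group has zero samples")
  if (sum(data$event) == 0) abort("need at least one event")
  fit <- survival::survdiff(
    survival::Surv(os_months, event) ~ grp,
    data = data.frame(os_months = data$os_months, event = data$event, grp = grp)
  )
  df <- nlevels(grp) - 1L
  tibble(statistic = fit$chisq, df = df,
         p_value = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; per-covariate hazard
#' ratios with Wald confidence intervals and p-values.
#'
#' @param data Data frame with `os_months` and `event`.
#' @param covariates Character vector of covariate column names in `data`,
#'   or a separate data frame of covariates (row order matching `data`).
#' @param follow_up Optional administrative censoring horizon in months.
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @param ties Tie-handling method (`"efron"` or `"breslow"`).
#'
#' @return A `cox_fit` tibble `term`, `estimate` (log HR), `hazard_ratio`,
#'   `conf_low`, `conf_high`, `std_error`, `statistic`, `p_value`, with the
#'   `survival::coxph` fit in attribute `fit`.
#' @export
cox_ph <- function(data, covariates, follow_up = NULL, conf_level = 0.95,
                   ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  data <- as_survival_data(data, follow_up)
  if (is.character(covariates)) {
    missing <- setdiff(covariates, names(data))
    if (length(missing)) abort(sprintf("covariate(s) not in data: %s",
                                       paste(missing, collapse = ", ")))
    covs <- data[covariates]
  } else {
    covs <- as_tibble(covariates)
  }
  constant <- vapply(covs, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    abort(sprintf("constant covariate(s): %s",
                  paste(names(covs)[constant], collapse = ", ")))
  }
  df <- data.frame(os_months = data$os_months, event = data$event, covs)
  form <- stats::as.formula(paste(
    "survival::Surv(os_months, event) ~",
    paste(sprintf("`%s`", names(covs)), collapse = " + ")
  ))
  fit <- withCallingHandlers(
    survival::coxph(form, data = df, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("Ran out of iterations", conditionMessage(w))) {
        abort(paste("Cox model did not converge in 100 iterations:",
                    conditionMessage(w)))
      }
      # separation and infinite-coefficient warnings pass through unchanged
    }
  )
  s <- summary(fit, conf.int = conf_level)
  out <- tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    hazard_ratio = s$coefficients[, "exp(coef)"],
    conf_low = s$conf.int[, 3],
    conf_high = s$conf.int[, 4],
    std_error = s$coefficients[, "se(coef)"],
    statistic = s$coefficients[, "z"],
    p_value = s$coefficients[, "Pr(>|z|)"]
  )
  attr(out, "fit") <- fit
  class(out) <- c("cox_fit", class(out))
  out
}

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic without continuity correction, `df = (r - 1)(c -
#' 1)`. "Unknown" rows, when present, enter as ordinary categories unless
#' `drop_unknown`.
#'
#' @param table A counts matrix (>= 2 rows and columns) with dimnames.
#' @param drop_unknown Drop a row named `"unknown"` before testing.
#'
#' @return A tibble `statistic`, `df`, `p_value`.
#' @export
pearson_chisq <- function(table, drop_unknown = FALSE) {
  if (!is.matrix(table)) table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  if (drop_unknown && !is.null(rownames(table))) {
    table <- table[tolower(rownames(table)) != "unknown", , drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) abort("need at least 2 rows and 2 columns")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero row or column margin")
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value)
}

#' Group-comparison tests for continuous variables
#'
#' One-way ANOVA and Kruskal-Wallis for multi-group comparisons; two-sample
#' t (pooled-variance by default, Welch optional) and Mann-Whitney U for
#' two-group comparisons. All p-values two-sided.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length as `values`.
#' @return A tibble with the test statistic, degrees of freedom where
#'   defined, and `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- check_groups(values, groups, min_groups = 2)
  fit <- summary(aov(values ~ groups))[[1]]
  tibble(statistic = fit[["F value"]][1], df1 = fit[["Df"]][1],
         df2 = fit[["Df"]][2], p_value = fit[["Pr(>F)"]][1])
}

#' @rdname anova_oneway
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- check_groups(values, groups, min_groups = 2)
  res <- kruskal.test(values, groups)
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value)
}

#' @rdname anova_oneway
#' @param a,b Numeric samples to compare.
#' @param welch Use the Welch (unequal-variance) t-test.
#' @export
t_test <- function(a, b, welch = FALSE) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  res <- t.test(a, b, var.equal = !welch)
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value)
}

#' @rdname anova_oneway
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  res <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  tibble(statistic = unname(res$statistic), p_value = res$p.value)
}

check_groups <- function(values, groups, min_groups = 2) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have the same length")
  }
  groups <- factor(as.character(groups))
  if (nlevels(groups) < min_groups) {
    abort(sprintf("need at least %d groups", min_groups))
  }
  if (any(table(groups) == 0)) abort("a group has zero members")
  groups
}
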