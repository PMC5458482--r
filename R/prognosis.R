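#' Survivor methylation signature
#'
#' Compares primary tumors from short survivors (melanoma-specific death
#' before `cutoff_months`) with long survivors (survival beyond
#' `cutoff_months`) probe by probe: group means (means, not the medians of
#' the DGMB screen), Mann-Whitney p, Benjamini-Hochberg adjustment, and
#' selection of probes with `|mean difference| >= diff_min` and adjusted
#' p below `q_max`. Samples whose survival equals the cutoff exactly, and
#' censored samples with follow-up shorter than the cutoff, are ambiguous
#' and excluded (IDs logged in attribute `"excluded"`); set
#' `short_followup_as_long = TRUE` to count the latter as long survivors.
#'
#' @param beta beta-value matrix.
#' @param sheet sample sheet (see [read_sample_sheet()]); only rows with
#'   `group == "primary"` are used.
#' @param cutoff_months survival cutoff separating short from long.
#' @param diff_min minimum absolute mean-beta difference.
#' @param q_max adjusted-p ceiling.
#' @param min_group_n minimum non-missing values per group per probe.
#' @param short_followup_as_long count censored short-follow-up samples as
#'   long survivors instead of excluding them.
#' @return data.frame of class `"survivor_signature"`, one row per testable
#'   probe: `probe_id`, `mean_short`, `mean_long`, `mean_diff`
#'   (short minus long), `p_raw`, `p_adj`, `selected`. Attributes:
#'   `groups` (sample IDs per arm), `excluded`, `params`.
#' @export
survivor_signature <- function(beta, sheet, cutoff_months = 48,
                               diff_min = 0.2, q_max = 0.01,
                               min_group_n = 3L,
                               short_followup_as_long = FALSE) {
  pri <- sheet[sheet$group == "primary" & !is.na(sheet$survival_months), ,
               drop = FALSE]
  short <- pri$sample_id[pri$event & pri$survival_months < cutoff_months]
  long <- pri$sample_id[pri$survival_months > cutoff_months]
  ambiguous <- pri$sample_id[pri$survival_months == cutoff_months]
  short_fu <- pri$sample_id[!pri$event & pri$survival_months < cutoff_months]
  if (short_followup_as_long) {
    long <- union(long, short_fu)
    excluded <- ambiguous
  } else {
    excluded <- c(ambiguous, short_fu)
  }
  short <- intersect(short, colnames(beta))
  long <- intersect(long, colnames(beta))
  if (length(short) < 3 || length(long) < 3)
    stop(sprintf("need >= 3 samples per survival arm (short %d, long %d)",
                 length(short), length(long)))

  ms <- beta[, short, drop = FALSE]
  ml <- beta[, long, drop = FALSE]
  testable <- rowSums(!is.na(ms)) >= min_group_n &
              rowSums(!is.na(ml)) >= min_group_n
  ms <- ms[testable, , drop = FALSE]
  ml <- ml[testable, , drop = FALSE]
  mean_short <- rowMeans(ms, na.rm = TRUE)
  mean_long <- rowMeans(ml, na.rm = TRUE)
  p_raw <- vapply(seq_len(nrow(ms)), function(i) {
    mann_whitney(ms[i, ], ml[i, ], min_group_n = min_group_n)
  }, 0)
  p_adj <- bh_adjust(p_raw)
  diff <- mean_short - mean_long
  out <- data.frame(
    probe_id = rownames(beta)[testable],
    mean_short = mean_short, mean_long = mean_long, mean_diff = diff,
    p_raw = p_raw, p_adj = p_adj,
    selected = abs(diff) >= diff_min & !is.na(p_adj) & p_adj < q_max,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("survivor_signature", "data.frame"),
            groups = list(short = short, long = long),
            excluded = excluded,
            params = list(cutoff_months = cutoff_months,
                          diff_min = diff_min, q_max = q_max))
}

#' @export
print.survivor_signature <- function(x, ...) {
  g <- attr(x, "groups")
  pr <- attr(x, "params")
  cat(sprintf(
    "Survivor signature (cutoff %g months: %d short vs %d long survivors)\n",
    pr$cutoff_months, length(g$short), length(g$long)))
  cat(sprintf("  %d testable probes, %d selected (|diff| >= %.2f, q < %.3g)\n",
              nrow(x), sum(x$selected), pr$diff_min, pr$q_max))
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. Censored times enter
#' the risk sets but never drop the curve; S(0) = 1 and the curve is
#' non-increasing and right-continuous.
#'
#' @param time follow-up times (months), non-negative.
#' @param event logical/0-1 event indicators.
#' @return data.frame of class `"km_curve"`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, one row per distinct observed time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("need at least one record")
  if (any(time < 0)) stop("negative survival time")
  event <- as.logical(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' @export
#' @rdname km_estimate
#' @param x a `"km_curve"`.
#' @param ... passed to [graphics::plot()].
plot.km_curve <- function(x, ...) {
  graphics::plot(c(0, x$time), c(1, x$surv), type = "s",
                 xlab = "time (months)", ylab = "survival", ylim = c(0, 1),
                 ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: at each event time the observed events per
#' group are compared with their hypergeometric expectation given the risk
#' sets; the standardized squared sum is chi-square with 1 df.
#'
#' @param time,event follow-up times and event flags.
#' @param group two-level grouping vector.
#' @return list `chi_square`, `p`, `n_events`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2)
    stop("log-rank test needs exactly two non-empty groups")
  event <- as.logical(event)
  if (!any(event)) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi_square = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n_events = sum(event))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Cox regression of survival on a dichotomized marker and clinical
#' covariates (Breslow thickness, ulceration) via the partial likelihood
#' with Breslow tie handling by default (Efron behind `ties`). Monotone
#' likelihoods (perfect separation) and constant covariates are flagged
#' `converged = FALSE` with `NA` estimates rather than reported as spurious
#' numbers.
#'
#' @param data data.frame with columns `time`, `event` plus the covariates.
#' @param covariates character vector of covariate column names; logical or
#'   `low`/`high` character columns are encoded 0/1.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame of class `"cox_fit"`: `covariate`, `coef`, `hr`,
#'   `ci_lower`, `ci_upper` (95%), `p` (Wald), `converged`; attribute
#'   `"model"` holds the `coxph` object.
#' @export
cox_fit <- function(data, covariates = c("marker_level", "breslow_mm",
                                         "ulceration"),
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)))
  if (!any(as.logical(data$event))) stop("no events observed")
  d <- data
  for (cv in covariates) {
    if (!cv %in% names(d)) stop("missing covariate column: ", cv)
    v <- d[[cv]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      if (!all(v %in% c("low", "high")))
        stop("character covariate '", cv, "' must be low/high")
      v <- as.numeric(v == "high")
    } else if (is.logical(v)) {
      v <- as.numeric(v)
    }
    d[[cv]] <- v
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, as.logical(event)) ~",
    paste(covariates, collapse = " + ")))
  constant <- vapply(covariates, function(cv) stats::var(d[[cv]]) == 0, TRUE)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) invokeRestart("muffleWarning"))
  sm <- summary(fit)
  coefs <- sm$coefficients
  se <- coefs[, "se(coef)"]
  est <- coefs[, "coef"]
  # monotone likelihood shows up as exploding |coef| and se
  diverged <- !is.na(est) & (abs(est) > 15 | se > 100)
  ok <- !constant & !is.na(est) & !diverged
  out <- data.frame(
    covariate = covariates,
    coef = ifelse(ok, est, NA_real_),
    hr = ifelse(ok, exp(est), NA_real_),
    ci_lower = ifelse(ok, exp(est - stats::qnorm(0.975) * se), NA_real_),
    ci_upper = ifelse(ok, exp(est + stats::qnorm(0.975) * se), NA_real_),
    p = ifelse(ok, coefs[, "Pr(>|z|)"], NA_real_),
    converged = ok,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(out, class = c("cox_fit", "data.frame"), model = fit)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit\n")
  df <- as.data.frame(x)
  df$hr <- round(df$hr, 3)
  df$ci_lower <- round(df$ci_lower, 3)
  df$ci_upper <- round(df$ci_upper, 3)
  df$p <- signif(df$p, 3)
  print(df[, c("covariate", "hr", "ci_lower", "ci_upper", "p", "converged")],
        row.names = FALSE)
  invisible(x)
}

#' Dichotomize a marker into low / high
#'
#' Splits continuous marker values (e.g. H-scores or methylation fractions)
#' at a cohort-derived cutoff: the median, the first or third quartile
#' (type-7 linear-interpolation quantiles), or a fixed value
#' (`"fixed:x"`). `high` means strictly above the cutoff; ties at the
#' cutoff go to `low`.
#'
#' @param values numeric marker values.
#' @param rule `"median"`, `"q1"`, `"q3"` or `"fixed:x"`.
#' @return character vector (`"low"`/`"high"`) with attribute `"cutoff"`.
#' @export
#' @examples
#' dichotomize(1:10)  # 6..10 high
dichotomize <- function(values, rule = "median") {
  if (any(is.na(values))) stop("missing marker values")
  cutoff <- if (rule == "median") {
    stats::median(values)
  } else if (rule == "q1") {
    stats::quantile(values, 0.25, type = 7, names = FALSE)
  } else if (rule == "q3") {
    stats::quantile(values, 0.75, type = 7, names = FALSE)
  } else if (grepl("^fixed:", rule)) {
    as.numeric(sub("^fixed:", "", rule))
  } else {
    stop("unknown dichotomization rule: ", rule)
  }
  if (!grepl("^fixed:", rule) && length(unique(values)) == 1)
    stop("all marker values identical: no split possible")
  structure(ifelse(values > cutoff, "high", "low"), cutoff = cutoff)
}
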