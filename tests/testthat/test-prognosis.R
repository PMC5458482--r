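test_that("survivor signature recovers planted prognostic probes", {
  fx <- make_survivor_fixture()
  sig <- survivor_signature(fx$sim$beta, fx$sheet)
  planted <- fx$sim$truth$probe_id[fx$sim$truth$class == "prognostic"]
  sens <- mean(planted %in% sig$probe_id[sig$selected])
  expect_gte(sens, 0.9)
  false_hits <- setdiff(sig$probe_id[sig$selected], planted)
  expect_lte(length(false_hits), 0.1 * sum(sig$selected))
})

test_that("survivor signature applies the mean-difference gate strictly", {
  fx <- make_survivor_fixture(delta = 0.19, n_planted = 40)
  sig <- survivor_signature(fx$sim$beta, fx$sheet)
  # shifts straddle 0.19 < 0.2: essentially nothing passes the gate even
  # though the planted p-values are tiny
  planted <- fx$sim$truth$probe_id[fx$sim$truth$class == "prognostic"]
  rows <- sig[sig$probe_id %in% planted, ]
  small_effect <- rows[abs(rows$mean_diff) < 0.2, ]
  expect_gt(nrow(small_effect), 0)
  expect_false(any(small_effect$selected))
  expect_true(all(small_effect$p_adj < 0.01))  # gated on effect, not p
})

test_that("identical survival arms select nothing and selection is monotone", {
  fx <- make_survivor_fixture(n_planted = 0, n_probes = 500)
  sig0 <- survivor_signature(fx$sim$beta, fx$sheet)
  expect_equal(sum(sig0$selected), 0)

  fx2 <- make_survivor_fixture()
  n_sel <- function(...) sum(survivor_signature(fx2$sim$beta, fx2$sheet,
                                                ...)$selected)
  base <- n_sel()
  expect_lte(n_sel(diff_min = 0.35), base)
  expect_lte(n_sel(q_max = 1e-6), base)

  # ambiguous samples are excluded (and logged)
  sheet <- fx2$sheet
  sheet$survival_months[1] <- 48
  sig <- survivor_signature(fx2$sim$beta, sheet)
  expect_true(sheet$sample_id[1] %in% attr(sig, "excluded"))
  # short-follow-up censored samples excluded unless opted in as long
  sheet2 <- fx2$sheet
  short_ids <- sheet2$sample_id[sheet2$survival_months < 48]
  sheet2$event[sheet2$sample_id %in% short_ids[1:5]] <- FALSE
  sig_def <- survivor_signature(fx2$sim$beta, sheet2)
  expect_setequal(attr(sig_def, "excluded"), short_ids[1:5])
  expect_equal(length(attr(sig_def, "groups")$short),
               length(short_ids) - 5)
  sig2 <- survivor_signature(fx2$sim$beta, sheet2,
                             short_followup_as_long = TRUE)
  expect_equal(length(attr(sig2, "groups")$long), 25)
  expect_equal(length(attr(sig2, "excluded")), 0)
})

test_that("Kaplan-Meier curve equals the hand product-limit", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  # risk sets 3, 2, 1; events at t=1 and t=3
  expect_equal(km$time, c(1, 2, 3))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored -> flat at 1
  km2 <- km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(km2$surv == 1))
  # no censoring -> complement of the ECDF of event times
  tm <- c(2, 5, 5, 9, 11)
  km3 <- km_estimate(tm, rep(TRUE, 5))
  ecdf_surv <- 1 - ecdf(tm)(km3$time)
  expect_equal(km3$surv, ecdf_surv)
  # monotone, S(0) = 1 by construction, negative times rejected
  set.seed(3)
  km4 <- km_estimate(rexp(50), runif(50) < 0.5)
  expect_true(all(diff(c(1, km4$surv)) <= 0))
  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)), "negative")
})

test_that("log-rank test matches the hand O-E table and is symmetric", {
  # A: events at 1,2,3; B: events at 4,5,6
  time <- 1:6
  event <- rep(TRUE, 6)
  group <- rep(c("A", "B"), each = 3)
  # hand tabulation: at each event time t, O_A - E_A with E from risk sets
  # t=1: O=1 E=3/6; t=2: O=1 E=2/5; t=3: O=1 E=1/4; t=4,5,6: O=0
  o_minus_e <- (1 - 3 / 6) + (1 - 2 / 5) + (1 - 1 / 4) + 0 + 0 + 0
  # variance at t: n1 n2 d (n - d) / (n^2 (n - 1)) with d = 1; after t=3
  # group A has no one at risk, so those terms vanish
  v <- (3 * 3 * 1 * 5) / (6^2 * 5) + (2 * 3 * 1 * 4) / (5^2 * 4) +
    (1 * 3 * 1 * 3) / (4^2 * 3)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chi_square, o_minus_e^2 / v, tolerance = 1e-9)
  # statistic is invariant to label swap
  lr2 <- logrank_test(time, event, rev(group))
  expect_equal(lr$chi_square, lr2$chi_square)
  # identical groups -> chi-square 0, p 1
  lr0 <- logrank_test(rep(time, 2), rep(event, 2),
                      rep(c("A", "B"), each = 6))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(time, rep(FALSE, 6), group), "no events")
})

test_that("Cox coefficient matches brute-force partial likelihood", {
  # 10-sample fixture, single binary covariate, no ties
  time <- c(3.1, 5.4, 7.2, 8.8, 10.1, 2.2, 4.4, 6.6, 9.9, 12.3)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  x <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  fit <- cox_fit(data.frame(time = time, event = event, marker_level = x),
                 covariates = "marker_level")
  expect_equal(fit$coef[1], cox_brute_coef(time, event, x),
               tolerance = 1e-4)
  expect_true(fit$converged[1])
  expect_equal(fit$hr[1], exp(fit$coef[1]))
})

test_that("Cox recovery improves with sample size and flags degeneracies", {
  for (n in c(200, 2000)) {
    sv <- simulate_survival(sprintf("s%04d", 1:n),
                            rep(c(TRUE, FALSE), n / 2),
                            hazard_ratio = 3, censor_frac = 0.3, seed = 42)
    cf <- cox_fit(data.frame(time = sv$time, event = sv$event,
                             marker_level = sv$marker_level),
                  covariates = "marker_level")
    expect_lt(abs(cf$coef[1] - log(3)), if (n == 200) 0.25 else 0.1)
  }
  # constant covariate is flagged non-identifiable
  cf <- cox_fit(data.frame(time = c(1, 2, 3, 4), event = TRUE,
                           marker_level = c(1, 0, 1, 0), breslow_mm = 2),
                covariates = c("marker_level", "breslow_mm"))
  expect_false(cf$converged[cf$covariate == "breslow_mm"])
  expect_true(is.na(cf$hr[cf$covariate == "breslow_mm"]))
  # perfect separation (marker-high all die first) is flagged, not reported
  sep <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                    event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                    marker_level = c(1, 1, 1, 0, 0, 0))
  cf2 <- cox_fit(sep, covariates = "marker_level")
  expect_false(cf2$converged[1])
  expect_true(is.na(cf2$coef[1]))
})

test_that("multivariate Cox keeps the marker effect alongside covariates", {
  sv <- simulate_survival(sprintf("s%04d", 1:400), rep(c(TRUE, FALSE), 200),
                          hazard_ratio = 3, censor_frac = 0.2, seed = 10)
  cf <- cox_fit(data.frame(time = sv$time, event = sv$event,
                           marker_level = sv$marker_level,
                           breslow_mm = sv$breslow_mm,
                           ulceration = sv$ulceration))
  expect_equal(nrow(cf), 3)
  expect_true(all(cf$converged))
  expect_lt(abs(cf$coef[cf$covariate == "marker_level"] - log(3)), 0.4)
  expect_lt(cf$p[cf$covariate == "marker_level"], 0.05)
})

test_that("dichotomization rules and tie handling follow the conventions", {
  expect_equal(as.vector(dichotomize(1:10)),
               rep(c("low", "high"), each = 5))
  d <- dichotomize(1:8, rule = "q3")
  expect_equal(attr(d, "cutoff"), 6.25)  # type-7 linear interpolation
  expect_equal(which(d == "high"), c(7L, 8L))
  d1 <- dichotomize(1:8, rule = "q1")
  expect_equal(attr(d1, "cutoff"), 2.75)
  expect_equal(sum(d1 == "low"), 2)
  expect_true(all(dichotomize(c(3, 7, 9), rule = "fixed:0") == "high"))
  # ties at the cutoff go low (strict >)
  expect_equal(unname(dichotomize(c(1, 2, 2, 3), rule = "median"))[2:3],
               c("low", "low"))
  expect_error(dichotomize(rep(4, 5)), "identical")
  expect_error(dichotomize(c(1, NA)), "missing")
})
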