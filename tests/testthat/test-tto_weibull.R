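mk_tto_cohort <- function(start, event, event_imprecise = FALSE) {
  mk_reports(
    demo = data.frame(primaryid = "1", event_dt = as.Date(event),
                      event_imprecise = event_imprecise),
    drugs = data.frame(primaryid = "1", drug_name = "ABECMA", role = "PS",
                       start_dt = as.Date(start), start_imprecise = FALSE),
    reactions = data.frame(primaryid = "1", pt = "Pyrexia")
  )
}

q_ide <- drug_query("ide-cel", "abecma")

test_that("time to onset is event date minus earliest matching start, with validity codes", {
  expect_equal(compute_tto(mk_tto_cohort("2023-01-01", "2023-01-03"), q_ide)$tto_days, 2L)
  same_day <- compute_tto(mk_tto_cohort("2023-01-01", "2023-01-01"), q_ide)
  expect_equal(same_day$tto_days, 0L)
  expect_equal(same_day$validity, "valid")
  neg <- compute_tto(mk_tto_cohort("2023-01-10", "2023-01-05"), q_ide)
  expect_equal(neg$validity, "negative")
  expect_true(is.na(neg$tto_days))
  expect_equal(compute_tto(mk_tto_cohort(NA, "2023-01-05"), q_ide)$validity, "missing_start")
  expect_equal(compute_tto(mk_tto_cohort("2023-01-01", NA), q_ide)$validity, "missing_event")
})

test_that("imprecise dates are excluded by default but usable on request", {
  co <- mk_tto_cohort("2023-01-01", "2023-06-15", event_imprecise = TRUE)
  expect_equal(compute_tto(co, q_ide)$validity, "imprecise_date")
  inc <- compute_tto(co, q_ide, include_imprecise = TRUE)
  expect_equal(inc$validity, "valid")
  expect_equal(inc$tto_days, 165L)
})

test_that("the earliest matching start wins when several drug entries match", {
  co <- mk_reports(
    demo = data.frame(primaryid = "1", event_dt = as.Date("2023-03-01"),
                      event_imprecise = FALSE),
    drugs = data.frame(primaryid = "1", drug_seq = c("1", "2", "3"),
                       drug_name = c("ABECMA", "ABECMA", "OTHER"),
                       role = c("PS", "SS", "PS"),
                       start_dt = as.Date(c("2023-02-01", "2023-01-01", "2022-01-01")),
                       start_imprecise = FALSE),
    reactions = data.frame(primaryid = "1", pt = "Pyrexia")
  )
  tt <- compute_tto(co, q_ide)
  expect_equal(tt$tto_days, as.integer(as.Date("2023-03-01") - as.Date("2023-01-01")))
})

test_that("onset-window summaries are hand-checkable and empty input is explicit", {
  s <- onset_window_summary(c(0, 0, 2, 10, 40))
  expect_equal(s$median, 2)
  expect_equal(s$prop_within_window, 0.8)
  expect_equal(s$prop_day0, 0.4)
  expect_equal(onset_window_summary(c(1, 5, 30))$prop_within_window, 1.0)
  # midpoint-of-middle-two convention for even n
  expect_equal(onset_window_summary(c(1, 2, 10, 20))$median, 6)
  empty <- onset_window_summary(numeric(0))
  expect_equal(empty$n_valid, 0L)
  expect_true(is.na(empty$median))
})

test_that("the Weibull log-likelihood at shape 1 equals the exponential log-likelihood", {
  set.seed(4)
  x <- rexp(500, rate = 1 / 10)
  lam <- 12.3
  expect_equal(-faersignal:::weibull_negloglik(c(0, log(lam)), x),
               sum(dexp(x, rate = 1 / lam, log = TRUE)))
})

test_that("exponential data yield a shape CI containing 1", {
  set.seed(7)
  x <- rexp(10000, rate = 1 / 10)
  fit <- weibull_mle(x)
  expect_true(fit$converged)
  expect_true(fit$beta_ci[1] < 1 && 1 < fit$beta_ci[2])
  expect_equal(fit$failure_type, "random")
})

test_that("MLE recovers the generating shape on a large early-failure sample", {
  set.seed(21)
  x <- rweibull(10000, shape = 0.43, scale = 12.67)
  fit <- weibull_mle(x, zero_handling = "drop")
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - 0.43), 0.02)
  expect_lt(abs(fit$alpha - 12.67) / 12.67, 0.05)
  expect_equal(fit$failure_type, "early")
  expect_true(fit$alpha_ci[1] <= fit$alpha && fit$alpha <= fit$alpha_ci[2])
})

test_that("the fit agrees with an independent Weibull MLE implementation", {
  set.seed(33)
  x <- rweibull(800, shape = 0.7, scale = 20)
  fit <- weibull_mle(x, zero_handling = "drop")
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(fit$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
  expect_equal(fit$log_likelihood, ref$loglik, tolerance = 1e-6)
  # our optimum should be at least as good as the reference's
  expect_gte(fit$log_likelihood, ref$loglik - 1e-6)
})

test_that("rescaling time rescales alpha and leaves beta unchanged", {
  set.seed(12)
  x <- rweibull(600, shape = 1.4, scale = 30)
  f1 <- weibull_mle(x, zero_handling = "drop")
  f2 <- weibull_mle(7 * x, zero_handling = "drop")
  expect_equal(f2$beta, f1$beta, tolerance = 1e-5)
  expect_equal(f2$alpha, 7 * f1$alpha, tolerance = 1e-5)
})

test_that("zero handling: shift keeps day-0 mass, drop removes it, offset shifts everything", {
  x <- c(0, 0, 0, 1, 2, 3, 5, 8, 13, 21, 34, 55)
  expect_equal(weibull_mle(x, "shift")$n_used, 12L)
  expect_equal(weibull_mle(x, "drop")$n_used, 9L)
  f_off <- weibull_mle(x, "offset")
  expect_equal(f_off$n_used, 12L)
})

test_that("degenerate inputs give explicit failure results, not errors", {
  few <- weibull_mle(c(1, 2, 3))
  expect_false(few$converged)
  expect_match(few$reason, "fewer than")
  same <- weibull_mle(rep(5, 50))
  expect_false(same$converged)
  expect_match(same$reason, "degenerate")
  expect_equal(classify_failure_type(same), "indeterminate")
})

test_that("failure type is a total deterministic function of the shape CI", {
  mk <- function(lo, hi) list(converged = TRUE, beta_ci = c(lo, hi))
  expect_equal(classify_failure_type(mk(0.40, 0.46)), "early")
  expect_equal(classify_failure_type(mk(0.9, 1.1)), "random")
  expect_equal(classify_failure_type(mk(1.2, 1.5)), "wear_out")
  expect_equal(classify_failure_type(mk(0.99999, 1.00001)), "random")
})

test_that("the 95% Wald CI covers the true shape in at least 90% of replicates", {
  shapes <- c(0.4, 1.0, 2.0)
  covered <- 0L; total <- 0L
  for (i in seq_len(201)) {
    sh <- shapes[1 + (i - 1) %% 3]
    set.seed(5000 + i)
    x <- rweibull(500, shape = sh, scale = 15)
    fit <- weibull_mle(x, zero_handling = "drop")
    if (!fit$converged) next
    total <- total + 1L
    if (fit$beta_ci[1] <= sh && sh <= fit$beta_ci[2]) covered <- covered + 1L
  }
  expect_gte(total, 195L)
  expect_gte(covered / total, 0.90)
})
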