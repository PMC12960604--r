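test_that("pseudo_ipd validates its inputs", {
  expect_error(pseudo_ipd(c(1, -2), c(1, 0)), "positive")
  expect_error(pseudo_ipd(c(1, 2), c(1)), "equal length")
  expect_error(pseudo_ipd(c(1, 2), c(1, 2)), "0 or 1")
  d <- pseudo_ipd(c(1, 2), c(1, 0))
  expect_s3_class(d, "pseudo_ipd")
})

test_that("exponential MLE on uncensored data is exactly 1/mean", {
  set.seed(11)
  t <- rexp(80, rate = 0.04)
  fit <- fit_parametric(pseudo_ipd(t, rep(1, 80)), "exponential")
  expect_identical(unname(fit$params["rate"]), 1 / mean(t))
  expect_equal(fit$mean_duration, mean(t))
  # closed-form log-likelihood agrees with an independent evaluation
  ll <- sum(dexp(t, rate = 1 / mean(t), log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-12)
})

test_that("censored exponential MLE is events over exposure", {
  set.seed(12)
  t <- rexp(200, rate = 0.03)
  cens <- pmin(t, 30)
  ev <- as.integer(t < 30)
  fit <- fit_parametric(pseudo_ipd(cens, ev), "exponential")
  expect_equal(unname(fit$params["rate"]), sum(ev) / sum(cens))
})

test_that("lognormal parameters are recovered within 3 SE under censoring", {
  ipd <- gen_pseudo_ipd("lognormal", c(meanlog = 3.6, sdlog = 0.6),
                        n = 500, censor_time = 60.6, seed = 101)
  expect_gt(mean(1 - ipd$event), 0.10)  # meaningful censoring
  fit <- fit_parametric(ipd, "lognormal")
  # standard errors from the observed information (independent refit)
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                               data = as.data.frame(ipd), dist = "lnorm")
  se <- ref$res[, "se"]
  expect_lt(abs(fit$params[["meanlog"]] - 3.6), 3 * se[["meanlog"]])
  expect_lt(abs(fit$params[["sdlog"]] - 0.6), 3 * se[["sdlog"]])
  # fitted likelihood dominates the generating parameters' likelihood
  ll_true <- sum(ifelse(ipd$event == 1,
                        dlnorm(ipd$time, 3.6, 0.6, log = TRUE),
                        plnorm(ipd$time, 3.6, 0.6, lower.tail = FALSE,
                               log.p = TRUE)))
  expect_gte(fit$loglik, ll_true - 1e-6)
})

test_that("closed-form means match numerical integration of survival", {
  surv_mean <- function(S) integrate(S, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(exp(3.6 + 0.6^2 / 2),
               surv_mean(function(t) plnorm(t, 3.6, 0.6,
                                            lower.tail = FALSE)),
               tolerance = 1e-6)
  set.seed(13)
  ipd <- gen_pseudo_ipd("weibull", c(shape = 1.4, scale = 50), n = 300,
                        seed = 14)
  fit <- fit_parametric(ipd, "weibull")
  sh <- fit$params[["shape"]]; sc <- fit$params[["scale"]]
  expect_equal(fit$mean_duration,
               surv_mean(function(t) pweibull(t, sh, sc,
                                              lower.tail = FALSE)),
               tolerance = 1e-6)
  ipd2 <- gen_pseudo_ipd("loglogistic", c(shape = 2.5, scale = 40),
                         n = 300, seed = 15)
  fit2 <- fit_parametric(ipd2, "loglogistic")
  b <- fit2$params[["shape"]]; a <- fit2$params[["scale"]]
  expect_equal(fit2$mean_duration,
               surv_mean(function(t) flexsurv::pllogis(t, shape = b,
                                                       scale = a,
                                                       lower.tail = FALSE)),
               tolerance = 1e-5)
  expect_true(is.finite(fit2$mean_duration))
})

test_that("AIC and BIC identities hold and match flexsurv", {
  ipd <- gen_pseudo_ipd("lognormal", c(meanlog = 3.4, sdlog = 0.8),
                        n = 120, censor_time = 80, seed = 21)
  fit <- fit_parametric(ipd, "lognormal")
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_equal(fit$bic, 2 * log(120) - 2 * fit$loglik)
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                               data = as.data.frame(ipd), dist = "lnorm")
  expect_equal(fit$aic, ref$AIC, tolerance = 1e-8)
})

test_that("fit_parametric guards degenerate data", {
  expect_error(fit_parametric(pseudo_ipd(1:5, rep(0, 5)), "exponential"),
               "censored")
  expect_warning(fit_parametric(pseudo_ipd(1:5, rep(1, 5)), "exponential"),
                 "events")
})

test_that("select_best minimizes the criterion with deterministic ties", {
  ipd <- gen_pseudo_ipd("lognormal", c(meanlog = 3.6, sdlog = 0.6),
                        n = 500, censor_time = 78, seed = 31)
  fits <- lapply(c("exponential", "weibull", "lognormal", "loglogistic"),
                 function(f) fit_parametric(ipd, f))
  expect_identical(select_best(fits, "aic")$family, "lognormal")
  expect_identical(select_best(fits, "bic")$family, "lognormal")
  # single candidate returns itself
  expect_identical(select_best(fits[2], "aic")$family, "weibull")
  # equal criterion: fewer parameters win, then family order
  f1 <- make_fit("weibull", c(shape = 1, scale = 10), -50, 100)
  f2 <- make_fit("exponential", c(rate = 0.1), -51, 100)  # same AIC = 104
  expect_identical(select_best(list(f1, f2), "aic")$family, "exponential")
  f3 <- make_fit("lognormal", c(meanlog = 2, sdlog = 1), -50, 100)
  expect_identical(select_best(list(f3, f1), "aic")$family, "weibull")
  # fits on different data are rejected
  f4 <- make_fit("weibull", c(shape = 1, scale = 10), -50, 90)
  expect_error(select_best(list(f1, f4)), "different data")
})

test_that("exponential is preferred on exponential data across replicates", {
  wins <- vapply(1:20, function(s) {
    ipd <- gen_pseudo_ipd("exponential", c(rate = 1 / 40), n = 150,
                          censor_time = 120, seed = 4000 + s)
    fits <- list(fit_parametric(ipd, "exponential"),
                 fit_parametric(ipd, "weibull"))
    select_best(fits, "aic")$family == "exponential"
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("per-cycle exit probability inverts the sojourn mean", {
  expect_equal(per_cycle_exit_prob(42.66), 0.0231685528791,
               tolerance = 1e-10)
  expect_equal(per_cycle_exit_prob(46.72), 0.0211766672592,
               tolerance = 1e-10)
  expect_equal(per_cycle_exit_prob(Inf), 0)
  expect_error(per_cycle_exit_prob(0), "> 0")
  expect_error(per_cycle_exit_prob(-3), "> 0")
  # geometric sojourn exceeds the target by the half-cycle gap
  # 1/2 + 1/(12 D) + O(D^-3)
  for (D in c(5, 8, 10, 20, 42.66, 100, 200)) {
    gap <- 1 / per_cycle_exit_prob(D) - D
    expect_lt(abs(gap - 0.5 - 1 / (12 * D)), 1e-3)
  }
})

test_that("pseudo-IPD CSV round-trips and fit reports tabulate", {
  ipd <- gen_pseudo_ipd("weibull", c(shape = 1.2, scale = 45), n = 50,
                        censor_time = 70, seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pseudo_ipd(ipd, path)
  back <- read_pseudo_ipd(path)
  expect_equal(back$time, ipd$time)
  expect_equal(back$event, ipd$event)
  fits <- list(fit_parametric(ipd, "exponential"),
               fit_parametric(ipd, "weibull"))
  rep <- fit_report(fits)
  expect_equal(nrow(rep), 2)
  expect_true(all(c("family", "aic", "bic", "mean_duration") %in%
                  names(rep)))
})
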