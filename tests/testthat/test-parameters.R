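test_that("param_value enforces ordering and family supports", {
  expect_error(param_value(1.2, 0.9, 1.3, "beta", name = "p"),
               "beta-family values must lie in \\[0, 1\\]")
  expect_error(param_value(0.5, 0.6, 0.7, "beta"), "low <= base <= high")
  expect_error(param_value(-1, -2, 3, "gamma"), ">= 0")
  expect_error(param_value(0, 0, 1, "lognormal"), "> 0")
  p <- param_value(0.577, 0.4616, 0.6924, "beta")
  expect_s3_class(p, "param_value")
  expect_equal(p$base, 0.577)
})

test_that("the shipped configuration encodes the published input tables", {
  cfg <- cfg_default
  expect_equal(cfg$efficacy$p_response_eltrombopag$base, 0.577)
  expect_equal(cfg$efficacy$or_elt_vs_het$base, 0.74)
  expect_equal(cfg$efficacy$or_elt_vs_ava$base, 0.56)
  expect_equal(cfg$efficacy$mean_duration_elt$base, 42.66)
  expect_equal(cfg$efficacy$mean_duration_subsequent$base, 46.72)
  expect_equal(cfg$mortality$smr_bsc$base, 4.2)
  expect_equal(cfg$costs$drug_eltrombopag$base, 6365.52)
  expect_equal(cfg$costs$drug_hetrombopag$base, 6527.92)
  expect_equal(cfg$costs$drug_avatrombopag$base, 11088.00)
  expect_equal(cfg$costs$terminal$base, 37442.00)
  expect_equal(cfg$utilities$u_response_no_bleed$base, 0.863)
  expect_equal(cfg$settings$wtp, 287391)
  expect_equal(cfg$settings$annual_discount, 0.05)
  expect_equal(cfg$settings$cycle_days, 28)
})

test_that("schema and invariant violations name the offending key", {
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg_default, path)
  raw <- yaml::read_yaml(path)
  raw$costs$rituximab <- NULL
  yaml::write_yaml(raw, path)
  expect_error(load_config(path), "costs\\.rituximab")

  save_config(cfg_default, path)
  raw <- yaml::read_yaml(path)
  raw$efficacy$p_response_eltrombopag$base <- 1.2
  raw$efficacy$p_response_eltrombopag$high <- 1.3
  yaml::write_yaml(raw, path)
  expect_error(load_config(path),
               "efficacy\\.p_response_eltrombopag")
  expect_error(load_config(tempfile()), "does not exist")
})

test_that("save/load round-trip reproduces the configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg_default, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2, cfg_default, tolerance = 1e-12)
})

test_that("moment matching reproduces hand-solved beta parameters", {
  # independent method-of-moments arithmetic: sd = range / 3.92,
  # K = m(1-m)/v - 1, alpha = mK, beta = (1-m)K
  m <- 0.577
  v <- ((0.69244 - 0.46156) / 3.92)^2
  k <- m * (1 - m) / v - 1
  d <- build_distribution(param_value(0.577, 0.46156, 0.69244, "beta"))
  expect_equal(unname(d$pars["alpha"]), m * k, tolerance = 1e-10)
  expect_equal(unname(d$pars["beta"]), (1 - m) * k, tolerance = 1e-10)
  expect_equal(round(unname(d$pars["alpha"]), 1), 40.0)
  expect_equal(round(unname(d$pars["beta"]), 1), 29.3)
})

test_that("analytic means of built distributions equal the base value", {
  for (name in param_table(cfg_default)$name) {
    p <- itpcea:::get_param(cfg_default, name)
    d <- build_distribution(p)
    analytic <- switch(d$family,
      fixed = d$pars[["value"]],
      beta = d$pars[["alpha"]] / (d$pars[["alpha"]] + d$pars[["beta"]]),
      gamma = d$pars[["shape"]] * d$pars[["scale"]],
      lognormal = exp(d$pars[["meanlog"]] + d$pars[["sdlog"]]^2 / 2))
    expect_equal(analytic, p$base, tolerance = 1e-9, label = name)
  }
})

test_that("draws are reproducible, support-respecting, and mean-faithful", {
  d <- build_distribution(param_value(0.74, 0.38, 1.43, "lognormal"))
  expect_identical(draw(d, 100, seed = 1), draw(d, 100, seed = 1))
  x <- draw(d, 1e5, seed = 2)
  expect_true(all(x > 0))
  # distribution mean is the base-case odds ratio
  expect_equal(mean(x), 0.74, tolerance = 3 * d$sd / sqrt(1e5) / 0.74 + 0.01)

  g <- build_distribution(param_value(500, 400, 600, "gamma"))
  xg <- draw(g, 1e5, seed = 3)
  expect_true(all(xg >= 0))
  expect_lt(abs(mean(xg) - 500), 3 * g$sd / sqrt(1e5) + 1)

  b <- build_distribution(param_value(0.0108, 0.0086, 0.0130, "beta"))
  xb <- draw(b, 1e4, seed = 4)
  expect_true(all(xb >= 0 & xb <= 1))
})

test_that("infeasible beta moments error in strict mode, truncate otherwise", {
  p <- param_value(0.5, 0, 1, "beta")  # sd 0.255, var > feasible at edges?
  # force infeasibility with an extreme range around a small mean
  p2 <- param_value(0.05, 0, 1, "beta")
  expect_error(build_distribution(p2, strict = TRUE), "infeasible")
  expect_warning(d <- build_distribution(p2), "truncated")
  expect_true(all(d$pars > 0))
  expect_error(build_distribution(param_value(0.5, 0.5, 0.5, "beta"),
                                  strict = TRUE), NA)
  expect_error(
    build_distribution(param_value(0.7, 0.1, 0.2, "gamma")),
    "low <= base|inside")
})

test_that("parameter table flattens every group with bounds and family", {
  pt <- param_table(cfg_default)
  expect_true(all(c("name", "base", "low", "high", "family") %in%
                  names(pt)))
  expect_true(all(pt$low <= pt$base & pt$base <= pt$high))
  expect_true("costs.rhtpo" %in% pt$name)
  expect_true("utilities.u_ich" %in% pt$name)
  path <- withr::local_tempfile(fileext = ".csv")
  write_param_table(cfg_default, path)
  expect_equal(read.csv(path)$base, pt$base)
})
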