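# Shared fixtures, built in code.

# The shipped configuration, loaded once per test run.
cfg_default <- default_config()

# A constant-mortality life table over a narrow age range, for
# hand-checkable engine tests.
flat_life_table <- function(q, ages = 0:110) data.frame(age = ages, q = q)

# Shrink every uncertain parameter's bounds to a relative half-width of
# eps around its base value (eps = 0 degenerates the uncertainty).
shrink_uncertainty <- function(cfg, eps) {
  for (name in param_table(cfg)$name) {
    p <- itpcea:::get_param(cfg, name)
    if (p$dist == "fixed") next
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    p$low <- p$base * (1 - eps)
    p$high <- p$base * (1 + eps)
    cfg[[parts[1]]][[parts[2]]] <- p
  }
  cfg
}

# Set a parameter's base value without touching its bounds.
with_param <- function(cfg, name, value) {
  itpcea:::set_param(cfg, name, value, clip = FALSE)
}

# Config whose horizon is exactly `n_cycles` cycles under constant
# annual mortality q, for spreadsheet-style unrolling.
short_horizon_config <- function(n_cycles, q = 0.05, start_age = 60,
                                 discount = 0.05) {
  cfg <- cfg_default
  cyc_frac <- 28 / 365.25
  cfg$settings$start_age <- start_age
  cfg$settings$max_age <- start_age + (n_cycles - 0.5) * cyc_frac
  cfg$settings$annual_discount <- discount
  cfg$mortality$life_table <- flat_life_table(q)
  cfg$mortality$life_table_source <- "inline"
  itpcea:::validate_config(cfg)
}

# Independent life-table expectancy oracle: person-years from `from`
# truncated at `to`, deaths contributing half a year.
expectancy_oracle <- function(lt, from, to) {
  q <- lt$q[lt$age >= from & lt$age < to]
  l <- cumprod(c(1, 1 - q))[seq_along(q)]
  sum(l * (1 - q / 2))
}

# Set every utility parameter to `value`.
with_all_utilities <- function(cfg, value) {
  for (key in itpcea:::CONFIG_PARAMS$utilities) {
    cfg$utilities[[key]] <- param_value(value, dist = "fixed")
  }
  cfg
}

# Zero every cost parameter except those named in `keep`.
with_only_costs <- function(cfg, keep = character(0)) {
  for (key in itpcea:::CONFIG_PARAMS$costs) {
    if (!key %in% keep) cfg$costs[[key]] <- param_value(0, dist = "fixed")
  }
  cfg
}

# Independent spreadsheet-style unrolling of a 3-cycle eltrombopag run
# under constant annual mortality q: plain arithmetic over the published
# inputs, no engine code.
unroll_oracle_3cycle <- function(q = 0.05, discount = 0.05) {
  f <- 28 / 365.25
  m <- 1 - exp(log(1 - q) * f)
  mb <- 1 - exp(log(1 - q) * 4.2 * f)
  p <- 0.577
  pR <- 1 - exp(-1 / 42.66)
  pS <- 1 - exp(-1 / 46.72)
  psub <- 0.792
  cR <- 6365.52 + 41.04 + 463 + 0.0108 * 132.62
  cS <- 4120 + 14026.21 + 1094.40 + 463 + 0.0108 * 132.62
  cB <- 463 + 0.0381 * 132.62 +
    0.0015 * (21017.80 + 8398.50 + 8398.50) / 3
  uR <- (0.9892 * 0.863 + 0.0108 * 0.734) * f
  uB <- (0.9604 * 0.841 + 0.0381 * 0.732 +
         0.0015 * (0.038 + 0.54 + 0.54) / 3) * f
  term <- 37442
  # states: response, sub-pending, sub-responding, bsc, death
  o0 <- c(1, 0, 0, 0, 0)
  o1 <- c((1 - m) * p, (1 - m) * (1 - p), 0, 0, m)
  o2 <- c(o1[1] * (1 - m) * (1 - pR),
          o1[1] * (1 - m) * pR,
          o1[2] * (1 - m) * psub,
          o1[2] * (1 - m) * (1 - psub),
          o1[5] + (o1[1] + o1[2]) * m)
  o3 <- c(o2[1] * (1 - m) * (1 - pR),
          o2[1] * (1 - m) * pR,
          o2[2] * (1 - m) * psub + o2[3] * (1 - m) * (1 - pS),
          o2[4] * (1 - mb) + o2[2] * (1 - m) * (1 - psub) +
            o2[3] * (1 - m) * pS,
          o2[5] + (o2[1] + o2[2] + o2[3]) * m + o2[4] * mb)
  costs <- c(cR, cS, cS, cB, 0)
  utils <- c(uR, uR, uR, uB, 0)
  rows <- list(o0, o1, o2, o3)
  total_cost <- total_qaly <- 0
  for (t in 1:3) {
    mid <- (rows[[t]] + rows[[t + 1]]) / 2
    df <- (1 + discount)^(-t * f)
    inc_death <- rows[[t + 1]][5] - rows[[t]][5]
    total_cost <- total_cost + df * (sum(mid * costs) + inc_death * term)
    total_qaly <- total_qaly + df * sum(mid * utils)
  }
  list(cost = total_cost, qaly = total_qaly, rows = rows)
}

make_fit <- function(family, params, loglik, n, n_events = n) {
  k <- length(params)
  structure(list(family = family, params = params, loglik = loglik,
                 aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik,
                 mean_duration = 10, n = n, n_events = n_events),
            class = "parametric_fit")
}
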