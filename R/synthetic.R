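#' Specification of the synthetic life-table generator
#'
#' The Chinese national life table used by the original analysis is not
#' publicly printed, so the package ships a Gompertz-Makeham stand-in:
#' the annual hazard at age `x` is `a + c * exp(b * x)`, giving an annual
#' death probability `q(x) = 1 - exp(-(a + c * exp(b * x)))`. The default
#' constants are tuned once so that life expectancy at birth is about 78
#' years, the approximate contemporary Chinese level. Users with the real
#' table can supply it through the configuration instead.
#'
#' @param makeham_a Age-independent hazard component (per year).
#' @param gompertz_b Exponential ageing rate (per year).
#' @param gompertz_c Gompertz hazard scale (per year).
#' @param age_range Integer vector `c(min, max)` of ages to tabulate.
#' @return An object of class `life_table_spec`.
#' @export
life_table_spec <- function(makeham_a = 2e-4, gompertz_b = 0.1,
                            gompertz_c = 2.276e-5, age_range = c(0L, 110L)) {
  stopifnot(makeham_a >= 0, gompertz_b >= 0, gompertz_c >= 0,
            length(age_range) == 2L, age_range[1] < age_range[2])
  structure(list(makeham_a = makeham_a, gompertz_b = gompertz_b,
                 gompertz_c = gompertz_c,
                 age_range = as.integer(age_range)),
            class = "life_table_spec")
}

#' Generate the synthetic age-indexed life table
#'
#' @param spec A [life_table_spec()].
#' @return A data frame with columns `age` (years) and `q` (annual death
#'   probability).
#' @examples
#' lt <- gen_life_table()
#' head(lt)
#' @export
gen_life_table <- function(spec = life_table_spec()) {
  stopifnot(inherits(spec, "life_table_spec"))
  ages <- seq(spec$age_range[1], spec$age_range[2])
  haz <- spec$makeham_a + spec$gompertz_c * exp(spec$gompertz_b * ages)
  q <- 1 - exp(-haz)
  if (any(q >= 1 - 1e-12)) {
    stop("gen_life_table: parameters yield q >= 1 before the maximum age",
         call. = FALSE)
  }
  data.frame(age = ages, q = q)
}

#' Period life expectancy from a life table
#'
#' Standard abridged calculation with deaths spread uniformly within the
#' year of death (each death contributes half a person-year), truncated
#' at the last tabulated age.
#'
#' @param lt Life table data frame (`age`, `q`).
#' @param age Age at which remaining expectancy is evaluated.
#' @return Remaining life expectancy in years.
#' @export
life_expectancy <- function(lt, age = 0) {
  idx <- which(lt$age >= age)
  if (length(idx) == 0) stop("age beyond life table", call. = FALSE)
  q <- lt$q[idx]
  l <- cumprod(c(1, 1 - q))[seq_along(q)]
  sum(l * (1 - q / 2))
}

#' Generate right-censored pseudo individual-patient data
#'
#' Emulates reconstructed time-to-loss-of-response data: event times are
#' drawn from a parametric family and administratively censored at a
#' fixed follow-up time, as in a long-term extension study.
#'
#' @param family `"exponential"`, `"weibull"`, `"lognormal"`, or
#'   `"loglogistic"`.
#' @param params Named family parameters: `rate`; `shape`/`scale`;
#'   `meanlog`/`sdlog`; `shape`/`scale` respectively.
#' @param n Number of patients.
#' @param censor_time Administrative censoring time (cycles); `Inf`
#'   disables censoring.
#' @param seed Integer seed for reproducibility.
#' @return A [pseudo_ipd()] object; the generating family, parameters,
#'   censoring time, and seed are recorded as attributes.
#' @examples
#' ipd <- gen_pseudo_ipd("lognormal", c(meanlog = 3.43, sdlog = 0.8),
#'                       n = 200, censor_time = 78, seed = 1)
#' @export
gen_pseudo_ipd <- function(family = c("exponential", "weibull", "lognormal",
                                      "loglogistic"),
                           params, n, censor_time = Inf, seed = NULL) {
  family <- match.arg(family)
  stopifnot(n >= 1)
  if (censor_time <= 0) {
    stop("gen_pseudo_ipd: censor_time must be > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  t <- switch(family,
    exponential = stats::rexp(n, rate = params[["rate"]]),
    weibull = stats::rweibull(n, shape = params[["shape"]],
                              scale = params[["scale"]]),
    lognormal = rlnorm(n, params[["meanlog"]], params[["sdlog"]]),
    loglogistic = flexsurv::rllogis(n, shape = params[["shape"]],
                                    scale = params[["scale"]]))
  out <- pseudo_ipd(time = pmin(t, censor_time),
                    event = as.integer(t < censor_time))
  attr(out, "family") <- family
  attr(out, "params") <- params
  attr(out, "censor_time") <- censor_time
  attr(out, "seed") <- seed
  out
}

#' Randomly perturb a configuration (property-test support)
#'
#' Multiplies every uncertain parameter's base value (and its bounds) by
#' an independent factor `1 + u`, `u ~ Uniform(-rel_noise, rel_noise)`,
#' clipping back into each family's hard support so the perturbed
#' configuration always validates.
#'
#' @param cfg An `itp_config`.
#' @param rel_noise Relative noise amplitude in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A perturbed, validated `itp_config`.
#' @export
perturb_config <- function(cfg, rel_noise, seed = NULL) {
  stopifnot(inherits(cfg, "itp_config"), rel_noise >= 0, rel_noise < 0.5)
  if (!is.null(seed)) set.seed(seed)
  if (rel_noise == 0) return(cfg)
  pt <- param_table(cfg)
  for (i in seq_len(nrow(pt))) {
    name <- pt$name[i]
    if (name == "efficacy.time_to_response") next  # structural constant
    p <- get_param(cfg, name)
    f <- 1 + runif(1, -rel_noise, rel_noise)
    vals <- sort(c(p$low, p$base, p$high) * f)
    if (p$dist == "beta") vals <- pmin(pmax(vals, 0), 1)
    if (p$dist == "gamma") vals <- pmax(vals, 0)
    if (p$dist == "lognormal") vals <- pmax(vals, .Machine$double.eps)
    # keep model-level invariants intact
    if (name %in% c("efficacy.p_response_eltrombopag",
                    "efficacy.p_response_subsequent")) {
      vals <- pmin(pmax(vals, 1e-6), 1 - 1e-6)
    }
    if (name %in% c("efficacy.mean_duration_elt",
                    "efficacy.mean_duration_subsequent")) {
      vals <- pmax(vals, 1 + 1e-6)
    }
    if (name == "mortality.smr_bsc") vals <- pmax(vals, 1)
    parts <- strsplit(name, ".", fixed = TRUE)[[1]]
    p$low <- vals[1]; p$base <- vals[2]; p$high <- vals[3]
    cfg[[parts[1]]][[parts[2]]] <- p
  }
  validate_config(cfg)
}
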