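#' Model parameter with uncertainty bounds
#'
#' A single model input as printed in the input tables: a base-case value,
#' lower and upper values (interpreted as a 95% interval when a sampling
#' distribution is built), and the distribution family used for
#' probabilistic sensitivity analysis.
#'
#' @param base Base-case value.
#' @param low,high Lower and upper values. Default to `base` (no
#'   uncertainty).
#' @param dist Distribution family: `"beta"` for probabilities and
#'   utilities, `"gamma"` for costs, `"lognormal"` for relative effect
#'   measures and durations, `"fixed"` for structural constants.
#' @param name Optional parameter name used in error messages.
#' @return An object of class `param_value`.
#' @examples
#' param_value(0.577, 0.4616, 0.6924, "beta")
#' @export
param_value <- function(base, low = base, high = base,
                        dist = c("fixed", "beta", "gamma", "lognormal"),
                        name = "parameter") {
  dist <- match.arg(dist)
  for (v in list(base, low, high)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_valid(name, "values must be finite numeric scalars")
    }
  }
  if (!(low <= base && base <= high)) {
    stop_valid(name, sprintf("requires low <= base <= high, got [%g, %g, %g]",
                             low, base, high))
  }
  rng <- range(low, high)
  if (dist == "beta" && (rng[1] < 0 || rng[2] > 1)) {
    stop_valid(name, "beta-family values must lie in [0, 1]")
  }
  if (dist == "gamma" && rng[1] < 0) {
    stop_valid(name, "gamma-family values must be >= 0")
  }
  if (dist == "lognormal" && rng[1] <= 0) {
    stop_valid(name, "lognormal-family values must be > 0")
  }
  structure(list(base = base, low = low, high = high, dist = dist),
            class = "param_value")
}

#' @export
print.param_value <- function(x, ...) {
  cat(sprintf("<param_value> base %g [%g, %g] ~ %s\n",
              x$base, x$low, x$high, x$dist))
  invisible(x)
}

is_param_value <- function(x) inherits(x, "param_value")

# Required schema: group -> parameter name -> distribution family expected
# for the shipped configuration. Families are not enforced per key (a user
# may legitimately fix any parameter) but every key must be present.
CONFIG_PARAMS <- list(
  efficacy = c("p_response_eltrombopag", "or_elt_vs_het", "or_elt_vs_ava",
               "mean_duration_elt", "p_response_subsequent",
               "mean_duration_subsequent", "time_to_response"),
  mortality = "smr_bsc",
  bleeding = c("p_minor_on_treatment", "p_minor_bsc", "p_severe_bsc"),
  costs = c("drug_hetrombopag", "drug_eltrombopag", "drug_avatrombopag",
            "rituximab", "rhtpo", "admin_tpora", "admin_subsequent",
            "management", "minor_bleed", "ich", "gi_bleed", "other_severe",
            "terminal"),
  utilities = c("u_response_no_bleed", "u_response_minor", "u_bsc_no_bleed",
                "u_bsc_minor", "u_ich", "u_gi", "u_other_severe")
)

CONFIG_SETTINGS <- c("annual_discount", "cycle_days", "wtp", "start_age",
                     "max_age", "psa_iterations", "seed")

as_param_value <- function(x, name) {
  if (is_param_value(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    return(param_value(x, name = name))
  }
  if (is.list(x)) {
    if (is.null(x$base)) stop_schema(paste0(name, ".base"))
    return(param_value(x$base,
                       low = if (is.null(x$low)) x$base else x$low,
                       high = if (is.null(x$high)) x$base else x$high,
                       dist = if (is.null(x$dist)) "fixed" else x$dist,
                       name = name))
  }
  stop_valid(name, "cannot be interpreted as a parameter value")
}

#' Assemble and validate a model configuration
#'
#' Builds the complete, validated input set for one model run: treatment
#' efficacy, background and excess mortality, bleeding probabilities,
#' costs (2024 CNY), health-state utilities, and economic settings.
#' Most users will start from [load_config()] or [default_config()].
#'
#' @param efficacy,mortality,bleeding,costs,utilities Named lists of
#'   [param_value()] objects (see the shipped configuration for the
#'   required keys). `mortality` additionally carries `life_table`, a
#'   data frame with columns `age` and `q` (annual death probability);
#'   `bleeding` additionally carries `severe_split`, the proportions of
#'   severe bleeds that are intracranial, gastrointestinal, and other.
#' @param settings Named list of economic settings: `annual_discount`,
#'   `cycle_days`, `wtp`, `start_age`, `max_age`, `psa_iterations`,
#'   `seed`, and optionally `apply_or_to_duration` (logical; also scale
#'   the duration of response by the odds ratio, off by default).
#' @return An object of class `itp_config`.
#' @export
model_config <- function(efficacy, mortality, bleeding, costs, utilities,
                         settings) {
  cfg <- structure(list(efficacy = efficacy, mortality = mortality,
                        bleeding = bleeding, costs = costs,
                        utilities = utilities, settings = settings),
                   class = "itp_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  for (grp in names(CONFIG_PARAMS)) {
    if (is.null(cfg[[grp]])) stop_schema(grp)
    for (key in CONFIG_PARAMS[[grp]]) {
      full <- paste(grp, key, sep = ".")
      if (is.null(cfg[[grp]][[key]])) stop_schema(full)
      cfg[[grp]][[key]] <- as_param_value(cfg[[grp]][[key]], full)
    }
  }
  if (is.null(cfg$settings)) stop_schema("settings")
  for (key in CONFIG_SETTINGS) {
    if (is.null(cfg$settings[[key]])) stop_schema(paste0("settings.", key))
  }
  s <- cfg$settings
  if (s$annual_discount < 0) {
    stop_valid("settings.annual_discount", "must be >= 0")
  }
  if (s$cycle_days <= 0) stop_valid("settings.cycle_days", "must be > 0")
  if (s$wtp < 0) stop_valid("settings.wtp", "must be >= 0")
  if (!(s$start_age < s$max_age)) {
    stop_valid("settings.start_age", "must be below settings.max_age")
  }
  if (s$psa_iterations < 1) {
    stop_valid("settings.psa_iterations", "must be >= 1")
  }
  if (is.null(cfg$settings$apply_or_to_duration)) {
    cfg$settings$apply_or_to_duration <- FALSE
  }

  eff <- cfg$efficacy
  for (key in c("p_response_eltrombopag", "p_response_subsequent")) {
    b <- eff[[key]]$base
    if (!(b > 0 && b < 1)) {
      stop_valid(paste0("efficacy.", key), "must lie strictly in (0, 1)")
    }
  }
  for (key in c("mean_duration_elt", "mean_duration_subsequent")) {
    if (eff[[key]]$base <= 1) {
      stop_valid(paste0("efficacy.", key), "must exceed 1 cycle")
    }
  }
  for (key in c("or_elt_vs_het", "or_elt_vs_ava")) {
    if (eff[[key]]$base <= 0) {
      stop_valid(paste0("efficacy.", key), "odds ratios must be > 0")
    }
  }
  if (eff$time_to_response$base != 1) {
    stop_valid("efficacy.time_to_response",
               "is structurally one cycle in this model")
  }
  if (cfg$mortality$smr_bsc$base < 1) {
    stop_valid("mortality.smr_bsc", "must be >= 1")
  }

  split <- cfg$bleeding$severe_split
  if (is.null(split)) stop_schema("bleeding.severe_split")
  split <- as.numeric(split)
  if (length(split) != 3L || any(split < 0) ||
      abs(sum(split) - 1) > 1e-6) {
    stop_valid("bleeding.severe_split",
               "must be 3 non-negative proportions summing to 1")
  }
  cfg$bleeding$severe_split <- split / sum(split)

  lt <- cfg$mortality$life_table
  if (is.null(lt)) stop_schema("mortality.life_table")
  validate_life_table(lt, floor(s$start_age), ceiling(s$max_age))
  cfg
}

validate_life_table <- function(lt, min_age, max_age) {
  if (!is.data.frame(lt) || !all(c("age", "q") %in% names(lt))) {
    stop_valid("mortality.life_table",
               "must be a data frame with columns 'age' and 'q'")
  }
  if (any(lt$q < 0) || any(lt$q >= 1)) {
    stop_valid("mortality.life_table",
               "annual death probabilities must lie in [0, 1)")
  }
  if (any(diff(lt$age) != 1L)) {
    stop_valid("mortality.life_table", "ages must be contiguous")
  }
  if (min(lt$age) > min_age || max(lt$age) < max_age - 1L) {
    stop_valid("mortality.life_table",
               sprintf("must cover ages %d to %d", min_age, max_age - 1L))
  }
  invisible(lt)
}

#' Load a model configuration from a YAML file
#'
#' Reads, validates, and returns a complete model configuration. The file
#' follows the schema of the shipped `itp_china_2024` configuration:
#' groups `efficacy`, `mortality`, `bleeding`, `costs`, `utilities`, and
#' `settings`, with each uncertain parameter written as
#' `{base, low, high, dist}`. `mortality.life_table` may be the string
#' `"synthetic"` (use the package's Gompertz-Makeham stand-in, see
#' [gen_life_table()]), a path to a two-column CSV (`age`, `q`) resolved
#' relative to the configuration file, or an inline mapping with `age`
#' and `q` sequences.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `itp_config` object.
#' @seealso [default_config()], [save_config()], [param_table()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  for (grp in c(names(CONFIG_PARAMS), "settings")) {
    if (is.null(raw[[grp]])) stop_schema(grp)
  }
  lt_src <- raw$mortality$life_table
  if (is.null(lt_src)) stop_schema("mortality.life_table")
  if (is.character(lt_src) && identical(lt_src, "synthetic")) {
    lt <- gen_life_table()
    source <- "synthetic"
  } else if (is.character(lt_src)) {
    lt_path <- if (file.exists(lt_src)) lt_src else {
      file.path(dirname(path), lt_src)
    }
    if (!file.exists(lt_path)) {
      stop(sprintf("life table file '%s' does not exist", lt_src),
           call. = FALSE)
    }
    lt <- read.csv(lt_path)
    source <- "inline"
  } else if (is.list(lt_src)) {
    lt <- data.frame(age = as.integer(lt_src$age), q = as.numeric(lt_src$q))
    source <- "inline"
  } else {
    stop_valid("mortality.life_table", "unrecognised specification")
  }
  raw$mortality$life_table <- lt
  raw$mortality$life_table_source <- source
  cfg <- structure(raw, class = "itp_config")
  validate_config(cfg)
}

#' The shipped `itp_china_2024` configuration
#'
#' The default configuration encodes the published 2024 Chinese input
#' tables: efficacy (initial response rates, odds ratios from the network
#' meta-analysis, mean durations of response), per-cycle bleeding
#' probabilities, the standardized mortality ratio for best supportive
#' care, all costs in 2024 CNY, health-state utilities, a 5% annual
#' discount rate, 4-week cycles, and a willingness-to-pay threshold of
#' CNY 287,391 per QALY (three times the 2024 per-capita GDP).
#'
#' @return A validated `itp_config` object.
#' @export
default_config <- function() {
  load_config(system.file("extdata", "itp_china_2024.yaml",
                          package = "itpcea", mustWork = TRUE))
}

#' Save a model configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces `cfg`. A synthetic life table is stored as the marker
#' `"synthetic"`; any other table is inlined.
#'
#' @param cfg An `itp_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "itp_config"))
  out <- list()
  for (grp in names(CONFIG_PARAMS)) {
    out[[grp]] <- lapply(cfg[[grp]][CONFIG_PARAMS[[grp]]], function(p) {
      list(base = p$base, low = p$low, high = p$high, dist = p$dist)
    })
  }
  out$bleeding$severe_split <- cfg$bleeding$severe_split
  if (identical(cfg$mortality$life_table_source, "synthetic")) {
    out$mortality$life_table <- "synthetic"
  } else {
    lt <- cfg$mortality$life_table
    out$mortality$life_table <- list(age = lt$age, q = lt$q)
  }
  out$settings <- cfg$settings[c(CONFIG_SETTINGS, "apply_or_to_duration")]
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.itp_config <- function(x, ...) {
  s <- x$settings
  cat("<itp_config>\n")
  cat(sprintf("  strategies: %s\n", paste(STRATEGIES, collapse = ", ")))
  cat(sprintf("  cohort: start age %g, horizon to age %g, %g-day cycles\n",
              s$start_age, s$max_age, s$cycle_days))
  cat(sprintf("  discount %g%%/yr, WTP CNY %s/QALY\n",
              100 * s$annual_discount, format(s$wtp, big.mark = ",")))
  cat(sprintf("  %d uncertain parameters (see param_table())\n",
              nrow(param_table(x))))
  invisible(x)
}

#' Flatten the uncertain parameters of a configuration
#'
#' @param cfg An `itp_config` object.
#' @return A data frame with columns `name` (dot-separated `group.param`),
#'   `base`, `low`, `high`, and `family`.
#' @export
param_table <- function(cfg) {
  stopifnot(inherits(cfg, "itp_config"))
  rows <- lapply(names(CONFIG_PARAMS), function(grp) {
    do.call(rbind, lapply(CONFIG_PARAMS[[grp]], function(key) {
      p <- cfg[[grp]][[key]]
      data.frame(name = paste(grp, key, sep = "."), base = p$base,
                 low = p$low, high = p$high, family = p$dist,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Export the resolved parameter table as CSV
#'
#' @param cfg An `itp_config` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(cfg, path) {
  write.csv(param_table(cfg), path, row.names = FALSE)
  invisible(path)
}

get_param <- function(cfg, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  p <- cfg[[parts[1]]][[parts[2]]]
  if (is.null(p)) stop_schema(name)
  p
}

# Replace the base value of one named parameter. Values outside the
# family's hard support are clipped with a warning (the deterministic
# sensitivity analysis contract).
set_param <- function(cfg, name, value, clip = TRUE) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  p <- get_param(cfg, name)
  if (clip) {
    clipped <- value
    if (p$dist == "beta") clipped <- min(max(value, 0), 1)
    if (p$dist == "gamma") clipped <- max(value, 0)
    if (p$dist == "lognormal") clipped <- max(value, .Machine$double.eps)
    if (clipped != value) {
      warning(sprintf("parameter '%s': value %g clipped to %g (outside the %s support)",
                      name, value, clipped, p$dist), call. = FALSE)
      value <- clipped
    }
  }
  p$base <- value
  p$low <- min(p$low, value)
  p$high <- max(p$high, value)
  cfg[[parts[1]]][[parts[2]]] <- p
  cfg
}

#' Build a sampling distribution from a parameter's printed summary
#'
#' Interprets the lower/upper values as a 95% interval, so the standard
#' deviation is `(high - low) / (2 * 1.96)`, and matches moments:
#' beta (`alpha`, `beta` from mean and variance) for probabilities and
#' utilities, gamma (`shape`, `scale`) for costs, log-normal (`meanlog`,
#' `sdlog` of the log) for relative effect measures. The analytic mean of
#' the returned distribution equals `base` by construction.
#'
#' When the implied beta variance is infeasible (`var >= mean(1-mean)`,
#' possible for utilities with very wide printed ranges), the standard
#' deviation is truncated to 95% of the feasibility limit with a warning
#' unless `strict = TRUE`, in which case an error is thrown.
#'
#' @param p A [param_value()] with a non-fixed family (fixed parameters
#'   yield a degenerate distribution).
#' @param strict Error instead of truncating infeasible beta moments.
#' @return An object of class `itp_dist` with fields `family`, `pars`,
#'   `mean`, `sd`; draw from it with [draw()].
#' @examples
#' d <- build_distribution(param_value(0.577, 0.46156, 0.69244, "beta"))
#' d$pars # alpha ~ 40.0, beta ~ 29.3
#' @export
build_distribution <- function(p, strict = FALSE) {
  stopifnot(is_param_value(p))
  if (p$dist == "fixed" || p$low == p$high) {
    return(structure(list(family = "fixed", pars = c(value = p$base),
                          mean = p$base, sd = 0), class = "itp_dist"))
  }
  if (!(p$low < p$high)) {
    stop("build_distribution: requires low < high", call. = FALSE)
  }
  if (!(p$base > p$low && p$base < p$high)) {
    stop("build_distribution: base must lie strictly inside (low, high)",
         call. = FALSE)
  }
  m <- p$base
  sd <- (p$high - p$low) / (2 * 1.96)
  v <- sd^2
  pars <- switch(p$dist,
    beta = {
      vmax <- m * (1 - m)
      if (v >= vmax) {
        if (strict) {
          stop(sprintf("build_distribution: infeasible beta moments (var %g >= mean(1-mean) %g)",
                       v, vmax), call. = FALSE)
        }
        warning(sprintf("beta moments infeasible for mean %g; SD truncated from %g to %g",
                        m, sd, 0.95 * sqrt(vmax)), call. = FALSE)
        sd <- 0.95 * sqrt(vmax)
        v <- sd^2
      }
      k <- vmax / v - 1
      c(alpha = m * k, beta = (1 - m) * k)
    },
    gamma = c(shape = m^2 / v, scale = v / m),
    lognormal = {
      s2 <- log(1 + v / m^2)
      c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    },
    stop("build_distribution: unsupported family", call. = FALSE))
  structure(list(family = p$dist, pars = pars, mean = m, sd = sd),
            class = "itp_dist")
}

#' Draw from a built sampling distribution
#'
#' @param x An `itp_dist` from [build_distribution()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when supplied, draws are
#'   reproducible independently of the surrounding RNG state.
#' @return Numeric vector of `n` draws within the family's support.
#' @export
draw <- function(x, n, seed = NULL) UseMethod("draw")

#' @export
draw.itp_dist <- function(x, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- x$pars
  switch(x$family,
    fixed = rep(p[["value"]], n),
    beta = rbeta(n, p[["alpha"]], p[["beta"]]),
    gamma = rgamma(n, shape = p[["shape"]], scale = p[["scale"]]),
    lognormal = rlnorm(n, p[["meanlog"]], p[["sdlog"]]))
}

#' @export
print.itp_dist <- function(x, ...) {
  cat(sprintf("<itp_dist> %s(%s): mean %g, sd %g\n", x$family,
              paste(sprintf("%s=%.5g", names(x$pars), x$pars),
                    collapse = ", "), x$mean, x$sd))
  invisible(x)
}
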