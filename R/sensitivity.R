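#' One-way deterministic sensitivity analysis (tornado)
#'
#' Sets each uncertain parameter in turn to its lower and upper value
#' (all others at base), reruns both strategies of the comparison, and
#' records the incremental net monetary benefit at the configured
#' willingness-to-pay threshold. Bounds that would violate a family's
#' hard support are clipped with a warning.
#'
#' @param cfg An `itp_config`.
#' @param pair Length-2 character vector: intervention, comparator.
#' @param params Optional subset of parameter names (default: every
#'   uncertain parameter in the configuration).
#' @return Data frame of class `tornado` sorted by decreasing bar width,
#'   with columns `param`, `inmb_low`, `inmb_high`, `range`,
#'   `crosses_zero`; the base-case iNMB is attached as attribute
#'   `base_inmb`.
#' @export
run_dsa <- function(cfg, pair, params = NULL) {
  stopifnot(inherits(cfg, "itp_config"), length(pair) == 2L)
  pair <- unname(vapply(pair, match_strategy, character(1)))
  pt <- param_table(cfg)
  if (is.null(params)) params <- pt$name
  wtp <- cfg$settings$wtp
  pair_inmb <- function(cfg_i) {
    a <- run_markov(cfg_i, pair[1])$result
    b <- run_markov(cfg_i, pair[2])$result
    inmb(a$total_qalys - b$total_qalys, a$total_cost - b$total_cost, wtp)
  }
  base_inmb <- pair_inmb(cfg)
  rows <- lapply(params, function(name) {
    p <- get_param(cfg, name)
    lo <- pair_inmb(set_param(cfg, name, p$low))
    hi <- pair_inmb(set_param(cfg, name, p$high))
    data.frame(param = name, inmb_low = lo, inmb_high = hi,
               range = abs(hi - lo),
               crosses_zero = min(lo, hi) < 0 && max(lo, hi) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range, out$param), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_inmb") <- base_inmb
  attr(out, "pair") <- pair
  class(out) <- c("tornado", "data.frame")
  out
}

# Static (iteration-invariant) engine quantities shared by all PSA
# iterations: the discount vector and the per-cycle background hazard
# increments derived from the life table.
psa_static <- function(cfg) {
  s <- cfg$settings
  cyc_frac <- s$cycle_days / DAYS_PER_YEAR
  n_cycles <- ceiling((s$max_age - s$start_age) / cyc_frac)
  ages <- s$start_age + (seq_len(n_cycles) - 1) * cyc_frac
  idx <- match(floor(ages), cfg$mortality$life_table$age)
  if (anyNA(idx)) stop("psa: cohort age leaves the life table", call. = FALSE)
  q <- cfg$mortality$life_table$q[idx]
  rr <- -log(1 - q) * cyc_frac  # per-cycle cumulative hazard at SMR 1
  list(rr = rr, m_bg = 1 - exp(-rr),
       df = discount_factor(seq_len(n_cycles), s$annual_discount,
                            s$cycle_days),
       n_cycles = n_cycles, cyc_frac = cyc_frac,
       ages = c(ages, s$start_age + n_cycles * cyc_frac),
       settings = s)
}

# Assemble engine parameters for one strategy from a named vector of
# sampled parameter values (names as in param_table()).
psa_engine_pars <- function(v, strategy, static, severe_split, m_bsc) {
  g <- function(name) v[[name]]
  p_elt <- g("efficacy.p_response_eltrombopag")
  p_response <- switch(strategy,
    eltrombopag = p_elt,
    hetrombopag = odds_transform(p_elt, g("efficacy.or_elt_vs_het")),
    avatrombopag = odds_transform(p_elt, g("efficacy.or_elt_vs_ava")))
  dur <- g("efficacy.mean_duration_elt")
  if (isTRUE(static$settings$apply_or_to_duration) &&
      strategy != "eltrombopag") {
    dur <- dur / switch(strategy,
                        hetrombopag = g("efficacy.or_elt_vs_het"),
                        avatrombopag = g("efficacy.or_elt_vs_ava"))
  }
  drug <- switch(strategy,
    hetrombopag = g("costs.drug_hetrombopag"),
    eltrombopag = g("costs.drug_eltrombopag"),
    avatrombopag = g("costs.drug_avatrombopag"))
  cyc_frac <- static$cyc_frac
  severe_cost <- sum(severe_split * c(g("costs.ich"), g("costs.gi_bleed"),
                                      g("costs.other_severe")))
  severe_u <- sum(severe_split * c(g("utilities.u_ich"),
                                   g("utilities.u_gi"),
                                   g("utilities.u_other_severe")))
  p_minor_tx <- g("bleeding.p_minor_on_treatment")
  p_minor_bsc <- g("bleeding.p_minor_bsc")
  p_severe_bsc <- g("bleeding.p_severe_bsc")
  list(strategy = strategy, p_response = p_response,
       p_exit_resp = per_cycle_exit_prob(dur),
       p_exit_sub = per_cycle_exit_prob(g("efficacy.mean_duration_subsequent")),
       p_response_sub = g("efficacy.p_response_subsequent"),
       m_bg = static$m_bg, m_bsc = m_bsc, df = static$df,
       n_cycles = static$n_cycles, ages = static$ages,
       cyc_frac = cyc_frac,
       drug = drug, drug_sub = g("costs.rituximab") + g("costs.rhtpo"),
       admin_tpora = g("costs.admin_tpora"),
       admin_subsequent = g("costs.admin_subsequent"),
       management = g("costs.management"),
       bleed_tx = p_minor_tx * g("costs.minor_bleed"),
       bleed_bsc = p_minor_bsc * g("costs.minor_bleed") +
         p_severe_bsc * severe_cost,
       terminal = g("costs.terminal"),
       u_tx_cycle = ((1 - p_minor_tx) * g("utilities.u_response_no_bleed") +
                     p_minor_tx * g("utilities.u_response_minor")) * cyc_frac,
       u_bsc_cycle = ((1 - p_minor_bsc - p_severe_bsc) *
                        g("utilities.u_bsc_no_bleed") +
                      p_minor_bsc * g("utilities.u_bsc_minor") +
                      p_severe_bsc * severe_u) * cyc_frac)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo resampling of every uncertain parameter from its
#' method-of-moments distribution (see [build_distribution()]), with one
#' draw per parameter per iteration applied consistently across all
#' strategies of that iteration. Draws violating a model invariant
#' (response probabilities outside (0, 1), durations of one cycle or
#' less) are redrawn; the redraw count is recorded as attribute
#' `redraws` of the returned object.
#'
#' @param cfg An `itp_config`.
#' @param n Number of iterations (default: `settings$psa_iterations`).
#' @param seed Integer seed (default: `settings$seed`).
#' @param strategies Strategies to evaluate.
#' @param progress_every Emit a progress message every this many
#'   iterations; 0 disables.
#' @return An object of class `psa_results`: iteration-by-strategy
#'   matrices `cost` and `qalys`, the parameter draw matrix `draws`,
#'   `iterations`, `strategies`, `wtp`, `seed`.
#' @export
run_psa <- function(cfg, n = NULL, seed = NULL, strategies = STRATEGIES,
                    progress_every = 0) {
  stopifnot(inherits(cfg, "itp_config"))
  if (is.null(n)) n <- cfg$settings$psa_iterations
  if (is.null(seed)) seed <- cfg$settings$seed
  strategies <- unname(vapply(strategies, match_strategy, character(1)))
  pt <- param_table(cfg)
  dists <- lapply(seq_len(nrow(pt)), function(i) {
    build_distribution(get_param(cfg, pt$name[i]))
  })
  names(dists) <- pt$name
  set.seed(seed)
  draws <- matrix(NA_real_, n, nrow(pt),
                  dimnames = list(NULL, pt$name))
  redraws <- 0L
  must_be_prob <- c("efficacy.p_response_eltrombopag",
                    "efficacy.p_response_subsequent")
  must_exceed_one <- c("efficacy.mean_duration_elt",
                       "efficacy.mean_duration_subsequent")
  for (j in seq_len(nrow(pt))) {
    x <- draw(dists[[j]], n)
    bad <- if (pt$name[j] %in% must_be_prob) {
      x <= 0 | x >= 1
    } else if (pt$name[j] %in% must_exceed_one) {
      x <= 1
    } else rep(FALSE, n)
    tries <- 0L
    while (any(bad) && tries < 100L) {
      redraws <- redraws + sum(bad)
      x[bad] <- draw(dists[[j]], sum(bad))
      bad <- if (pt$name[j] %in% must_be_prob) {
        x <= 0 | x >= 1
      } else x <= 1
      tries <- tries + 1L
    }
    if (any(bad)) {
      stop(sprintf("run_psa: could not obtain a feasible draw for '%s'",
                   pt$name[j]), call. = FALSE)
    }
    draws[, j] <- x
  }
  static <- psa_static(cfg)
  split <- cfg$bleeding$severe_split
  cost <- qalys <- matrix(NA_real_, n, length(strategies),
                          dimnames = list(NULL, strategies))
  for (i in seq_len(n)) {
    v <- as.list(draws[i, ])
    m_bsc <- 1 - exp(-static$rr * v[["mortality.smr_bsc"]])
    for (s in strategies) {
      p <- psa_engine_pars(v, s, static, split, m_bsc)
      res <- engine_results(p, markov_engine(p))
      cost[i, s] <- res$total_cost
      qalys[i, s] <- res$total_qalys
    }
    if (progress_every > 0 && i %% progress_every == 0) {
      message(sprintf("psa: %d/%d iterations", i, n))
    }
  }
  structure(list(iterations = n, strategies = strategies, cost = cost,
                 qalys = qalys, draws = draws, wtp = cfg$settings$wtp,
                 seed = seed),
            class = "psa_results", redraws = redraws)
}

#' @export
print.psa_results <- function(x, ...) {
  cat(sprintf("<psa_results> %d iterations, seed %d\n", x$iterations,
              x$seed))
  for (s in x$strategies) {
    cat(sprintf("  %-13s mean cost CNY %s, mean QALYs %.3f\n", s,
                formatC(mean(x$cost[, s]), format = "f", digits = 0,
                        big.mark = ","), mean(x$qalys[, s])))
  }
  invisible(x)
}

#' Long-format PSA samples
#'
#' @param psa A `psa_results` object.
#' @return Data frame with columns `iteration`, `strategy`, `cost`,
#'   `qalys`.
#' @export
psa_samples <- function(psa) {
  stopifnot(inherits(psa, "psa_results"))
  do.call(rbind, lapply(psa$strategies, function(s) {
    data.frame(iteration = seq_len(psa$iterations), strategy = s,
               cost = psa$cost[, s], qalys = psa$qalys[, s],
               stringsAsFactors = FALSE)
  }))
}

# Index of the NMB-optimal strategy per iteration with the
# rank_strategies tie-break (max NMB, then lower cost, then name).
psa_winners <- function(psa, wtp) {
  nmb <- psa$qalys * wtp - psa$cost
  ord <- order(psa$strategies)
  win <- max.col(nmb, ties.method = "first")
  rmax <- nmb[cbind(seq_len(nrow(nmb)), win)]
  tied <- rowSums(nmb == rmax) > 1L
  if (any(tied)) {
    for (i in which(tied)) {
      cand <- which(nmb[i, ] == rmax[i])
      cand <- cand[order(psa$cost[i, cand], psa$strategies[cand])]
      win[i] <- cand[1]
    }
  }
  win
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each strategy
#' attains the maximal net monetary benefit across PSA iterations (ties
#' resolved as in [rank_strategies()]).
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Ascending vector of WTP thresholds (CNY/QALY).
#' @return Data frame of class `ceac_curve`: column `wtp` plus one
#'   probability column per strategy; each row sums to 1.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 600000, by = 10000)) {
  stopifnot(inherits(psa, "psa_results"), psa$iterations >= 1,
            !is.unsorted(wtp_grid))
  probs <- t(vapply(wtp_grid, function(w) {
    win <- psa_winners(psa, w)
    tabulate(win, nbins = length(psa$strategies)) / psa$iterations
  }, numeric(length(psa$strategies))))
  colnames(probs) <- psa$strategies
  out <- data.frame(wtp = wtp_grid, probs)
  class(out) <- c("ceac_curve", "data.frame")
  out
}

#' Incremental scatter data for one ordered pair
#'
#' Per-iteration incremental cost and QALYs of the intervention versus
#' the comparator, with cost-effectiveness-plane quadrant labels
#' (NE/SE/SW/NW).
#'
#' @param psa A [run_psa()] result.
#' @param pair Length-2 character vector: intervention, comparator.
#' @return Data frame with columns `intervention`, `comparator`,
#'   `iteration`, `delta_cost`, `delta_qalys`, `quadrant`.
#' @export
scatter_data <- function(psa, pair) {
  stopifnot(inherits(psa, "psa_results"), length(pair) == 2L,
            all(pair %in% psa$strategies))
  dc <- psa$cost[, pair[1]] - psa$cost[, pair[2]]
  de <- psa$qalys[, pair[1]] - psa$qalys[, pair[2]]
  quadrant <- ifelse(de >= 0, ifelse(dc >= 0, "NE", "SE"),
                     ifelse(dc >= 0, "NW", "SW"))
  data.frame(intervention = pair[1], comparator = pair[2],
             iteration = seq_len(psa$iterations), delta_cost = dc,
             delta_qalys = de, quadrant = quadrant,
             stringsAsFactors = FALSE)
}

SCENARIOS <- c("wtp_1x_gdp", "subsequent_plus30", "subsequent_minus30",
               "none")

#' Scenario analyses
#'
#' `"wtp_1x_gdp"` lowers the willingness-to-pay threshold to one
#' per-capita GDP (the configured threshold divided by 3);
#' `"subsequent_plus30"` / `"subsequent_minus30"` scale the
#' subsequent-treatment cost parameters (rituximab, rhTPO, their
#' administration) and efficacy parameters (initial response rate,
#' clipped below 1, and mean duration of response) by 1.3 / 0.7;
#' `"none"` reruns the unmodified base case.
#'
#' @param cfg An `itp_config`.
#' @param scenario Scenario name.
#' @return An `itp_base_case` for the modified model; the scenario name
#'   is attached as attribute `scenario`.
#' @export
run_scenario <- function(cfg, scenario = SCENARIOS) {
  stopifnot(inherits(cfg, "itp_config"))
  scenario <- match.arg(scenario)
  if (scenario == "wtp_1x_gdp") {
    cfg$settings$wtp <- cfg$settings$wtp / 3
  } else if (scenario %in% c("subsequent_plus30", "subsequent_minus30")) {
    f <- if (scenario == "subsequent_plus30") 1.3 else 0.7
    for (name in c("costs.rituximab", "costs.rhtpo",
                   "costs.admin_subsequent",
                   "efficacy.mean_duration_subsequent")) {
      cfg <- set_param(cfg, name, get_param(cfg, name)$base * f)
    }
    p <- get_param(cfg, "efficacy.p_response_subsequent")$base * f
    if (p >= 1) {
      warning(sprintf("scenario %s: subsequent response rate %.4f clipped to 0.999",
                      scenario, p), call. = FALSE)
      p <- 0.999
    }
    cfg <- set_param(cfg, "efficacy.p_response_subsequent", p)
  }
  out <- run_base_case(cfg)
  attr(out, "scenario") <- scenario
  out
}
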