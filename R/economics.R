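#' Incremental net monetary benefit
#'
#' `iNMB = delta_e * wtp - delta_c`. Positive values mean the
#' intervention is cost-effective against the comparator at the given
#' willingness-to-pay threshold.
#'
#' @param delta_e Incremental effectiveness (QALYs).
#' @param delta_c Incremental cost (CNY).
#' @param wtp Willingness-to-pay threshold (CNY/QALY, >= 0).
#' @return Incremental net monetary benefit in CNY.
#' @examples
#' inmb(0.176, -8605, 287391)
#' @export
inmb <- function(delta_e, delta_c, wtp) {
  if (any(wtp < 0)) stop("inmb: wtp must be >= 0", call. = FALSE)
  delta_e * wtp - delta_c
}

#' Incremental cost-effectiveness ratio with dominance labels
#'
#' @param delta_c Incremental cost (CNY).
#' @param delta_e Incremental effectiveness (QALYs).
#' @return `delta_c / delta_e` when the ratio is interpretable;
#'   otherwise the character label `"dominant"` (cheaper and more
#'   effective), `"dominated"` (costlier and less effective), or
#'   `"cost-minimization"` (no QALY difference).
#' @export
icer <- function(delta_c, delta_e) {
  stopifnot(length(delta_c) == 1L, length(delta_e) == 1L)
  if (delta_e == 0) return("cost-minimization")
  if (delta_c < 0 && delta_e > 0) return("dominant")
  if (delta_c > 0 && delta_e < 0) return("dominated")
  delta_c / delta_e
}

as_result_df <- function(results) {
  if (is.data.frame(results)) {
    stopifnot(all(c("strategy", "total_cost", "total_qalys") %in%
                  names(results)))
    return(results)
  }
  do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "strategy_result"))
    data.frame(strategy = r$strategy, total_cost = r$total_cost,
               total_qalys = r$total_qalys, stringsAsFactors = FALSE)
  }))
}

#' Rank strategies by net monetary benefit
#'
#' Computes `NMB = total_qalys * wtp - total_cost` per strategy and
#' sorts in decreasing order; the first row is the optimal strategy.
#' Ties are broken by lower cost, then by strategy name.
#'
#' @param results List of `strategy_result` objects (or a data frame
#'   with columns `strategy`, `total_cost`, `total_qalys`).
#' @param wtp Willingness-to-pay threshold (CNY/QALY).
#' @return Data frame sorted by decreasing NMB with columns `strategy`,
#'   `total_cost`, `total_qalys`, `nmb`, `rank`.
#' @export
rank_strategies <- function(results, wtp) {
  d <- as_result_df(results)
  d$nmb <- d$total_qalys * wtp - d$total_cost
  d <- d[order(-d$nmb, d$total_cost, d$strategy), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

#' Pairwise incremental comparisons
#'
#' Produces the comparison block of a base-case table: for each ordered
#' pair, the incremental cost, incremental QALYs, ICER (or dominance
#' label), and incremental net monetary benefit of the first strategy
#' versus the second.
#'
#' @param results List of `strategy_result` objects or equivalent data
#'   frame.
#' @param wtp Willingness-to-pay threshold (CNY/QALY).
#' @param pairs List of length-2 character vectors; defaults to the
#'   three ordered comparisons among the strategies in `results`, in
#'   listed order.
#' @return Data frame with columns `intervention`, `comparator`,
#'   `delta_cost`, `delta_qalys`, `icer`, `inmb`.
#' @export
compare_strategies <- function(results, wtp, pairs = NULL) {
  d <- as_result_df(results)
  if (is.null(pairs)) {
    cmb <- utils::combn(d$strategy, 2, simplify = FALSE)
    pairs <- cmb
  }
  rows <- lapply(pairs, function(pr) {
    a <- d[d$strategy == pr[1], ]
    b <- d[d$strategy == pr[2], ]
    if (nrow(a) != 1 || nrow(b) != 1) {
      stop(sprintf("compare_strategies: unknown pair %s vs %s", pr[1],
                   pr[2]), call. = FALSE)
    }
    dc <- a$total_cost - b$total_cost
    de <- a$total_qalys - b$total_qalys
    ic <- icer(dc, de)
    data.frame(intervention = pr[1], comparator = pr[2], delta_cost = dc,
               delta_qalys = de,
               icer = if (is.character(ic)) ic else sprintf("%.0f", ic),
               inmb = inmb(de, dc, wtp), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the base-case analysis for all strategies
#'
#' Runs the cohort model once per strategy and assembles per-strategy
#' discounted totals, all pairwise incremental comparisons, and the NMB
#' ranking at the configured willingness-to-pay threshold.
#'
#' @param cfg An `itp_config`.
#' @param strategies Strategies to run (default: all three).
#' @return An object of class `itp_base_case` with components `results`
#'   (data frame of totals), `comparisons`, `ranking`, `runs` (the full
#'   [run_markov()] output per strategy), and `wtp`.
#' @examples
#' \donttest{
#' bc <- run_base_case(default_config())
#' bc$comparisons
#' }
#' @export
run_base_case <- function(cfg, strategies = STRATEGIES) {
  stopifnot(inherits(cfg, "itp_config"))
  runs <- lapply(strategies, function(s) run_markov(cfg, s))
  names(runs) <- strategies
  results <- do.call(rbind, lapply(runs, function(r) {
    data.frame(strategy = r$result$strategy,
               total_cost = r$result$total_cost,
               total_qalys = r$result$total_qalys,
               life_years = r$result$life_years, stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  structure(list(results = results,
                 comparisons = compare_strategies(results,
                                                  cfg$settings$wtp),
                 ranking = rank_strategies(results, cfg$settings$wtp),
                 runs = runs, wtp = cfg$settings$wtp),
            class = "itp_base_case")
}

#' @export
print.itp_base_case <- function(x, ...) {
  cat(sprintf("<itp_base_case> WTP CNY %s/QALY\n",
              format(x$wtp, big.mark = ",")))
  r <- x$results
  r$total_cost <- formatC(r$total_cost, format = "f", digits = 0,
                          big.mark = ",")
  r$total_qalys <- sprintf("%.3f", r$total_qalys)
  r$life_years <- sprintf("%.3f", r$life_years)
  print(r, row.names = FALSE)
  cat("comparisons:\n")
  cmp <- x$comparisons
  cmp$delta_cost <- formatC(cmp$delta_cost, format = "f", digits = 0,
                            big.mark = ",")
  cmp$delta_qalys <- sprintf("%.3f", cmp$delta_qalys)
  cmp$inmb <- formatC(cmp$inmb, format = "f", digits = 0, big.mark = ",")
  print(cmp, row.names = FALSE)
  cat(sprintf("optimal strategy by NMB: %s\n", x$ranking$strategy[1]))
  invisible(x)
}
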