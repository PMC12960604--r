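test_that("DSA with degenerate bounds reproduces the base-case iNMB", {
  cfg <- shrink_uncertainty(cfg_default, 0)
  tor <- run_dsa(cfg, c("hetrombopag", "eltrombopag"))
  base <- attr(tor, "base_inmb")
  expect_true(all(abs(tor$inmb_low - base) < 1e-9))
  expect_true(all(abs(tor$inmb_high - base) < 1e-9))
  expect_true(all(tor$range < 1e-9))
  expect_false(any(tor$crosses_zero))
})

test_that("tornado entries are sorted and order-invariant", {
  params <- c("costs.drug_hetrombopag", "efficacy.or_elt_vs_het",
              "mortality.smr_bsc", "utilities.u_response_no_bleed")
  tor1 <- run_dsa(cfg_default, c("hetrombopag", "eltrombopag"), params)
  tor2 <- run_dsa(cfg_default, c("hetrombopag", "eltrombopag"),
                  rev(params))
  expect_equal(tor1, tor2, ignore_attr = TRUE)
  expect_true(all(diff(tor1$range) <= 0))
  expect_equal(tor1$range, abs(tor1$inmb_high - tor1$inmb_low))
})

test_that("DSA respects bar endpoints computed from single reruns", {
  # an independent two-run check for one parameter
  tor <- run_dsa(cfg_default, c("eltrombopag", "avatrombopag"),
                 params = "costs.drug_avatrombopag")
  lo_cfg <- with_param(cfg_default, "costs.drug_avatrombopag", 8870.40)
  a <- run_markov(lo_cfg, "eltrombopag")$result
  b <- run_markov(lo_cfg, "avatrombopag")$result
  expect_equal(tor$inmb_low[1],
               inmb(a$total_qalys - b$total_qalys,
                    a$total_cost - b$total_cost, 287391),
               tolerance = 1e-9)
})

test_that("PSA is seed-reproducible and parameter draws are consistent", {
  p1 <- run_psa(cfg_default, n = 3, seed = 7)
  p2 <- run_psa(cfg_default, n = 3, seed = 7)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$qalys, p2$qalys)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(cfg_default, n = 3, seed = 8)
  expect_false(identical(p1$cost, p3$cost))
  expect_true(all(p1$cost > 0))
  expect_true(all(is.finite(p1$qalys)))
})

test_that("PSA with near-zero variance converges to the base case", {
  cfg <- shrink_uncertainty(cfg_default, 1e-7)
  psa <- run_psa(cfg, n = 20, seed = 5)
  bc <- run_base_case(cfg_default)
  for (s in psa$strategies) {
    base_cost <- bc$results$total_cost[bc$results$strategy == s]
    base_q <- bc$results$total_qalys[bc$results$strategy == s]
    expect_lt(abs(mean(psa$cost[, s]) / base_cost - 1), 1e-3)
    expect_lt(abs(mean(psa$qalys[, s]) / base_q - 1), 1e-3)
  }
})

test_that("PSA strategy means stay near the deterministic base case", {
  psa <- run_psa(cfg_default, n = 200, seed = 42)
  bc <- run_base_case(cfg_default)
  for (s in psa$strategies) {
    base_cost <- bc$results$total_cost[bc$results$strategy == s]
    expect_lt(abs(mean(psa$cost[, s]) / base_cost - 1), 0.05)
  }
})

test_that("CEAC probabilities partition the iterations", {
  psa <- run_psa(cfg_default, n = 50, seed = 31)
  cc <- ceac(psa, wtp_grid = seq(0, 6e5, 5e4))
  probs <- as.matrix(cc[, psa$strategies])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))
  expect_true(all(probs >= 0 & probs <= 1))
  # a single iteration yields degenerate 0/1 probabilities
  psa1 <- run_psa(cfg_default, n = 1, seed = 3)
  cc1 <- ceac(psa1, wtp_grid = c(0, 287391))
  expect_true(all(as.matrix(cc1[, psa1$strategies]) %in% c(0, 1)))
  # at wtp = 0 the winner is the cheapest strategy in each iteration
  cc0 <- ceac(psa, wtp_grid = 0)
  cheapest <- table(factor(psa$strategies[apply(psa$cost, 1, which.min)],
                           levels = psa$strategies)) / psa$iterations
  expect_equal(as.numeric(cc0[1, psa$strategies]), as.numeric(cheapest))
})

test_that("scatter data labels cost-effectiveness-plane quadrants", {
  psa <- run_psa(cfg_default, n = 25, seed = 17)
  sc <- scatter_data(psa, c("hetrombopag", "avatrombopag"))
  expect_equal(nrow(sc), 25)
  expect_equal(sc$delta_cost,
               psa$cost[, "hetrombopag"] - psa$cost[, "avatrombopag"])
  with(sc[sc$quadrant == "SW", ],
       expect_true(all(delta_cost < 0 & delta_qalys < 0)))
  expect_true(all(sc$quadrant %in% c("NE", "SE", "SW", "NW")))
})

test_that("the identity scenario reproduces the base case", {
  sc <- run_scenario(cfg_default, "none")
  bc <- run_base_case(cfg_default)
  expect_equal(sc$results, bc$results, tolerance = 1e-12)
  expect_equal(sc$comparisons$inmb, bc$comparisons$inmb,
               tolerance = 1e-12)
})

test_that("scenario modifications act on the intended parameters", {
  sc <- run_scenario(cfg_default, "wtp_1x_gdp")
  expect_equal(sc$wtp, 287391 / 3)
  expect_warning(up <- run_scenario(cfg_default, "subsequent_plus30"),
                 "clipped")
  dn <- run_scenario(cfg_default, "subsequent_minus30")
  bc <- run_base_case(cfg_default)
  # cheaper, shorter subsequent treatment lowers every total cost
  expect_true(all(dn$results$total_cost < bc$results$total_cost))
  expect_error(run_scenario(cfg_default, "unknown"), "arg")
})
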