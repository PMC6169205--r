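test_that("annual drug and dialysis costs match hand arithmetic", {
  # dose * price * 365 on the base-case inputs
  expect_equal(annual_drug_cost(2.184, 5.0069), 2.184 * 5.0069 * 365)
  expect_equal(round(annual_drug_cost(2.184, 5.0069), 2), 3991.30)
  expect_equal(round(annual_drug_cost(2.950, 0.0871), 2), 93.78)
  expect_equal(annual_drug_cost(0, 99), 0)
  expect_error(annual_drug_cost(-1, 1), "non-negative")

  ci <- cost_inputs()
  expect_equal(annual_dialysis_cost(ci),
               0.88 * 156 * 259.09 + 0.12 * 365 * 99.04)
  expect_equal(round(annual_dialysis_cost(ci), 2), 39905.83)
  ci_hd0 <- cost_inputs(hd_cost_rm_per_session = 0, hd_share = 1,
                        capd_share = 0)
  expect_equal(annual_dialysis_cost(ci_hd0), 0)
  ci_capd <- cost_inputs(hd_share = 0, capd_share = 1)
  expect_equal(annual_dialysis_cost(ci_capd), 365 * 99.04)
  expect_error(cost_inputs(hd_share = 0.7, capd_share = 0.2), "equal 1")
})

test_that("discount factors follow (1+r)^-t", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0, 17), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(round(discount_factor(0.03, 1), 6), 0.970874)
  expect_error(discount_factor(-0.01, 1))
})

test_that("a single predialysis cycle accrues one life-year and one year
           of drug cost", {
  occ <- rbind(c(1, 0, 0), c(0, 0, 1))
  out <- value_trace(make_trace(occ), cost_inputs(), utility_inputs(),
                     discount_spec(0, 0))
  expect_equal(out$ly, 1)
  expect_equal(out$qaly, 0.86)
  expect_equal(out$cost_rm, annual_drug_cost(2.184, 5.0069))
})

test_that("QALYs equal life-years exactly when both utilities are one", {
  occ <- rbind(c(1, 0, 0), c(0.6, 0.3, 0.1), c(0.2, 0.4, 0.4))
  out <- value_trace(make_trace(occ), cost_inputs(),
                     utility_inputs(1, 1), discount_spec())
  expect_equal(out$qaly, out$ly)
  expect_equal(out$qaly_undisc, out$ly_undisc)
})

test_that("a two-cycle split trace equals the hand-computed weighted sum", {
  ci <- cost_inputs(drug_dose_g_per_day = c(sevelamer = 1, caco3 = 1),
                    drug_price_rm_per_g = c(sevelamer = 1, caco3 = 1),
                    hd_cost_rm_per_session = 10, hd_sessions_per_year = 100,
                    capd_cost_rm_per_day = 0, capd_days_per_year = 365,
                    hd_share = 1, capd_share = 0)
  # drug 365/yr, dialysis 1000/yr, binder continues on dialysis
  occ <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0, 0, 1))
  out <- value_trace(make_trace(occ), ci, utility_inputs(0.86, 0.8),
                     discount_spec(0.03, 0.03))
  expect_equal(out$cost_rm, 365 + (0.5 * 365 + 0.5 * (1000 + 365)) / 1.03)
  expect_equal(out$ly, 1 + 1 / 1.03)
  expect_equal(out$qaly, 0.86 + (0.5 * 0.86 + 0.5 * 0.8) / 1.03)
  expect_equal(out$cost_rm_undisc, 365 + 0.5 * 365 + 0.5 * 1365)
  # the binder switch removes drug cost from dialysis cycles
  ci_stop <- ci
  ci_stop$binder_continues_on_dialysis <- FALSE
  out2 <- value_trace(make_trace(occ), ci_stop, utility_inputs(),
                      discount_spec(0.03, 0.03))
  expect_equal(out2$cost_rm, 365 + (0.5 * 365 + 0.5 * 1000) / 1.03)
})

test_that("valuation is linear in unit costs and bounded by life-years", {
  tr <- run_cohort(const_schedule(0.15, 0.25, 40))
  ci <- cost_inputs()
  ci2 <- cost_inputs(
    drug_dose_g_per_day = ci$drug_dose_g_per_day * 2,
    drug_price_rm_per_g = ci$drug_price_rm_per_g,
    hd_cost_rm_per_session = ci$hd_cost_rm_per_session * 2,
    capd_cost_rm_per_day = ci$capd_cost_rm_per_day * 2
  )
  a <- value_trace(tr, ci)
  b <- value_trace(tr, ci2)
  expect_equal(b$cost_rm, 2 * a$cost_rm, tolerance = 1e-12)
  expect_lt(a$qaly, a$ly)
  expect_lte(a$cost_rm, a$cost_rm_undisc)
  expect_lte(a$ly, a$ly_undisc)
  # zero dialysis cost strictly reduces total cost when dialysis occurs
  ci0 <- cost_inputs(hd_cost_rm_per_session = 0, capd_cost_rm_per_day = 0)
  expect_lt(value_trace(tr, ci0)$cost_rm, a$cost_rm)
})

test_that("half-cycle correction averages adjacent occupancies", {
  occ <- rbind(c(1, 0, 0), c(0, 0, 1))
  out <- value_trace(make_trace(occ), cost_inputs(), utility_inputs(),
                     discount_spec(0, 0), half_cycle_correction = TRUE)
  expect_equal(out$ly, 0.5)
  expect_equal(out$qaly, 0.43)
})

test_that("per-cycle valuation tables are exposed on request", {
  tr <- run_cohort(const_schedule(0.2, 0.2, 5))
  out <- value_trace(tr, keep_cycles = TRUE)
  cyc <- attr(out, "cycles")
  expect_equal(nrow(cyc), 5)
  expect_equal(sum(cyc$cost_rm * cyc$discount_costs), out$cost_rm)
  expect_equal(sum(cyc$qaly * cyc$discount_outcomes), out$qaly)
})
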