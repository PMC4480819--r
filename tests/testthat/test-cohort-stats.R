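test_that("pooled response rate pools counts and is invariant to grouping", {
  fx <- load_outcome_fixture()
  r3 <- pooled_response_rate(data.frame(responders = fx$responders_3m,
                                        evaluable = fx$evaluable_3m))
  expect_equal(r3$responders, 30)
  expect_equal(r3$evaluable, 74)
  expect_equal(round(r3$rate_pct), 41)
  # order and merging invariance
  shuffled <- data.frame(responders = rev(fx$responders_3m),
                         evaluable = rev(fx$evaluable_3m))
  expect_equal(pooled_response_rate(shuffled)$rate_pct, r3$rate_pct)
  merged <- data.frame(responders = sum(fx$responders_3m),
                       evaluable = sum(fx$evaluable_3m))
  expect_equal(pooled_response_rate(merged)$rate_pct, r3$rate_pct)
  expect_equal(pooled_response_rate(data.frame(responders = 0, evaluable = 10))$rate_pct, 0)
  expect_error(pooled_response_rate(data.frame(responders = 0, evaluable = 0)),
               "evaluable")
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  k <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$surv, c(2/3, 1/3, 0))
  expect_equal(k$median, 2)
  # no events: flat at 1, median not reached
  k0 <- km_curve(c(4, 8, 15), c(0, 0, 0))
  expect_true(all(k0$surv == 1))
  expect_true(is.na(k0$median))
  # censoring removes subjects from the risk set
  kc <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(kc$surv[kc$time == 1], 2/3)
  expect_equal(kc$surv[kc$time == 3], 0)  # risk set of one at t = 3
  expect_error(km_curve(numeric(0), logical(0)), "empty")
})

test_that("Kaplan-Meier equals the empirical survivor function without censoring", {
  set.seed(31)
  times <- rexp(40, 0.1)
  k <- km_curve(times, rep(1, 40))
  for (t in k$time) {
    expect_equal(k$surv[k$time == t], ref_empirical_surv(times, t), tolerance = 1e-12)
  }
})

test_that("log-rank matches the brute-force hypergeometric tabulation", {
  g1 <- list(times = c(1, 2, 3), events = c(1, 1, 1))
  g2 <- list(times = c(10, 20, 30), events = c(1, 1, 1))
  got <- logrank(list(g1, g2))
  ref <- ref_logrank2(g1$times, g1$events, g2$times, g2$events)
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-9)
  expect_equal(got$df, 1)
  # the two-group statistic is the squared standardized O - E
  expect_equal(got$statistic, ref$o_minus_e^2 / ref$var, tolerance = 1e-9)

  set.seed(17)
  t1 <- round(rexp(15, 0.1), 1); e1 <- rbinom(15, 1, 0.8)
  t2 <- round(rexp(15, 0.2), 1); e2 <- rbinom(15, 1, 0.8)
  got2 <- logrank(list(list(times = t1, events = e1), list(times = t2, events = e2)))
  ref2 <- ref_logrank2(t1, e1, t2, e2)
  expect_equal(got2$statistic, ref2$statistic, tolerance = 1e-9)

  # identical groups: statistic 0, p = 1
  same <- logrank(list(g1, g1))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  expect_error(logrank(list(g1)), "two groups")
  expect_error(logrank(list(g1, list(times = numeric(0), events = numeric(0)))),
               "at least one subject")
})

test_that("stratified log-rank pools over strata and reduces to unstratified", {
  g1 <- list(times = c(2, 4, 6, 9), events = c(1, 1, 0, 1))
  g2 <- list(times = c(5, 7, 8, 12), events = c(1, 0, 1, 1))
  one_stratum <- logrank(list(g1, g2),
                         strata = list(rep("a", 4), rep("a", 4)))
  plain <- logrank(list(g1, g2))
  expect_equal(one_stratum$statistic, plain$statistic, tolerance = 1e-9)
  # two genuine strata: pooled O-E and V across strata
  st <- list(c("a", "a", "b", "b"), c("a", "b", "b", "a"))
  pooled <- logrank(list(g1, g2), strata = st)
  # stratum a: g1 subjects 1,2 and g2 subjects 1,4; stratum b: the rest
  oa <- ref_logrank2(c(2, 4), c(1, 1), c(5, 12), c(1, 1))
  ob <- ref_logrank2(c(6, 9), c(0, 1), c(7, 8), c(0, 1))
  pooled_ref <- (oa$o_minus_e + ob$o_minus_e)^2 / (oa$var + ob$var)
  expect_equal(pooled$statistic, pooled_ref, tolerance = 1e-9)
})

test_that("chi-squared reproduces textbook values and brute force", {
  flat <- chi_squared_rxc(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  set.seed(23)
  for (rep in 1:6) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    m <- matrix(rpois(r * c, 8) + 1, r, c)
    got <- chi_squared_rxc(m)
    ref <- ref_chisq(m)
    expect_equal(got$statistic, ref$statistic, tolerance = 1e-9)
    expect_equal(got$df, ref$df)
    expect_equal(got$p, pchisq(ref$statistic, ref$df, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
  expect_error(chi_squared_rxc(matrix(c(0, 0, 1, 2), 2, 2)), "margins")
  expect_error(chi_squared_rxc(matrix(1:3, 3, 1)), "2 x 2")
})

test_that("between-group outcome tables reproduce the published p-values", {
  fx <- load_outcome_fixture()
  p_resp <- chi_squared_rxc(fixture_response_table_3m(fx))$p
  p_tox <- chi_squared_rxc(fixture_toxicity_table(fx))$p
  expect_equal(round(p_resp, 3), 0.098)
  expect_equal(round(p_tox, 3), 0.022)
})

test_that("rank comparison uses exact Mann-Whitney for tiny samples", {
  same <- rank_compare(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$p, 1)
  tiny <- rank_compare(list(c(1, 2), c(3, 4)))
  expect_equal(tiny$statistic, 0)       # U at its extreme
  expect_equal(tiny$p, 1/3)             # 2 of 6 rank assignments as extreme
  expect_identical(tiny$method, "mann-whitney")
  three <- rank_compare(list(rnorm(10), rnorm(10), rnorm(10)))
  expect_identical(three$method, "kruskal-wallis")
  expect_true(three$p >= 0 && three$p <= 1)
  expect_error(rank_compare(list(1:3)), "two groups")
  expect_error(rank_compare(list(1:3, numeric(0))), "empty")
})

test_that("toxicity grade change is the per-lab floored maximum increase", {
  expect_equal(toxicity_grade_change(1, 3), 2)
  expect_equal(toxicity_grade_change(c(3, 2), c(2, 2)), 0)
  expect_equal(toxicity_grade_change(c(0, 2), c(1, 2)), 1)
  expect_error(toxicity_grade_change(c(0, 5), c(1, 2)), "0..4")
  expect_error(toxicity_grade_change(c(0, 1), c(1)), "panels")
})

test_that("REILD banding uses strict outer boundaries and flags empty bands", {
  rec <- data.frame(d_fl_tot = c(rep(70, 13), rep(45, 4)),
                    prior_liver_dose = 0,
                    reild = c(rep(TRUE, 5), rep(FALSE, 12)))
  s <- reild_band_summary(rec)
  hi <- s[s$band == ">60", ]
  expect_equal(hi$n, 13)
  expect_equal(round(hi$incidence_pct, 1), 38.5)
  expect_true(is.na(s$incidence_pct[s$band == "<30"]))  # empty band: missing
  # boundaries 30 and 60 belong to the middle band; prior dose shifts bands
  rec2 <- data.frame(d_fl_tot = c(30, 60, 29.99, 60.01),
                     prior_liver_dose = c(0, 0, 0, 0),
                     reild = FALSE)
  s2 <- reild_band_summary(rec2)
  expect_equal(s2$n[s2$band == "30-60"], 2)
  expect_equal(s2$n[s2$band == "<30"], 1)
  expect_equal(s2$n[s2$band == ">60"], 1)
  expect_equal(s2$incidence_pct[s2$band == ">60"], 0)
  rec3 <- data.frame(d_fl_tot = 25, prior_liver_dose = 40, reild = FALSE)
  expect_equal(reild_band_summary(rec3)$n[3], 1)  # cumulative 65 Gy
})
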