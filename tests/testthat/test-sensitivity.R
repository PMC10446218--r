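test_that("moment fits hit the requested mean and spread", {
  b <- fit_distribution(0.189, 0.1701, 0.2079, "beta")
  expect_equal(b$mean, 0.189)
  expect_equal(b$sd, (0.2079 - 0.1701) / (2 * 1.96))
  expect_equal(b$sd, 0.009643, tolerance = 1e-4)
  # fitted beta moments equal the targets analytically
  m <- b$shape1 / (b$shape1 + b$shape2)
  v <- b$shape1 * b$shape2 /
    ((b$shape1 + b$shape2)^2 * (b$shape1 + b$shape2 + 1))
  expect_equal(m, 0.189, tolerance = 1e-9)
  expect_equal(v, b$sd^2, tolerance = 1e-12)

  g <- fit_distribution(13.46, 12.114, 14.806, "gamma")
  expect_equal(g$sd, 0.6867, tolerance = 1e-4)
  expect_equal(g$shape * g$scale, 13.46, tolerance = 1e-9)
  expect_equal(g$shape * g$scale^2, g$sd^2, tolerance = 1e-12)

  # zero-width range: point mass, every draw equals the base
  d <- fit_distribution(0.5, 0.5, 0.5, "beta")
  expect_true(d$degenerate)
  expect_equal(draw_distribution(d, 5), rep(0.5, 5))

  expect_error(fit_distribution(0.2, 0.3, 0.4, "beta"), "does not contain")
  expect_error(fit_distribution(0.01, 0, 0.4, "beta"), "beta fit impossible")
  expect_error(fit_distribution(0, -1, 1, "gamma"), "positive mean")
})

test_that("sampled parameter means converge to their base values", {
  sc <- paper_fixture("whole_group")
  tab <- parameter_table(sc)
  tab <- tab[!tab$complement & tab$param != "discount_rate", ]
  set.seed(99)
  n <- 1000
  for (i in seq_len(nrow(tab))) {
    d <- fit_distribution(tab$base[i], tab$low[i], tab$high[i], tab$dist[i])
    x <- draw_distribution(d, n)
    # within 3 Monte-Carlo standard errors (99.7% of seeds)
    expect_lt(abs(mean(x) - tab$base[i]), 3 * d$sd / sqrt(n) + 1e-12,
              label = sprintf("mean of %s", tab$param[i]))
  }
})

test_that("every parameter at its base value reproduces the base-case ICER", {
  sc <- paper_fixture("whole_group")
  base_icer <- compare_strategies(sc)$icer$icer
  tab <- parameter_table(sc)
  for (i in seq_len(nrow(tab))) {
    sc_i <- apply_parameter(sc, tab$param[i], tab$base[i])
    expect_equal(compare_strategies(sc_i)$icer$icer, base_icer,
                 tolerance = 1e-8, label = tab$param[i])
  }
})

test_that("the tornado is sorted, complete, and flags zero-width bars", {
  sc <- paper_fixture("whole_group")
  dsa <- one_way_dsa(sc)
  expect_equal(nrow(dsa), nrow(parameter_table(sc)))
  expect_true(all(diff(dsa$bar_width) <= 1e-12))
  expect_false(any(dsa$flagged))
  # a zero-width range gives a zero-width bar
  sc0 <- sc
  sc0$shared_ranges$u_relapse <- c(0.5, 0.5)
  row <- one_way_dsa(sc0, params = "u_relapse")
  expect_equal(row$bar_width, 0)
  expect_error(one_way_dsa(sc, params = "nope"), "unknown parameter")
})

test_that("the remission self-transition of the intervention dominates the tornado", {
  dsa <- one_way_dsa(paper_fixture("whole_group"))
  expect_equal(dsa$param[1], "nc.p_rr")
})

test_that("PSA is bit-reproducible under a fixed seed", {
  sc <- paper_fixture("whole_group")
  a <- run_psa(sc, n_draws = 40, seed = 123)
  b <- run_psa(sc, n_draws = 40, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$quadrants, b$quadrants)
  c_ <- run_psa(sc, n_draws = 40, seed = 124)
  expect_false(identical(a$draws$delta_cost, c_$draws$delta_cost))
})

test_that("degenerate distributions collapse the PSA onto the base case", {
  sc <- degenerate_scenario(paper_fixture("whole_group"))
  base <- compare_strategies(sc)
  psa <- run_psa(sc, n_draws = 8, seed = 5)
  expect_equal(psa$draws$cost_a, rep(base$strategies$total_cost[1], 8),
               tolerance = 1e-10)
  expect_equal(psa$draws$qaly_b, rep(base$strategies$total_qaly[2], 8),
               tolerance = 1e-10)
  expect_true(all(psa$quadrants %in% c(0, 1)))
})

test_that("quadrant fractions sum to one and respect the WTP line", {
  sc <- paper_fixture("whole_group")
  psa <- run_psa(sc, n_draws = 60, seed = 21)
  expect_equal(sum(psa$quadrants), 1)
  d <- psa$draws
  frac_dominant <- mean(d$delta_qaly > 0 & d$delta_cost < 0)
  expect_equal(unname(psa$quadrants["dominant"]), frac_dominant)
  # identical arms land in the indifferent bucket
  twin <- generate_scenario(seed = 3, identical_arms = TRUE)
  twin <- degenerate_scenario(twin)
  psa_t <- run_psa(twin, n_draws = 5, seed = 1)
  expect_equal(unname(psa_t$quadrants["indifferent"]), 1)
})

test_that("acceptability curves are proper complementary probabilities", {
  sc <- paper_fixture("whole_group")
  psa <- run_psa(sc, n_draws = 60, seed = 8)
  cc <- ceac(psa)
  expect_equal(cc$prob_a + cc$prob_b, rep(1, nrow(cc)))
  expect_true(all(cc$prob_a >= 0 & cc$prob_a <= 1))
  # at WTP 0 the curve reduces to the probability of being cheaper
  cc0 <- ceac(psa, wtp_grid = 0)
  expect_equal(cc0$prob_a,
               mean(psa$draws$cost_a < psa$draws$cost_b) +
                 0.5 * mean(psa$draws$cost_a == psa$draws$cost_b))
  expect_error(ceac(psa, wtp_grid = numeric()), "non-empty")
})

test_that("PSA favours the intervention at the study threshold", {
  psa <- run_psa(paper_fixture("whole_group"), n_draws = 200, seed = 14)
  favour_a <- mean(psa$draws$nmb_a > psa$draws$nmb_b)
  expect_gt(favour_a, 0.5)
})

test_that("sensitivity plots build without error", {
  sc <- paper_fixture("whole_group")
  dsa <- one_way_dsa(sc, params = c("nc.p_rr", "u_remission", "lc.p_pd"))
  psa <- run_psa(sc, n_draws = 30, seed = 2)
  expect_s3_class(plot_tornado(dsa), "ggplot")
  expect_s3_class(plot_ce_plane(psa), "ggplot")
  expect_s3_class(plot_ceac(ceac(psa), names = psa$names), "ggplot")
})
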