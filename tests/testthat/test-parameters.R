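test_that("the whole-group fixture carries the published clinical values", {
  sc <- paper_fixture("whole_group")
  nc <- sc$strategies$nc
  lc <- sc$strategies$lc
  expect_equal(nc$clinical$rr, 0.63)
  expect_equal(nc$clinical$os_months, 24)
  expect_equal(nc$clinical$pfs_months, 8.8)
  expect_equal(nc$clinical$dor_months, 8.5)
  expect_equal(lc$clinical$rr, 0.7)
  expect_equal(lc$clinical$os_months, 22)
  expect_equal(lc$clinical$pfs_months, 6.6)
  expect_equal(lc$clinical$dor_months, 5.6)
  expect_equal(nc$utilities$remission, 0.85)
  expect_equal(nc$utilities$relapse, 0.5)
  expect_equal(nc$utilities$stable, 0.74)
  expect_equal(nc$utilities$death, 0)
  # unit prices and one-time schedule inputs
  dn <- nc$costs$dosing
  expect_equal(dn$unit_price_usd[dn$drug == "neratinib"], 13.46)
  expect_equal(dn$unit_price_usd[dn$drug == "capecitabine"], 0.6)
  dl <- lc$costs$dosing
  expect_equal(dl$unit_price_usd[dl$drug == "lapatinib"], 16.12)
  expect_equal(nc$costs$bsa_m2, 1.67)
  expect_equal(nc$costs$loperamide$unit_price_usd, 0.23)
  expect_null(lc$costs$loperamide)
  # adverse-event incidences
  expect_equal(
    nc$costs$ae_profile$incidence,
    c(0.307, 0.120, 0.050, 0.037, 0.024))
  expect_equal(
    lc$costs$ae_profile$incidence,
    c(0.143, 0.138, 0.024, 0.040, 0.044))
  # settings
  expect_equal(sc$settings$cycle_days, 21)
  expect_equal(sc$settings$annual_discount_rate, 0.03)
  expect_equal(sc$settings$wtp_per_qaly, 36000)
  expect_equal(n_cycles(sc$settings), 86L)
})

test_that("the subgroup fixture carries the published subgroup medians", {
  sc <- paper_fixture("asian_subgroup")
  expect_equal(sc$strategies$nc$clinical$os_months, 23.8)
  expect_equal(sc$strategies$nc$clinical$pfs_months, 7.0)
  expect_equal(sc$strategies$nc$clinical$dor_months, 11.1)
  expect_equal(sc$strategies$lc$clinical$os_months, 18.7)
  expect_equal(sc$strategies$lc$clinical$pfs_months, 5.4)
  expect_equal(sc$strategies$lc$clinical$dor_months, 4.2)
  # risk fractions are derived when not supplied
  expect_equal(sc$strategies$nc$clinical$rr, (23.8 - 7) / 23.8)
  expect_error(paper_fixture("something_else"))
})

test_that("clinical_summary enforces OS > PFS > 0 and rr in (0,1)", {
  expect_error(clinical_summary(os_months = 5, pfs_months = 6,
                                dor_months = 3),
               "must exceed")
  expect_error(clinical_summary(os_months = 5, pfs_months = -1,
                                dor_months = 3))
  expect_error(clinical_summary(os_months = 5, pfs_months = 2,
                                dor_months = 0))
  expect_error(clinical_summary(os_months = 5, pfs_months = 2,
                                dor_months = 2, rr = 1.2))
  expect_warning(clinical_summary(os_months = 24, pfs_months = 8.8,
                                  dor_months = 8.5, rr = 0.4),
                 "differs")
})

test_that("utility and cost constructors reject out-of-domain values", {
  expect_error(utility_set(stable = 1.2), "outside")
  expect_error(utility_set(death = 0.1), "fixed at 0")
  sc <- paper_fixture("whole_group")
  cs <- sc$strategies$nc$costs
  bad <- cs$dosing
  bad$unit_price_usd[1] <- -1
  expect_error(cost_schedule(bad, cs$ae_profile, cs$other_costs), ">= 0")
  bad_ae <- cs$ae_profile
  bad_ae$incidence[1] <- 1.4
  expect_error(cost_schedule(cs$dosing, bad_ae, cs$other_costs), "\\[0, 1\\]")
})

test_that("config save/load round-trips are the identity on all fields", {
  sc <- paper_fixture("whole_group")
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(sc, path)
  sc2 <- load_config(path)
  expect_equal(sc2, sc, tolerance = 1e-12)

  syn <- generate_scenario(seed = 7)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  save_config(syn, path2)
  expect_equal(load_config(path2), syn, tolerance = 1e-12)
})

test_that("shipped configs match the in-code fixtures byte for byte", {
  for (nm in c("whole_group", "asian_subgroup")) {
    shipped <- system.file("extdata", paste0(nm, ".yaml"),
                           package = "mbcmarkov")
    expect_true(nzchar(shipped))
    tmp <- withr::local_tempfile(fileext = ".yaml")
    save_config(paper_fixture(nm), tmp)
    expect_identical(readLines(tmp), readLines(shipped))
  }
})

test_that("load_config rejects broken configs with a named field", {
  expect_error(load_config("no/such/file.yaml"), "does not exist")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("schema: something-else", tmp)
  expect_error(load_config(tmp), "schema")
  # OS <= PFS caught on load
  sc <- paper_fixture("whole_group")
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(sc, path)
  txt <- readLines(path)
  txt <- sub("os_months: 24.*", "os_months: 5.0", txt)
  writeLines(txt, tmp)
  expect_error(load_config(tmp), "exceed")
})

test_that("every sensitivity range contains its base value", {
  for (nm in c("whole_group", "asian_subgroup")) {
    tab <- parameter_table(paper_fixture(nm))
    expect_true(all(tab$base >= tab$low - 1e-9))
    expect_true(all(tab$base <= tab$high + 1e-9))
    expect_true(all(tab$dist %in% c("beta", "gamma")))
    # distribution family matches parameter kind
    is_cost <- grepl("^price_|^cost_", tab$param)
    expect_true(all(tab$dist[is_cost] == "gamma"))
    expect_true(all(tab$dist[!is_cost] == "beta"))
  }
})

test_that("apply_parameter routes shared and arm-scoped parameters", {
  sc <- paper_fixture("whole_group")
  sc2 <- apply_parameter(sc, "u_remission", 0.7)
  expect_equal(sc2$strategies$nc$utilities$remission, 0.7)
  expect_equal(sc2$strategies$lc$utilities$remission, 0.7)

  sc3 <- apply_parameter(sc, "price_capecitabine", 1)
  for (id in c("nc", "lc")) {
    d <- sc3$strategies[[id]]$costs$dosing
    expect_equal(d$unit_price_usd[d$drug == "capecitabine"], 1)
  }

  # complement mapping: setting the remission self-transition adjusts p_rp
  sc4 <- apply_parameter(sc, "nc.p_rr", 0.9)
  pr <- derive_transition_probs(sc4$strategies$nc$clinical,
                                overrides = sc4$strategies$nc$prob_overrides)
  expect_equal(pr$p_rp, 0.1)
  # setting the stable self-transition rescales both exits proportionally
  sc5 <- apply_parameter(sc, "nc.p_ss", 0.5)
  pr5 <- derive_transition_probs(sc5$strategies$nc$clinical,
                                 overrides = sc5$strategies$nc$prob_overrides)
  expect_equal(pr5$p_sr + pr5$p_sp, 0.5)
  pr0 <- derive_transition_probs(sc$strategies$nc$clinical)
  expect_equal(pr5$p_sr / pr5$p_sp, pr0$p_sr / pr0$p_sp)

  expect_error(apply_parameter(sc, "nonsense", 1), "unrecognized")
  expect_error(apply_parameter(sc, "nc.inc_gout", 0.1), "unknown adverse event")
})

test_that("parameter CSV export mirrors the parameter table", {
  sc <- paper_fixture("whole_group")
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_parameter_csv(sc, tmp)
  back <- read.csv(tmp)
  expect_equal(nrow(back), nrow(parameter_table(sc)))
  expect_true(all(c("param", "base", "low", "high", "dist") %in% names(back)))
})
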