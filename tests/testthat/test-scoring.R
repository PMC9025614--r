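test_that("orthokeratosis degree is the percentual A/B ratio", {
  expect_equal(orthokeratosis_degree(0, 350), 0)
  expect_equal(orthokeratosis_degree(350, 350), 100)
  expect_equal(orthokeratosis_degree(175, 500), 35)
  expect_error(orthokeratosis_degree(10, 0), "B_um")
  expect_error(orthokeratosis_degree(11, 10), "A_um")
})

test_that("orthokeratosis degree is scale-invariant", {
  set.seed(12)
  for (i in 1:50) {
    B <- runif(1, 1, 1000); A <- runif(1, 0, B); c_ <- runif(1, 0.01, 100)
    expect_equal(orthokeratosis_degree(c_ * A, c_ * B),
                 orthokeratosis_degree(A, B))
  }
})

test_that("mean epidermal thickness averages valid readings", {
  expect_equal(mean_epidermal_thickness(rep(30, 5)), 30)
  expect_equal(mean_epidermal_thickness(c(20, 25, 30, 35, 40)), 30)
  expect_equal(mean_epidermal_thickness(c(20, NA, 40)), 30)
  expect_error(mean_epidermal_thickness(numeric(0)), "no valid")
  expect_error(mean_epidermal_thickness(c(NA_real_, NA_real_)), "no valid")
  expect_error(mean_epidermal_thickness(c(10, -1)), "> 0")
})

test_that("drug activity reproduces the published worked examples", {
  # (Oks - Okc) / (100 - Okc) * 100 against the vehicle control mean 19.64
  expect_equal(round(drug_activity(56.48, 19.64), 2), 45.84)
  expect_equal(round(drug_activity(48.72, 19.64), 2), 36.19)
  expect_equal(drug_activity(19.64, 19.64), 0)
  expect_equal(drug_activity(100, 19.64), 100)
})

test_that("drug activity properties: monotone in Oks, zero at the control, unclipped", {
  set.seed(3)
  for (i in 1:30) {
    Okc <- runif(1, 0, 99)
    o <- sort(runif(5, 0, 100))
    a <- drug_activity(o, Okc)
    expect_true(all(diff(a) > 0))           # strictly increasing
    expect_equal(drug_activity(Okc, Okc), 0)
  }
  expect_lt(drug_activity(10, 50), 0)       # worsening is reported as computed
  expect_error(drug_activity(50, 100), "Okc")
  expect_error(drug_activity(101, 50), "Oks")
})

test_that("summarize_groups reproduces the published drug-activity column at zero variance", {
  specs <- lapply(default_study_specs(), function(s) {
    s$ok_sd <- 0; s$thick_sd <- 0; s
  })
  tab <- generate_study(specs, seed = 1)
  s <- summarize_groups(tab, control_group = "white soft paraffin",
                        activity_exclude = "untreated mice")
  act <- setNames(round(s$drug_activity, 2), s$group)
  expect_equal(act[["tretinoin 0.05%"]], 36.19)
  expect_equal(act[["diclofenac 1%"]], 28.12)
  expect_equal(act[["diclofenac 2%"]], 27.10)
  expect_equal(act[["celecoxib 1%"]], 28.01)
  expect_equal(act[["celecoxib 2%"]], 45.84)
  expect_identical(act[["white soft paraffin"]], 0)
  expect_true(is.na(act[["untreated mice"]]))
  # zero-variance thickness summaries sit exactly at the spec means
  expect_equal(s$thick_mean[s$group == "untreated mice"], 24.77)
})

test_that("group summaries use sample SD, honor the unit switch and ignore row order", {
  specs <- default_study_specs()[c("white soft paraffin", "celecoxib 2%")]
  tab <- generate_study(specs, seed = 21)
  s <- summarize_groups(tab, control_group = "white soft paraffin")

  sub <- tab[tab$group == "celecoxib 2%", ]
  deg <- 100 * sub$A_um / sub$B_um
  expect_equal(s$ok_sd[s$group == "celecoxib 2%"], sd(deg))   # n - 1
  expect_equal(s$n_scales, c(60L, 60L))
  expect_equal(s$n_thickness, c(300L, 300L))

  shuffled <- tab[sample(nrow(tab)), ]
  sh <- summarize_groups(shuffled, "white soft paraffin")
  expect_equal(sh[order(sh$group), ], s[order(s$group), ],
               ignore_attr = TRUE)

  sa <- summarize_groups(tab, "white soft paraffin", unit = "animal")
  expect_equal(sa$ok_mean[2], mean(tapply(deg, sub$animal, mean)))
  expect_equal(sa$ok_sd[2], sd(tapply(deg, sub$animal, mean)))

  expect_error(summarize_groups(tab, "nonexistent"), "control group")
})

test_that("single-group table equal to its own control yields zero activity", {
  spec <- default_study_specs()[["white soft paraffin"]]
  tab <- generate_measurements(spec, seed = 4)
  s <- summarize_groups(tab, control_group = spec$name)
  expect_identical(s$drug_activity, 0)
  expect_gte(s$ok_sd, 0)
})

test_that("animal-level bootstrap brackets the drug-activity point estimate", {
  specs <- default_study_specs()[c("white soft paraffin", "celecoxib 2%",
                                   "untreated mice")]
  tab <- generate_study(specs, seed = 14)
  bs <- drug_activity_bootstrap(tab, "white soft paraffin",
                                activity_exclude = "untreated mice",
                                n_boot = 500, seed = 2)
  expect_equal(bs$group, "celecoxib 2%")
  expect_lt(bs$lower, bs$drug_activity)
  expect_gt(bs$upper, bs$drug_activity)
  # the point estimate is the animal-level drug activity
  s <- summarize_groups(tab, "white soft paraffin", unit = "animal")
  expect_equal(bs$drug_activity,
               drug_activity(s$ok_mean[s$group == "celecoxib 2%"],
                             s$ok_mean[s$group == "white soft paraffin"]))
  # deterministic given the seed
  bs2 <- drug_activity_bootstrap(tab, "white soft paraffin",
                                 activity_exclude = "untreated mice",
                                 n_boot = 500, seed = 2)
  expect_equal(bs, bs2)
})

test_that("summary renders as a mean +/- SD table, rounding half away from zero", {
  # exact binary halves: banker's rounding would give 0.12 and 2.12
  expect_equal(tailmorph:::round_half_up(0.125, 2), 0.13)
  expect_equal(tailmorph:::round_half_up(-0.125, 2), -0.13)
  expect_equal(tailmorph:::round_half_up(2.125, 2), 2.13)

  s <- data.frame(group = c("a", "b"), ok_mean = c(17.7, 45.8437),
                  ok_sd = c(1.81, 2), thick_mean = c(24.77, 30),
                  thick_sd = c(2.43, 1), drug_activity = c(NA, 45.8437),
                  n_scales = c(60L, 60L), n_thickness = c(300L, 300L))
  md <- format_summary_table(s)
  expect_match(md[3], "17.70 ± 1.81", fixed = TRUE)
  expect_match(md[4], "45.84", fixed = TRUE)
  expect_false(grepl("NA", md[3]))
})
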