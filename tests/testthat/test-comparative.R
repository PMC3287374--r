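test_that("venue_screen: skip on single venue, null calibration, power", {
  df <- tiny_cases()
  df$venue <- "laboratory"
  expect_s3_class(venue_screen(df), "stage_skip")

  # null: no venue effect, no phylogenetic signal -> uniform p (KS)
  pvals <- numeric(200)
  for (i in 1:200) {
    prm <- sim_params(n_species = 16, n_polytomy_species = 0,
                      sigma2_bm = 0, delta_log_rate = 0,
                      delta_log_mass = 0, group_assignment = "random",
                      seed = 3000 + i)
    sim <- simulate_dataset(prm)
    vs <- venue_screen(sim$cases)
    pvals[i] <- vs$p[vs$trait == "log10_dev_rate"]
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # power: a venue shift of 3 residual SDs (0.15 on log10 period, given
  # case_sd_log10 = 0.05) is detected in > 90% of simulations
  hits <- 0L
  for (i in 1:100) {
    prm <- sim_params(n_species = 16, n_polytomy_species = 0,
                      sigma2_bm = 0, delta_log_rate = 0,
                      delta_log_mass = 0, group_assignment = "random",
                      seed = 4000 + i)
    sim <- simulate_dataset(prm)
    cases <- sim$cases
    meso <- cases$venue == "mesocosm"
    if (!any(meso) || all(meso)) next
    cases$period_mean[meso] <- cases$period_mean[meso] * 10^0.15
    vs <- venue_screen(cases)
    hits <- hits + (vs$p[vs$trait == "log10_dev_rate"] < 0.05)
  }
  expect_gt(hits / 100, 0.90)
})

test_that("compare_groups surfaces data problems cleanly", {
  sim <- simulate_dataset(sim_params(n_species = 10,
                                     n_polytomy_species = 0, seed = 20))
  # species missing from the tree
  pruned <- ape::drop.tip(sim$tree, sim$tree$tip.label[1])
  expect_error(compare_groups(sim$cases, pruned, "log10_dev_rate"),
               "missing from tree")
  # constant trait vector -> degenerate fit error propagated
  cases <- sim$cases
  cases$mass_mean <- 1
  expect_error(compare_groups(cases, sim$tree, "log10_mass"),
               "degenerate|rank deficient")
})

test_that("conventional results never read the tree's branch lengths", {
  sim <- simulate_dataset(sim_params(n_species = 12,
                                     n_polytomy_species = 3,
                                     cases_per_polytomy = 3, seed = 21))
  mc1 <- compare_groups(sim$cases, sim$tree, "log10_dev_rate")
  # a different (random) topology over the same species
  alt <- simulate_tree(12, seed = 99,
                       labels = sample(sim$tree$tip.label))
  mc2 <- compare_groups(sim$cases, alt, "log10_dev_rate")
  s1 <- mc1$tests[mc1$tests$model == "star", ]
  s2 <- mc2$tests[mc2$tests$model == "star", ]
  expect_equal(s1$estimate, s2$estimate, tolerance = 1e-12)
  expect_equal(s1$se, s2$se, tolerance = 1e-12)
  expect_equal(aic(mc1$fits$star), aic(mc2$fits$star), tolerance = 1e-12)
})

test_that("stage outputs are invariant to case ordering", {
  sim <- simulate_dataset(sim_params(n_species = 12,
                                     n_polytomy_species = 3, seed = 22))
  set.seed(23)
  shuffled <- sim$cases[sample(nrow(sim$cases)), ]
  for (fun in list(
    function(cs) compare_groups(cs, sim$tree, "log10_mass"),
    function(cs) compare_plasticity(cs, sim$tree, "mass"),
    function(cs) plasticity_interaction(cs, sim$tree, "mass"))) {
    a <- fun(sim$cases)
    b <- fun(shuffled)
    expect_equal(a$aic, b$aic, tolerance = 1e-9)
    expect_equal(a$tests$estimate, b$tests$estimate, tolerance = 1e-9)
  }
})

test_that("ancova is consistent with compare_groups when covariate is idle", {
  # mass is generated independently of developmental rate, so adding the
  # covariate should not shift the risk estimate beyond MC error
  diffs <- numeric(100)
  for (i in 1:100) {
    sim <- simulate_dataset(sim_params(n_species = 16,
                                       n_polytomy_species = 0,
                                       delta_log_mass = 0.2, seed = 200 + i))
    m1 <- compare_groups(sim$cases, sim$tree, "log10_mass")
    m2 <- ancova_controlling_devtime(sim$cases, sim$tree, "log10_mass")
    e1 <- m1$tests[m1$tests$model == "grafen" &
                     m1$tests$coefficient == "riskHigh", "estimate"]
    e2 <- m2$tests[m2$tests$model == "grafen" &
                     m2$tests$coefficient == "riskHigh", "estimate"]
    diffs[i] <- e2 - e1
  }
  expect_lt(abs(mean(diffs)), 2 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("ancova: no spurious risk effect when trait follows the covariate", {
  hits <- 0L
  for (i in 1:100) {
    sim <- simulate_dataset(sim_params(n_species = 16,
                                       n_polytomy_species = 0,
                                       sigma2_bm = 0, delta_log_rate = 0,
                                       delta_log_mass = 0,
                                       group_assignment = "random",
                                       seed = 300 + i))
    cases <- sim$cases
    # mass an (almost) exact linear function of developmental time
    cases$mass_mean <- cases$period_mean^0.8 *
      10^rnorm(nrow(cases), 0, 0.01)
    m <- ancova_controlling_devtime(cases, sim$tree, "log10_mass")
    tt <- m$tests[m$tests$model == "star" &
                    m$tests$coefficient == "riskHigh", ]
    hits <- hits + (abs(tt$t) < 2)
  }
  expect_gte(hits / 100, 0.93)

  # perfectly collinear covariate and response -> rank error
  sim <- simulate_dataset(sim_params(n_species = 8, n_polytomy_species = 0,
                                     seed = 24))
  cases <- sim$cases
  # the covariate an exact function of risk: two distinct period values
  cases$period_mean <- ifelse(cases$risk_group == "High", 80, 40)
  expect_error(ancova_controlling_devtime(cases, sim$tree, "log10_mass"),
               "rank deficient")
})

test_that("compare_plasticity: skips and group-difference recovery", {
  # all drying rows absent -> skip
  sim <- simulate_dataset(sim_params(n_species = 10,
                                     n_polytomy_species = 0, seed = 25))
  dry_free <- sim$cases[sim$cases$treatment == "constant", ]
  expect_s3_class(compare_plasticity(dry_free, sim$tree, "dev_time"),
                  "stage_skip")
  # one group without enough paired cases -> skip
  few <- sim$cases
  paired_high <- unique(few$case_id[few$risk_group == "High"])
  drop <- few$case_id %in% paired_high[-(1:2)] & few$treatment == "drying"
  expect_s3_class(compare_plasticity(few[!drop, ], sim$tree, "dev_time"),
                  "stage_skip")

  # recovery of the injected group difference (-20 vs -5 => -15)
  est <- numeric(200)
  for (i in 1:200) {
    sim <- simulate_dataset(sim_params(n_species = 16,
                                       n_polytomy_species = 0,
                                       seed = 400 + i))
    mc <- compare_plasticity(sim$cases, sim$tree, "dev_time")
    est[i] <- mc$tests[mc$tests$model == "star" &
                         mc$tests$coefficient == "riskHigh", "estimate"]
  }
  mcse <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - (-15)), 2 * mcse)
})

test_that("plasticity_interaction: slopes, null calibration, skip", {
  sim <- simulate_dataset(sim_params(seed = 26))
  mc <- plasticity_interaction(sim$cases, sim$tree, "mass")
  sl <- attr(mc, "slopes")
  expect_named(sl, c("Low", "High"))
  # injected slopes: Low 0, High 1
  expect_lt(abs(sl[["Low"]]), 0.5)
  expect_gt(sl[["High"]], 0.5)

  # identical slopes -> interaction type-I error at or below nominal
  tstats <- numeric(200)
  rej <- 0L
  for (i in 1:200) {
    prm <- sim_params(n_species = 16, n_polytomy_species = 0,
                      sigma2_bm = 0, delta_log_rate = 0,
                      delta_log_mass = 0, group_assignment = "random",
                      mass_time_slope = c(Low = 0.5, High = 0.5),
                      seed = 600 + i)
    sim <- simulate_dataset(prm)
    mc <- plasticity_interaction(sim$cases, sim$tree, "mass")
    if (is_stage_skip(mc)) next
    tt <- mc$tests[mc$tests$model == "star" &
                     mc$tests$coefficient == "p_time:riskHigh", ]
    tstats[i] <- tt$t
    rej <- rej + (tt$p < 0.05)
  }
  expect_lt(abs(mean(tstats)), 2 * stats::sd(tstats) / sqrt(200))
  expect_lte(rej / 200, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))

  # single risk group -> skip
  mono <- simulate_dataset(sim_params(n_species = 10,
                                      n_polytomy_species = 0, seed = 27))
  cases <- mono$cases
  cases$risk_group <- "High"
  expect_s3_class(plasticity_interaction(cases, mono$tree, "mass"),
                  "stage_skip")
})

test_that("plasticity_vs_mean: unbiased null slope and sign recovery", {
  # null world: mass plasticity i.i.d. across cases (equal group means,
  # no time-plasticity slope), so it cannot depend on mean mass. Note the
  # default world is NOT such a null: risk shifts both mean mass and mean
  # plasticity, which induces a marginal slope.
  est <- numeric(100)
  for (i in 1:100) {
    sim <- simulate_dataset(sim_params(
      n_species = 16, n_polytomy_species = 0,
      mass_plasticity_mean = c(Low = -10, High = -10),
      mass_time_slope = c(Low = 0, High = 0),
      seed = 700 + i))
    mc <- plasticity_vs_mean(sim$cases, sim$tree, "mass", "log10_mass")
    row <- mc$tests[mc$tests$model == "star" &
                      mc$tests$coefficient == "log10_mass", ]
    est[i] <- row$estimate
  }
  expect_lt(abs(mean(est)), 2 * stats::sd(est) / sqrt(length(est)))

  # inject a negative dependence: larger species lose more mass
  sign_ok <- 0L
  for (i in 1:100) {
    sim <- simulate_dataset(sim_params(n_species = 16,
                                       n_polytomy_species = 0,
                                       seed = 800 + i))
    cases <- sim$cases
    cons <- cases[cases$treatment == "constant", ]
    lm10 <- log10(cons$mass_mean)[match(cases$case_id, cons$case_id)]
    dry <- cases$treatment == "drying"
    pm <- -10 - 25 * (lm10[dry] - mean(lm10)) + rnorm(sum(dry), 0, 5)
    pm <- pmax(pm, -95)
    cases$mass_mean[dry] <- cons$mass_mean[match(cases$case_id[dry],
                                                 cons$case_id)] *
      (1 + pm / 100)
    mc <- plasticity_vs_mean(cases, sim$tree, "mass", "log10_mass")
    row <- mc$tests[mc$tests$model == "star" &
                      mc$tests$coefficient == "log10_mass", ]
    sign_ok <- sign_ok + (row$estimate < 0)
  }
  expect_gte(sign_ok / 100, 0.95)

  # constant mean trait -> rank error
  sim <- simulate_dataset(sim_params(n_species = 8, n_polytomy_species = 0,
                                     seed = 28))
  cases <- sim$cases
  cases$mass_mean[cases$treatment == "constant"] <- 0.5
  expect_error(plasticity_vs_mean(cases, sim$tree, "mass", "log10_mass"),
               "rank deficient")
})

test_that("run_full_analysis: determinism, bookkeeping, stage isolation", {
  sim <- simulate_dataset(sim_params(n_species = 14,
                                     n_polytomy_species = 4,
                                     cases_per_polytomy = 3, seed = 29))
  cfg <- analysis_config(seed = 29)
  rep1 <- run_full_analysis(cfg, sim$cases, sim$tree)
  rep2 <- run_full_analysis(cfg, sim$cases, sim$tree)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(rep1, d1)
  write_report(rep2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_true(all(file.exists(file.path(
    d1, c("derived_traits.tsv", "plasticity.tsv", "model_tables.tsv")))))

  # polytomy count equals the generator's injected count
  expect_equal(rep1$polytomies$n_soft_polytomies, 4L)

  # every configured stage appears exactly once and AICw pairs sum to 1
  expect_false(anyDuplicated(names(rep1$stages)) > 0)
  for (st in rep1$stages) {
    if (inherits(st$result, "model_comparison")) {
      expect_equal(sum(st$result$akaike_weights), 1, tolerance = 1e-12)
    }
  }

  # a species missing from the tree fails model stages but not the screen
  pruned <- ape::drop.tip(sim$tree, sim$tree$tip.label[1])
  rep3 <- run_full_analysis(cfg, sim$cases, pruned)
  expect_equal(rep3$stages$venue_screen$status, "ok")
  expect_equal(rep3$stages[["compare_groups:log10_dev_rate"]]$status,
               "failed")
  expect_match(rep3$stages[["compare_groups:log10_dev_rate"]]$reason,
               "missing from tree")
})
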