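test_that("the generated scale mirrors the surveillance battery structure", {
  cfg <- sim_config(n_children = 10, seed = 2)
  sc <- generate_scale(cfg)
  expect_equal(nrow(sc$scale), 59)
  expect_setequal(unique(sc$scale$domain),
                  c("gross_motor", "fine_motor", "language", "personal_social"))
  # thresholds validate (monotone, nonnegative) by construction
  expect_s3_class(sc$scale, "devsurv_scale")
  # per-group step allocation: single-milestone steps 5 (motor) and
  # 3 (language-social), at least one milestone everywhere else
  counts <- table(sc$curves$domain_group, sc$curves$step)
  expect_equal(unname(counts["motor", "5"]), 1)
  expect_equal(unname(counts["language_social", "3"]), 1)
  expect_true(all(counts >= 1))
  # a typical child attains scheduled milestones: curves reach high
  # attainment at the scheduled visit
  p_at_visit <- plogis((sc$curves$visit_age - sc$curves$midpoint) /
                         sc$curves$slope)
  expect_true(all(p_at_visit > 0.95))
})

test_that("a minimal scale allocates one milestone per domain", {
  cfg <- sim_config(n_children = 10, n_milestones = 4, seed = 2)
  sc <- generate_scale(cfg)
  expect_equal(sort(table(sc$scale$domain)), sort(rep(1L, 4)),
               ignore_attr = TRUE)
  expect_error(sim_config(n_milestones = 3), "at least 4")
})

test_that("generation is deterministic: same seed, byte-identical files", {
  cfg <- sim_config(n_children = 60, seed = 19)
  gen <- function() {
    sc <- generate_scale(cfg)
    co <- generate_cohort(sc, cfg)
    dir <- withr::local_tempdir()
    write_scale(sc$scale, file.path(dir, "scale.csv"))
    write_attempts(co$attempts, file.path(dir, "attempts.csv"))
    write_children(co$children, file.path(dir, "children.csv"))
    write_truth(co$truth, file.path(dir, "truth.csv"))
    unname(tools::md5sum(file.path(dir, c("scale.csv", "attempts.csv",
                                          "children.csv", "truth.csv"))))
  }
  expect_identical(gen(), gen())
})

test_that("full retention yields a first attempt of every milestone per child", {
  cfg <- sim_config(n_children = 25, seed = 23, retention = 1)
  sc <- generate_scale(cfg)
  co <- generate_cohort(sc, cfg)
  first <- unique(co$attempts[c("child_id", "milestone_id")])
  expect_equal(nrow(first), 25 * 59)
  expect_true(all(table(co$attempts$child_id) >= 59))
})

test_that("a null cohort's mean score matches the analytic expectation", {
  cfg <- sim_config(n_children = 3000, seed = 11,
                    archetype_mixture = c(adequate = 1, catching_up = 0,
                                          worsening = 0),
                    covariate_effects = zero_effects(),
                    retention = 1, visit_jitter = 0, ability_noise_sd = 0)
  sc <- generate_scale(cfg)
  co <- generate_cohort(sc, cfg)
  scored <- score_attempts(co$attempts, sc$scale)
  emp <- mean(scored$lmas)

  # analytic expectation: numeric integration of failure probability x
  # score over the scheduled first attempt and the single retry
  va <- cfg$visit_ages
  tot_s <- 0; tot_n <- 0
  for (i in seq_len(nrow(sc$curves))) {
    v <- sc$curves$visit_age[i]
    mu <- sc$curves$midpoint[i]
    sl <- sc$curves$slope[i]
    row <- sc$scale[sc$scale$milestone_id == sc$curves$milestone_id[i], ]
    pf1 <- 1 - plogis((v - mu) / sl)
    tot_s <- tot_s + pf1 * score_lmas(row, v, FALSE)
    tot_n <- tot_n + 1
    nxt <- va[va > v][1]
    if (!is.na(nxt)) {
      pf2 <- 1 - plogis((nxt - mu) / sl)
      tot_s <- tot_s + pf1 * pf2 * score_lmas(row, nxt, FALSE)
      tot_n <- tot_n + pf1
    }
  }
  analytic <- tot_s / tot_n

  per_child <- dplyr::summarise(dplyr::group_by(scored, child_id),
                                s = sum(lmas), n = dplyr::n())
  se <- stats::sd(per_child$s - analytic * per_child$n) /
    (mean(per_child$n) * sqrt(nrow(per_child)))
  expect_lt(abs(emp - analytic), 2 * se)
})

test_that("attainment frequencies track the planted curves", {
  cfg <- sim_config(n_children = 5000, seed = 29,
                    archetype_mixture = c(adequate = 1, catching_up = 0,
                                          worsening = 0),
                    covariate_effects = zero_effects(),
                    retention = 1, visit_jitter = 0, ability_noise_sd = 0)
  sc <- generate_scale(cfg)
  co <- generate_cohort(sc, cfg)
  at <- dplyr::left_join(co$attempts, sc$curves, by = "milestone_id")
  bins <- dplyr::summarise(
    dplyr::group_by(at, milestone_id, age_months, midpoint, slope),
    n = dplyr::n(), observed = mean(attained), .groups = "drop"
  )
  bins <- bins[bins$n >= 30, ]
  p0 <- plogis((bins$age_months - bins$midpoint) / bins$slope)
  half <- 1.96 * sqrt(p0 * (1 - p0) / bins$n) + 1e-9
  covered <- abs(bins$observed - p0) <= half
  expect_gt(mean(covered), 0.9)   # nominal coverage 95%
})

test_that("planted covariate effects surface in subgroup scores", {
  co <- cohort_fixture(10000, 5)
  scores <- score_table(co$attempts, co$scale)
  onterm <- exclude_preterm(co$children)
  s1 <- scores[scores$window == "0-12" & !is.na(scores$dss) &
                 scores$child_id %in% onterm$child_id, ]
  m <- dplyr::inner_join(s1, co$children, by = "child_id")
  by_sex <- tapply(m$dss, list(m$sex, m$group), mean)
  expect_true(all(by_sex["male", ] > by_sex["female", ]))
})

test_that("planted truth round-trips through its CSV writer", {
  co <- cohort_fixture(400, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(co$truth, path)
  back <- read_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(co$truth))
  # empty cohort: header-only file
  write_truth(co$truth[0, ], path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_truth(path)), 0)
})

test_that("end-to-end clustering recovers the planted archetypes", {
  co <- cohort_fixture(2000, 7,
                       archetype_mixture = c(adequate = 0.78,
                                             catching_up = 0.15,
                                             worsening = 0.07))
  for (grp in c("motor", "language_social")) {
    d <- suppressMessages(filter_complete(
      build_dtvs(co$attempts, co$scale, grp)))
    rep <- cluster_dtvs(d, cluster_config(k = 4, seed = 11))
    j <- dplyr::inner_join(rep$assignments, co$truth, by = "child_id")
    agreement <- mean(rep$labels[j$cluster] == j$archetype)
    expect_gte(agreement, 0.9)
    expect_setequal(unique(j$archetype),
                    c("adequate", "catching_up", "worsening"))
  }
})

test_that("simulation configs validate their inputs", {
  expect_error(sim_config(retention = 0), "retention")
  expect_error(sim_config(archetype_mixture = c(adequate = 0.9,
                                                catching_up = 0.2,
                                                worsening = 0.1)),
               "sum to at most 1")
  expect_error(sim_config(archetype_mixture = c(adequate = 1)), "named")
})
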