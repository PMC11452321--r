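test_that("generator is deterministic in the seed", {
  cfg <- preset_config("study_sizes", seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(preset_config("study_sizes", seed = 2))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("degenerate no-noise, no-delta, no-separation config collapses", {
  cfg <- generator_config(n_patients = 6, cluster_sizes = c(3, 3),
                          baseline_means = c(1, 2, 3, 3),
                          trajectory_deltas = 0, noise_sd = 0,
                          separation = 0, seed = 5)
  co <- as.data.frame(generate_cohort(cfg))
  score_cols <- setdiff(names(co), c("patient_id", "true_cluster"))
  ## every patient identical across all timepoints and to each other
  for (cl in score_cols) expect_equal(length(unique(co[[cl]])), 1L)
  for (tp in oabss_timepoints()) {
    expect_equal(unique(co[[paste0(tp, "-OABSS")]]), 1 + 2 + 3 + 3)
  }
})

test_that("study_sizes preset plants cluster sizes 34/47/20 in n=101", {
  co <- generate_cohort(preset_config("study_sizes", seed = 3))
  expect_equal(nrow(co), 101L)
  expect_equal(as.integer(table(co$true_cluster)), c(34L, 47L, 20L))
})

test_that("bounds and total sums hold for every generated cohort", {
  bounds <- oabss_component_max()
  for (seed in 1:5) {
    cfg <- generator_config(n_patients = 40, cluster_sizes = c(25, 15),
                            baseline_means = c(1, 1.5, 2.5, 2.5),
                            baseline_offsets = rbind(c(0, 0, 0, 0),
                                                     c(1, 1, 2, 2)),
                            noise_sd = c(1, 1, 2, 2),  # heavy noise forces clipping
                            seed = seed)
    co <- as.data.frame(generate_cohort(cfg))
    for (tp in oabss_timepoints()) {
      for (comp in names(bounds)) {
        x <- co[[paste0(tp, "-", comp)]]
        expect_true(all(x >= 0 & x <= bounds[[comp]] & x == round(x)))
      }
      tot <- rowSums(co[, paste0(tp, "-", names(bounds))])
      expect_equal(co[[paste0(tp, "-OABSS")]], unname(tot))
    }
  }
})

test_that("mean change converges to the trajectory deltas without discretization", {
  deltas <- rbind(rep(0, 4),
                  c(-0.1, -0.2, -0.5, -1.0),
                  c(-0.1, -0.2, -0.5, -1.0),
                  c(0, -0.1, -0.4, -0.9),
                  c(0.1, 0, -0.3, -0.5))
  cfg <- generator_config(n_patients = 10000, cluster_sizes = 10000,
                          baseline_means = c(1, 1.5, 2.5, 2.5),
                          trajectory_deltas = deltas,
                          noise_sd = c(0.2, 0.4, 0.8, 1.0),
                          noise_cor = 0.5, seed = 11)
  co <- generate_cohort(cfg, discretize = FALSE)
  cs <- as.data.frame(change_summary(co))
  tps <- oabss_timepoints()
  for (row in seq_len(nrow(cs))) {
    m <- cs$measure[row]
    if (m == "total") next
    target <- deltas[match(cs$timepoint[row], tps), match(m, c("Q1", "Q2", "Q3", "Q4"))]
    se <- cs$sd_change[row] / sqrt(cs$n[row])
    expect_lt(abs(cs$mean_change[row] - target), 3 * se)
  }
})

test_that("discretization bias at the calibrated preset stays within 0.1 points", {
  ## same preset noise/deltas, scaled to a large cohort to isolate the
  ## rounding+clipping bias from sampling error
  base <- preset_config("table1_calibrated", seed = 17)
  cfg <- generator_config(n_patients = 20000, cluster_sizes = 20000,
                          baseline_means = base$baseline_means,
                          trajectory_deltas = base$trajectory_deltas[1],
                          noise_sd = base$noise_sd,
                          noise_cor = base$noise_cor, seed = 17)
  co <- generate_cohort(cfg)
  cs <- as.data.frame(change_summary(co))
  tg <- table1_change_targets()
  merged <- merge(cs, tg, by = c("timepoint", "measure"))
  expect_true(all(abs(merged$mean_change - merged$mean) < 0.1))
})

test_that("config validation rejects inconsistent inputs", {
  expect_error(generator_config(10, c(4, 4), baseline_means = c(1, 1, 1, 1)),
               "sum to n_patients")
  expect_error(generator_config(8, c(4, 4), baseline_means = c(1, 1, 1, 1),
                                noise_sd = -1),
               "nonnegative")
  expect_error(generator_config(8, c(4, 4), baseline_means = c(1, 1, 1, 1),
                                noise_cor = 1.2),
               "noise_cor")
  expect_error(generator_config(8, c(4, 4), baseline_means = c(1, 1, 1, 1),
                                trajectory_deltas = matrix(0, 2, 2)),
               "5 timepoints x 4 items")
})

test_that("cohort CSV round-trips in the component dialect", {
  co <- fixture_cohort3()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(co))
  expect_true(attr(back, "has_components"))
})

test_that("totals-only CSV reads with components absent", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(patient_id = c("a", "b"),
                   `T0-OABSS` = c(8, 12), `T6-OABSS` = c(7, 11),
                   `T12-OABSS` = c(6, 10), `T18-OABSS` = c(6, 10),
                   `T24-OABSS` = c(5, 9), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  co <- read_cohort_csv(path)
  expect_false(attr(co, "has_components"))
  expect_equal(co$`T24-OABSS`, c(5, 9))
  expect_equal(unclass(extract_totals(co))[1, ], c(T0 = 8, T6 = 7, T12 = 6, T18 = 6, T24 = 5))
})

test_that("reader flags missing columns and out-of-bounds scores", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(patient_id = "a", `T0-OABSS` = 8, `T6-OABSS` = 7,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "T12-OABSS")

  co <- as.data.frame(fixture_cohort3())
  co[2, "T6-Q3"] <- 7  # bound is 5
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(co[, !grepl("OABSS", names(co))], path2, row.names = FALSE)
  err <- tryCatch(read_cohort_csv(path2), error = identity)
  expect_match(conditionMessage(err), "T6-Q3")
  expect_match(conditionMessage(err), "P02")
})

test_that("generator config YAML round-trips", {
  cfg <- preset_config("study_sizes", seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_yaml(cfg, path)
  back <- read_generator_yaml(path)
  expect_equal(back$cluster_sizes, cfg$cluster_sizes)
  expect_equal(back$trajectory_deltas, cfg$trajectory_deltas)
  expect_equal(back$noise_sd, cfg$noise_sd, tolerance = 1e-12)
  expect_identical(as.data.frame(generate_cohort(back)),
                   as.data.frame(generate_cohort(cfg)))
})
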