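test_that("template calibration hits its published targets and self-consistency", {
  tm <- calibrated_template("M", "right")
  m <- coxmorph:::template_measurements(tm)
  expect_lt(abs(m[["coxal_bone_height"]] - 210.55) / 210.55, 0.01)
  expect_lt(max(attr(tm, "residuals")), 0.01)
  expect_gte(min(dist(tm)), 10)
  # self-consistency: targets generated from a known template are recovered
  set.seed(321)
  truth <- base_template() + matrix(rnorm(102, 0, 3), 34L, 3L)
  targets <- coxmorph:::template_measurements(truth)
  fit <- calibrate_template(targets)
  got <- coxmorph:::template_measurements(fit)
  expect_lt(max(abs(got - targets) / targets), 1e-6)
})

test_that("calibration is scale-equivariant in the linear targets", {
  set.seed(331)
  truth <- base_template() + matrix(rnorm(102, 0, 2), 34L, 3L)
  targets <- coxmorph:::template_measurements(truth)
  reg <- measurement_registry()
  lin <- reg$kind != "angle"
  t2 <- targets
  t2[lin] <- 2 * t2[lin]
  fit <- calibrate_template(t2, min_separation = 10)
  got <- coxmorph:::template_measurements(fit)
  expect_lt(max(abs(got[lin] - 2 * targets[lin]) / (2 * targets[lin])), 0.01)
  expect_lt(max(abs(got[!lin] - targets[!lin]) / targets[!lin]), 0.01)
})

test_that("calibration rejects invalid targets", {
  tm <- coxmorph:::template_measurements(base_template())
  bad <- tm; bad[1L] <- -1
  expect_error(calibrate_template(bad), "positive")
  bad2 <- tm; bad2["greater_sciatic_notch_angle"] <- 185
  expect_error(calibrate_template(bad2), "angle")
  expect_error(calibrate_template(tm[-1L]), "missing measurement")
})

test_that("measurement cohorts are seed-deterministic and match preset means", {
  a <- generate_measurement_cohort(cohort_config(seed = 341L), sides = "right")
  b <- generate_measurement_cohort(cohort_config(seed = 341L), sides = "right")
  expect_identical(a, b)
  c_ <- generate_measurement_cohort(cohort_config(seed = 342L), sides = "right")
  expect_false(identical(a$coxal_bone_height, c_$coxal_bone_height))

  # law-of-large-numbers round trip at n = 10,000 males
  big <- generate_measurement_cohort(
    cohort_config(n_males = 10000L, n_females = 1L, seed = 343L),
    sides = "right")
  males <- big[big$sex == "M", ]
  preset <- table2_preset()
  pm <- preset[preset$sex == "M" & preset$side == "right", ]
  tgt <- setNames(pm$mean, pm$measurement)
  sds <- setNames(pm$sd, pm$measurement)
  for (mname in c("pubic_symphysis_width", "coxal_bone_height",
                  "greater_sciatic_notch_angle")) {
    se <- sds[[mname]] / sqrt(nrow(males))
    expect_lt(abs(mean(males[[mname]]) - tgt[[mname]]), 3 * se)
  }
  # male - female mean differences reproduce the preset within 3 SE
  big2 <- generate_measurement_cohort(
    cohort_config(n_males = 10000L, n_females = 10000L, seed = 344L),
    sides = "right")
  pf <- preset[preset$sex == "F" & preset$side == "right", ]
  tgt_f <- setNames(pf$mean, pf$measurement)
  sds_f <- setNames(pf$sd, pf$measurement)
  for (mname in c("coxal_bone_height", "ischiopubic_ramus_length")) {
    d_obs <- mean(big2[[mname]][big2$sex == "M"]) -
      mean(big2[[mname]][big2$sex == "F"])
    d_tgt <- tgt[[mname]] - tgt_f[[mname]]
    se <- sqrt(sds[[mname]]^2 + sds_f[[mname]]^2) / sqrt(10000)
    expect_lt(abs(d_obs - d_tgt), 3 * se)
  }
})

test_that("rho = 0 gives uncorrelated measurements; rho = 0.3 does not", {
  tab0 <- generate_measurement_cohort(
    cohort_config(n_males = 4000L, n_females = 1L, seed = 351L),
    sides = "right", rho = 0)
  m0 <- as.matrix(tab0[tab0$sex == "M", measurement_columns(tab0)])
  cors <- cor(m0)
  off <- cors[upper.tri(cors)]
  expect_lt(max(abs(off)), 0.06)
  tab3 <- generate_measurement_cohort(
    cohort_config(n_males = 4000L, n_females = 1L, seed = 351L),
    sides = "right", rho = 0.3)
  m3 <- as.matrix(tab3[tab3$sex == "M", measurement_columns(tab3)])
  lin <- measurement_registry()$kind != "angle"
  cors3 <- cor(m3)[lin, lin]
  expect_gt(median(cors3[upper.tri(cors3)]), 0.25)
})

test_that("laterality offsets reproduce published right-minus-left differences", {
  tab <- generate_measurement_cohort(
    cohort_config(n_males = 10000L, n_females = 1L, seed = 361L),
    sides = "both", side_offsets = TRUE)
  males <- tab[tab$sex == "M", ]
  r <- males[males$side == "right", ]
  l <- males[males$side == "left", ]
  l <- l[match(r$individual_id, l$individual_id), ]
  d <- r$ischiopubic_ramus_length - l$ischiopubic_ramus_length
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - (-3.47)), 2 * se)
})

test_that("the four female-larger measurements emerge from the preset", {
  tab <- generate_measurement_cohort(
    cohort_config(n_males = 3000L, n_females = 3000L, seed = 371L),
    sides = "right")
  female_larger <- c("greater_sciatic_notch_breadth", "greater_sciatic_notch_angle",
                     "ischiopubic_ramus_length", "posterior_interspinal_height")
  for (mname in female_larger) {
    expect_gt(mean(tab[[mname]][tab$sex == "F"]),
              mean(tab[[mname]][tab$sex == "M"]))
  }
  # and a classic male-larger control
  expect_gt(mean(tab$coxal_bone_height[tab$sex == "M"]),
            mean(tab$coxal_bone_height[tab$sex == "F"]))
})

test_that("age model and cohort composition follow the configured study", {
  cc <- cohort_config()
  expect_equal(cc$n_males, 136L)
  expect_equal(cc$n_females, 140L)
  tab <- generate_measurement_cohort(cohort_config(seed = 381L), sides = "right")
  expect_equal(nrow(tab), 276L)
  expect_true(all(tab$age[tab$sex == "M"] >= 19 & tab$age[tab$sex == "M"] <= 83))
  expect_true(all(tab$age[tab$sex == "F"] >= 19 & tab$age[tab$sex == "F"] <= 88))
})

test_that("landmark cohorts honour the noiseless limit and missingness budget", {
  quiet <- generate_landmark_cohort(
    cohort_config(n_males = 2L, n_females = 2L, seed = 391L),
    sides = "right", scale_sd = 0, shape_sd = 0)
  tab <- compute_first_dataset(quiet)
  tm <- coxmorph:::template_measurements(calibrated_template("M", "right"))
  male_rows <- which(tab$sex == "M")
  for (i in male_rows)
    expect_equal(unlist(tab[i, names(tm)]), tm, tolerance = 1e-12)
  # default full-cohort missingness pattern
  masked <- generate_landmark_cohort(
    cohort_config(seed = 392L), sides = "both", n_masked = 35L)
  expect_equal(n_bones(masked), 552L)
  fnd <- validate_cohort(masked)
  expect_equal(nrow(fnd), 0L)   # 1-3 missing is within the imputable regime
  expect_equal(sum(lengths(missing_landmarks(masked)) > 0L), 35L)
  expect_true(all(lengths(missing_landmarks(masked)) %in% 0:3))
  # seed determinism at the landmark level
  again <- generate_landmark_cohort(
    cohort_config(seed = 392L), sides = "both", n_masked = 35L)
  expect_identical(masked$coords, again$coords)
})

test_that("classification accuracy rises as shape noise falls", {
  accs <- numeric(0)
  for (ssd in c(6, 3, 0.75)) {
    cohort <- generate_landmark_cohort(
      cohort_config(n_males = 60L, n_females = 60L, seed = 401L),
      sides = "right", shape_sd = ssd)
    tab <- compute_first_dataset(cohort)
    sp <- stratified_split(tab, 30L, c("sex", "age_group"), seed = 1L)
    m <- tune_and_fit(sp$train, "lr_l2", seed = 1L, n_candidates = 8L,
                      repeats = 2L)
    accs <- c(accs, evaluate_model(m, sp$test)$accuracy_pct)
  }
  expect_true(accs[3L] >= accs[1L])
  expect_gt(accs[3L], 85)
})
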