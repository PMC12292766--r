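#' Shipped published-summary presets
#'
#' Loaders for the parameter tables shipped with the package: sex/side
#' measurement means and SDs (with printed min/max ranges), right-minus-left
#' laterality offsets per sex, and young-minus-old age-group offsets per sex
#' and side (age split at 45 years). These drive the synthetic cohort
#' generators; they are summary statistics, not raw data.
#'
#' @return `table2_preset()`: data.frame `measurement, side, sex, mean, sd,
#'   min, max` (132 rows). `table3_preset()`: data.frame `measurement, diff_M,
#'   diff_F`. `table4_preset()`: data.frame `measurement, diff_M_right,
#'   diff_M_left, diff_F_right, diff_F_left`.
#' @export
table2_preset <- function() {
  utils::read.csv(system.file("extdata", "table2_means.csv",
                              package = "coxmorph"),
                  stringsAsFactors = FALSE)
}

#' @rdname table2_preset
#' @export
table3_preset <- function() {
  utils::read.csv(system.file("extdata", "table3_side_offsets.csv",
                              package = "coxmorph"),
                  stringsAsFactors = FALSE)
}

#' @rdname table2_preset
#' @export
table4_preset <- function() {
  utils::read.csv(system.file("extdata", "table4_age_offsets.csv",
                              package = "coxmorph"),
                  stringsAsFactors = FALSE)
}

#' Default cohort composition
#'
#' The emulated study cohort: 136 males and 140 females with sex-specific
#' truncated-Gaussian age distributions (males: mean 56.5, SD 14.8, range
#' 19-83; females: mean 56.7, SD 13.8, range 19-88 years).
#'
#' @param n_males,n_females cohort sizes per sex.
#' @param seed integer seed.
#' @return A list with `n_males`, `n_females`, `seed`, and per-sex age model
#'   parameters.
#' @export
cohort_config <- function(n_males = 136L, n_females = 140L, seed = 1L) {
  stopifnot(n_males >= 1L, n_females >= 1L)
  list(
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    seed = as.integer(seed),
    age_M = c(mean = 56.5, sd = 14.8, lo = 19, hi = 83),
    age_F = c(mean = 56.7, sd = 13.8, lo = 19, hi = 88)
  )
}

draw_truncated_ages <- function(n, par) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, par[["mean"]], par[["sd"]])
    out <- c(out, x[x >= par[["lo"]] & x <= par[["hi"]]])
  }
  out[seq_len(n)]
}

# exchangeable correlation among linear/height measurements, halved for the
# angle block; repaired by shrinking rho toward 0 if not positive definite
measurement_correlation <- function(rho = 0.3) {
  reg <- measurement_registry()
  p <- nrow(reg)
  ang <- reg$kind == "angle"
  for (try_rho in c(rho, rho * 0.5, rho * 0.25, 0)) {
    R <- matrix(try_rho, p, p)
    R[ang, ] <- try_rho / 2
    R[, ang] <- try_rho / 2
    diag(R) <- 1
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 1e-8) {
      if (try_rho != rho)
        warning(sprintf("correlation %.3g not positive definite; shrunk to %.3g",
                        rho, try_rho))
      return(R)
    }
  }
  stop("could not repair the measurement correlation matrix")
}

#' Generate a measurement-level synthetic cohort
#'
#' Draws per-bone measurement vectors from a sex/side-specific multivariate
#' Gaussian whose means and SDs come from the shipped published preset
#' ([table2_preset()]), with an exchangeable cross-measurement correlation
#' `rho` (halved for the angle block). With `sides = "both"`, each
#' individual's two bones share a latent vector centred on the mid-side mean,
#' and when `side_offsets = TRUE` the published right-minus-left offsets are
#' split +d/2 to the right and -d/2 to the left bone; independent
#' within-individual noise (a fraction `asymmetry_noise_frac` of the total
#' variance) separates the sides. With `age_offsets = TRUE` the over-45 age
#' group is shifted by minus the published young-minus-old offsets.
#'
#' The published min/max ranges are used only for validation: values outside
#' the printed range by more than 20% of its span are counted in the
#' `"range_flags"` attribute, never truncated.
#'
#' @param config a [cohort_config()].
#' @param sides `"right"`, `"left"`, or `"both"`.
#' @param rho exchangeable correlation (default 0.3).
#' @param side_offsets apply laterality offsets (only meaningful for
#'   `sides = "both"`; default `TRUE` there).
#' @param age_offsets apply age-group offsets (default `FALSE`, which keeps
#'   the generated means on the preset values).
#' @param asymmetry_noise_frac fraction of measurement variance assigned to
#'   independent within-individual side noise when `sides = "both"`.
#' @return A measurement table: `individual_id`, `side`, `sex`, `age` plus 33
#'   measurement columns.
#' @export
generate_measurement_cohort <- function(config = cohort_config(),
                                        sides = c("right", "left", "both"),
                                        rho = 0.3,
                                        side_offsets = NULL,
                                        age_offsets = FALSE,
                                        asymmetry_noise_frac = 0.1) {
  sides <- match.arg(sides)
  if (is.null(side_offsets)) side_offsets <- sides == "both"
  set.seed(config$seed)
  reg <- measurement_registry()
  preset <- table2_preset()
  t3 <- table3_preset()
  t4 <- table4_preset()
  R <- measurement_correlation(rho)
  L <- chol(R)
  rows <- list()
  for (sx in c("M", "F")) {
    n <- if (sx == "M") config$n_males else config$n_females
    ages <- draw_truncated_ages(n, config[[paste0("age_", sx)]])
    ids <- sprintf("%s%04d", sx, seq_len(n))
    sdev <- function(side) {
      sub <- preset[preset$sex == sx & preset$side == side, ]
      list(mean = stats::setNames(sub$mean, sub$measurement)[reg$name],
           sd = stats::setNames(sub$sd, sub$measurement)[reg$name])
    }
    d3 <- stats::setNames(t3[[paste0("diff_", sx)]], t3$measurement)[reg$name]
    z <- matrix(stats::rnorm(n * nrow(reg)), n) %*% L
    if (sides != "both") {
      par <- sdev(sides)
      vals <- sweep(sweep(z, 2L, par$sd, "*"), 2L, par$mean, "+")
      vals <- apply_age_offsets(vals, ages, sx, sides, t4, age_offsets, reg)
      rows[[sx]] <- data.frame(individual_id = ids, side = sides, sex = sx,
                               age = ages, vals, check.names = FALSE)
    } else {
      pr <- sdev("right"); pl <- sdev("left")
      mid_mean <- (pr$mean + pl$mean) / 2
      mid_sd <- (pr$sd + pl$sd) / 2
      lat_sd <- sqrt(1 - asymmetry_noise_frac) * mid_sd
      eps_sd <- sqrt(asymmetry_noise_frac) * mid_sd
      latent <- sweep(sweep(z, 2L, lat_sd, "*"), 2L, mid_mean, "+")
      off <- if (side_offsets) d3 / 2 else 0 * d3
      right <- latent + matrix(stats::rnorm(n * nrow(reg)), n) %*% diag(eps_sd)
      right <- sweep(right, 2L, off, "+")
      left <- latent + matrix(stats::rnorm(n * nrow(reg)), n) %*% diag(eps_sd)
      left <- sweep(left, 2L, off, "-")
      colnames(right) <- colnames(left) <- reg$name
      right <- apply_age_offsets(right, ages, sx, "right", t4, age_offsets, reg)
      left <- apply_age_offsets(left, ages, sx, "left", t4, age_offsets, reg)
      rows[[sx]] <- rbind(
        data.frame(individual_id = ids, side = "right", sex = sx, age = ages,
                   right, check.names = FALSE),
        data.frame(individual_id = ids, side = "left", sex = sx, age = ages,
                   left, check.names = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  colnames(out)[-(1:4)] <- reg$name
  attr(out, "range_flags") <- flag_out_of_range(out, preset, reg)
  out
}

apply_age_offsets <- function(vals, ages, sx, side, t4, enabled, reg) {
  if (!enabled) return(vals)
  col <- paste0("diff_", sx, "_", side)
  d <- stats::setNames(t4[[col]], t4$measurement)[reg$name]
  old <- ages > 45
  vals[old, ] <- sweep(vals[old, , drop = FALSE], 2L, d, "-")
  vals
}

flag_out_of_range <- function(table, preset, reg) {
  flags <- 0L
  for (sx in unique(table$sex)) for (sd_ in unique(table$side)) {
    sub <- preset[preset$sex == sx & preset$side == sd_, ]
    lo <- stats::setNames(sub$min, sub$measurement)[reg$name]
    hi <- stats::setNames(sub$max, sub$measurement)[reg$name]
    span <- hi - lo
    v <- as.matrix(table[table$sex == sx & table$side == sd_, reg$name])
    flags <- flags + sum(t(t(v) < lo - 0.2 * span) | t(t(v) > hi + 0.2 * span))
  }
  flags
}

#' Generate a landmark-level synthetic cohort
#'
#' Builds bones from the calibrated sex/side templates
#' ([calibrated_template()]): each individual draws a global scale factor
#' (Gaussian, mean 1) applied to both sides, and each bone adds independent
#' isotropic per-landmark shape jitter. Optionally, 1-3 landmarks are masked
#' (set missing) on `n_masked` randomly chosen bones, emulating incompletely
#' reconstructed bones.
#'
#' @param config a [cohort_config()].
#' @param sides `"right"`, `"left"`, or `"both"`.
#' @param scale_sd SD of the global scale factor (default 0.03).
#' @param shape_sd isotropic per-landmark, per-axis jitter SD in mm
#'   (default 1.5).
#' @param n_masked number of bones given 1-3 missing landmarks (default 0;
#'   the emulated full-cohort rate is 35 of 552 bones).
#' @return A `landmark_cohort`.
#' @export
generate_landmark_cohort <- function(config = cohort_config(),
                                     sides = c("both", "right", "left"),
                                     scale_sd = 0.03, shape_sd = 1.5,
                                     n_masked = 0L) {
  sides <- match.arg(sides)
  set.seed(config$seed)
  side_list <- if (sides == "both") c("right", "left") else sides
  metas <- list(); coords <- list()
  for (sx in c("M", "F")) {
    n <- if (sx == "M") config$n_males else config$n_females
    ages <- draw_truncated_ages(n, config[[paste0("age_", sx)]])
    ids <- sprintf("%s%04d", sx, seq_len(n))
    scales <- stats::rnorm(n, 1, scale_sd)
    for (sd_ in side_list) {
      tmpl <- calibrated_template(sx, sd_)
      arr <- array(NA_real_, dim = c(n, 34L, 3L),
                   dimnames = list(NULL, landmark_names(), c("x", "y", "z")))
      jitter <- array(stats::rnorm(n * 34L * 3L, 0, shape_sd), dim = c(n, 34L, 3L))
      for (i in seq_len(n)) arr[i, , ] <- tmpl * scales[i] + jitter[i, , ]
      metas[[paste(sx, sd_)]] <- data.frame(
        individual_id = ids, side = sd_, sex = sx, age = ages,
        stringsAsFactors = FALSE)
      coords[[paste(sx, sd_)]] <- arr
    }
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  co <- do.call(abind3, coords)
  if (n_masked > 0L) {
    if (n_masked > nrow(meta))
      stop("n_masked exceeds the number of bones")
    bones <- sample.int(nrow(meta), n_masked)
    for (b in bones) {
      k <- sample(1:3, 1L)
      lms <- sample.int(34L, k)
      co[b, lms, ] <- NA_real_
    }
  }
  landmark_cohort(meta, co,
                  provenance = sprintf(
                    "generate_landmark_cohort(seed=%d, scale_sd=%g, shape_sd=%g, n_masked=%d)",
                    config$seed, scale_sd, shape_sd, n_masked))
}

#' Generate a repeated-acquisition study for reliability analysis
#'
#' Emulates one observer landmarking the same bones `k` times: per subject and
#' side, a true bone is drawn from the calibrated template with the usual
#' individual deformation, and each acquisition adds independent isotropic
#' Gaussian noise of SD `sigma_acq` to every coordinate.
#'
#' @param n_subjects number of individuals (default 30; half male, the
#'   remainder female).
#' @param k acquisitions per bone (default 3).
#' @param sigma_acq acquisition noise SD per coordinate, mm (default 0.3).
#' @param scale_sd,shape_sd individual deformation parameters as in
#'   [generate_landmark_cohort()].
#' @param seed integer seed.
#' @return A `landmark_cohort` with an `acquisition` meta column covering both
#'   sides of every subject.
#' @export
generate_repeat_study <- function(n_subjects = 30L, k = 3L, sigma_acq = 0.3,
                                  scale_sd = 0.03, shape_sd = 1.5, seed = 1L) {
  stopifnot(n_subjects >= 2L, k >= 2L)
  set.seed(seed)
  n_m <- n_subjects %/% 2L
  sexes <- c(rep("M", n_m), rep("F", n_subjects - n_m))
  ids <- sprintf("R%04d", seq_len(n_subjects))
  ages <- c(draw_truncated_ages(n_m, cohort_config()$age_M),
            draw_truncated_ages(n_subjects - n_m, cohort_config()$age_F))
  scales <- stats::rnorm(n_subjects, 1, scale_sd)
  metas <- list(); coords <- list()
  idx <- 0L
  for (i in seq_len(n_subjects)) {
    for (sd_ in c("right", "left")) {
      tmpl <- calibrated_template(sexes[i], sd_)
      truth <- tmpl * scales[i] +
        matrix(stats::rnorm(34L * 3L, 0, shape_sd), 34L, 3L)
      for (acq in seq_len(k)) {
        idx <- idx + 1L
        metas[[idx]] <- data.frame(
          individual_id = ids[i], side = sd_, sex = sexes[i], age = ages[i],
          acquisition = acq, stringsAsFactors = FALSE)
        noisy <- truth + matrix(stats::rnorm(34L * 3L, 0, sigma_acq), 34L, 3L)
        coords[[idx]] <- array(noisy, dim = c(1L, 34L, 3L),
                               dimnames = list(NULL, landmark_names(),
                                               c("x", "y", "z")))
      }
    }
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  landmark_cohort(meta, do.call(abind3, coords),
                  provenance = sprintf(
                    "generate_repeat_study(n=%d, k=%d, sigma_acq=%g, seed=%d)",
                    n_subjects, k, sigma_acq, seed))
}
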