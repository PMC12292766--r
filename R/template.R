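#' Hand-built starting configuration for template calibration
#'
#' An approximate 34-landmark coxal bone layout (right side, roughly
#' male-sized, mm) used as the starting point and regularization anchor of
#' [calibrate_template()]. The frame is arbitrary: x runs anteriorly, y
#' superiorly, z laterally. The configuration is anatomically coarse but
#' non-degenerate: no coincident or collinear construction triples and
#' comfortable pairwise separations.
#'
#' @return A 34 x 3 matrix with registry row names.
#' @export
base_template <- function() {
  pts <- rbind(
    mla  = c(5, 115, 32),
    iit  = c(-18, -92, -5),
    sps  = c(92, -32, -22),
    pss  = c(-90, 86, -4),
    ass  = c(72, 98, 8),
    ais  = c(66, 62, 6),
    pis  = c(-62, 50, -10),
    mli  = c(-15, 30, 5),
    as   = c(45, -5, 8),
    asa  = c(25, 13, 12),
    ai   = c(5, -42, 10),
    ap   = c(-15, -25, 5),
    lss  = c(25, -5, 18),
    sfo  = c(50, -22, 0),
    ifo  = c(35, -78, -5),
    mfo  = c(62, -50, -8),
    lfo  = c(28, -48, -2),
    pirt = c(-58, 28, -8),
    is   = c(-42, -22, -10),
    ips  = c(88, -68, -24),
    iipr = c(35, -90, -15),
    lit  = c(-30, -70, -2),
    gsn  = c(-28, 4, -6),
    lsn  = c(-38, -42, -8),
    sij  = c(-30, 38, -12),
    pgl  = c(-55, 95, 5),
    pla  = c(70, -30, -10),
    plp  = c(45, -12, 2),
    mipr = c(60, -80, -20),
    lsi  = c(20, -32, 15),
    maps = c(97, -50, -20),
    mpps = c(83, -52, -26),
    ain  = c(69, 80, 12),
    pin  = c(-72, 68, -2)
  )
  stopifnot(identical(rownames(pts), landmark_names()))
  colnames(pts) <- c("x", "y", "z")
  pts
}

# precomputed integer-index plan for fast battery evaluation on one bone
measurement_plan <- local({
  plan <- NULL
  function() {
    if (!is.null(plan)) return(plan)
    reg <- measurement_registry()
    nm <- landmark_names()
    plan <<- list(
      reg = reg,
      i1 = match(reg$lm1, nm), i2 = match(reg$lm2, nm),
      i3 = ifelse(is.na(reg$lm3), 1L, match(reg$lm3, nm)),
      lin = which(reg$kind == "linear"),
      hgt = which(reg$kind == "height"),
      ang = which(reg$kind == "angle"))
    plan
  }
})

template_measurements <- function(template) {
  pl <- measurement_plan()
  vals <- numeric(33L)
  p1 <- template[pl$i1, , drop = FALSE]
  p2 <- template[pl$i2, , drop = FALSE]
  p3 <- template[pl$i3, , drop = FALSE]
  d12 <- p1 - p2
  vals[pl$lin] <- sqrt(rowSums(d12[pl$lin, , drop = FALSE]^2))
  # heights: apex = lm1, baseline = lm2-lm3
  h <- pl$hgt
  d <- p3[h, , drop = FALSE] - p2[h, , drop = FALSE]
  w <- p1[h, , drop = FALSE] - p2[h, , drop = FALSE]
  t_ <- rowSums(w * d) / rowSums(d^2)
  vals[h] <- sqrt(rowSums((w - d * t_)^2))
  # angles: vertex = lm2, arms to lm1 and lm3
  a <- pl$ang
  u1 <- p1[a, , drop = FALSE] - p2[a, , drop = FALSE]
  u2 <- p3[a, , drop = FALSE] - p2[a, , drop = FALSE]
  cosang <- pmin(1, pmax(-1, rowSums(u1 * u2) /
                           sqrt(rowSums(u1^2) * rowSums(u2^2))))
  vals[a] <- acos(cosang) * 180 / pi
  names(vals) <- pl$reg$name
  vals
}

#' Calibrate a 34-landmark template to target measurement means
#'
#' Least-squares fit of the 102 free coordinates: Levenberg-Marquardt
#' minimization of the relative measurement residuals
#' `(measurement(x) - target) / target` over the 33-measurement battery, plus
#' a weak quadratic pull toward the hand-built anatomical start (which also
#' pins the six rigid-motion gauge directions) and a hinge penalty that keeps
#' every landmark pair at least `min_separation` mm apart (close pairs would
#' inflate relative measurement error statistics downstream). The fit is
#' deterministic.
#'
#' @param target_means named numeric vector over the 33 measurement names
#'   (mm for linear/height, degrees for angles).
#' @param start optional 34 x 3 starting template (default [base_template()]).
#' @param max_rel_residual acceptance tolerance on the per-measurement
#'   relative residual (default 1%); the fit errors out beyond it.
#' @param min_separation minimum pairwise landmark distance to enforce, mm.
#' @param anchor_weight weight of the pull toward the start configuration.
#' @return A 34 x 3 calibrated template (registry row names) with attribute
#'   `"residuals"` holding the achieved relative residuals.
#' @export
calibrate_template <- function(target_means, start = base_template(),
                               max_rel_residual = 0.01,
                               min_separation = 10, anchor_weight = 1e-6) {
  reg <- measurement_registry()
  if (is.null(names(target_means)))
    stop("target_means must be named by measurement")
  target <- target_means[reg$name]
  if (anyNA(target))
    stop("target_means missing measurement(s): ",
         paste(setdiff(reg$name, names(target_means)), collapse = ", "))
  if (any(target <= 0)) stop("targets must be positive")
  ang <- reg$kind == "angle"
  if (any(target[ang] >= 180)) stop("angle targets must lie in (0, 180)")
  x0 <- as.vector(start)
  hinge_at <- min_separation * 1.25
  resid_fun <- function(x) {
    tmpl <- matrix(x, ncol = 3L, dimnames = dimnames(start))
    m <- template_measurements(tmpl)
    r_meas <- (m - target) / target
    d <- stats::dist(tmpl)
    r_sep <- pmax(0, (hinge_at - d) / hinge_at) * 10
    r_anchor <- sqrt(anchor_weight) * (x - x0) / 100
    c(r_meas, r_sep, r_anchor)
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = x0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 150, ftol = 1e-12,
                                         ptol = 1e-12, maxfev = 100000)))
  tmpl <- matrix(fit$par, ncol = 3L, dimnames = dimnames(start))
  achieved <- template_measurements(tmpl)
  rel <- abs(achieved - target) / target
  if (max(rel) > max_rel_residual) {
    worst <- utils::head(sort(rel, decreasing = TRUE), 5L)
    stop("template calibration failed the ", format(max_rel_residual),
         " relative tolerance; worst residuals: ",
         paste(sprintf("%s=%.3g", names(worst), worst), collapse = ", "))
  }
  if (min(stats::dist(tmpl)) < min_separation)
    stop("calibrated template violates the minimum landmark separation of ",
         min_separation, " mm")
  attr(tmpl, "residuals") <- rel
  tmpl
}

# session-level cache of calibrated sex/side templates
.template_cache <- new.env(parent = emptyenv())

#' Calibrated template for one sex and side
#'
#' Calibrates (and caches for the session) a template whose derived
#' measurements match the shipped sex/side-specific published mean preset to
#' within 1%.
#'
#' @param sex `"M"` or `"F"`.
#' @param side `"right"` or `"left"`.
#' @return A 34 x 3 calibrated template.
#' @export
calibrated_template <- function(sex = c("M", "F"), side = c("right", "left")) {
  sex <- match.arg(sex); side <- match.arg(side)
  key <- paste(sex, side, sep = ".")
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  preset <- table2_preset()
  sub <- preset[preset$sex == sex & preset$side == side, , drop = FALSE]
  targets <- stats::setNames(sub$mean, sub$measurement)
  tmpl <- calibrate_template(targets)
  assign(key, tmpl, envir = .template_cache)
  tmpl
}
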