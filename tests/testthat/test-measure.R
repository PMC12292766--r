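test_that("geometric primitives match closed forms and componentwise oracles", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(euclidean_distance(c(0, 0, NA), c(1, 1, 1)), "non-finite")
  set.seed(101)
  p <- matrix(rnorm(600, 0, 50), ncol = 3L)
  q <- matrix(rnorm(600, 0, 50), ncol = 3L)
  oracle <- sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2 + (p[, 3] - q[, 3])^2)
  expect_equal(euclidean_distance(p, q), oracle)

  expect_equal(vertex_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vertex_angle(c(-2, 0, 0), c(0, 0, 0), c(5, 0, 0)), 180)
  # equilateral triangle vertex
  expect_equal(vertex_angle(c(1, 0, 0), c(0, 0, 0), c(0.5, sqrt(3) / 2, 0)), 60)
  expect_error(vertex_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")

  expect_equal(point_line_height(c(0, 5, 0), c(0, 0, 0), c(1, 0, 0)), 5)
  expect_equal(point_line_height(c(7, 0, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_error(point_line_height(c(0, 1, 0), c(2, 2, 2), c(2, 2, 2)), "degenerate")
  # cross-product oracle on random triples
  apex <- matrix(rnorm(600, 0, 30), ncol = 3L)
  b1 <- matrix(rnorm(600, 0, 30), ncol = 3L)
  b2 <- matrix(rnorm(600, 0, 30), ncol = 3L)
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  num <- sqrt(rowSums(cross(apex - b1, b2 - b1)^2))
  den <- sqrt(rowSums((b2 - b1)^2))
  expect_equal(point_line_height(apex, b1, b2), num / den)
})

test_that("first dataset has the 27/3/3 battery and honours its definitions", {
  cohort <- make_test_cohort(n = 3L, seed = 21L)
  tab <- compute_first_dataset(cohort)
  cols <- measurement_columns(tab)
  expect_length(cols, 33L)
  reg <- measurement_registry()
  expect_equal(cols, reg$name)
  expect_equal(sum(reg$kind == "linear"), 27L)
  expect_equal(sum(reg$kind == "angle"), 3L)
  expect_equal(sum(reg$kind == "height"), 3L)
  # definition consistency: coxal bone height is the mla-iit distance
  manual <- euclidean_distance(cohort$coords[, "mla", ], cohort$coords[, "iit", ])
  expect_equal(tab$coxal_bone_height, manual)
  expect_true(all(as.matrix(tab[, cols]) >= 0))
  ang <- tab[, reg$name[reg$kind == "angle"]]
  expect_true(all(ang >= 0 & ang <= 180))
})

test_that("ILD dataset enumerates all 561 canonical pairs", {
  cohort <- make_test_cohort(n = 2L, seed = 22L)
  ild <- compute_ild_dataset(cohort)
  cols <- measurement_columns(ild)
  expect_length(cols, 561L)
  # brute-force double-loop enumeration oracle
  nm <- landmark_names()
  brute <- character(0)
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (i < j) brute <- c(brute, paste0(nm[i], "-", nm[j]))
  }
  expect_equal(cols, brute)
  # shared definition with the first dataset
  tab <- compute_first_dataset(cohort)
  expect_equal(ild[["sps-pss"]], tab$coxal_bone_breadth)
})

test_that("measurements demand complete records", {
  cohort <- make_test_cohort(n = 2L, seed = 23L)
  cohort$coords[1L, "gsn", ] <- NA_real_
  expect_error(compute_first_dataset(cohort), "impute")
  expect_error(compute_ild_dataset(cohort), "impute")
})

test_that("measurements are rigid-motion and mirror invariant and scale equivariant", {
  cohort <- make_test_cohort(n = 3L, seed = 31L)
  tab <- compute_first_dataset(cohort)
  ild <- compute_ild_dataset(cohort)
  cols <- measurement_columns(tab)
  icols <- measurement_columns(ild)
  set.seed(32)
  for (rep in 1:3) {
    R <- random_rotation()
    b <- rnorm(3, 0, 100)
    moved <- transform_cohort(cohort, R, b)
    tab2 <- compute_first_dataset(moved)
    ild2 <- compute_ild_dataset(moved)
    expect_lt(max(abs(as.matrix(tab2[, cols]) / as.matrix(tab[, cols]) - 1)), 1e-9)
    expect_lt(max(abs(as.matrix(ild2[, icols]) / as.matrix(ild[, icols]) - 1)), 1e-9)
  }
  # mirror through the xy-plane
  M <- diag(c(1, 1, -1))
  tabm <- compute_first_dataset(transform_cohort(cohort, M))
  expect_lt(max(abs(as.matrix(tabm[, cols]) / as.matrix(tab[, cols]) - 1)), 1e-9)
  ildm <- compute_ild_dataset(transform_cohort(cohort, M))
  expect_lt(max(abs(as.matrix(ildm[, icols]) / as.matrix(ild[, icols]) - 1)), 1e-9)
  # scaling doubles lengths, leaves angles unchanged
  tabs <- compute_first_dataset(transform_cohort(cohort, diag(3) * 2))
  reg <- measurement_registry()
  lin <- reg$name[reg$kind != "angle"]
  ang <- reg$name[reg$kind == "angle"]
  expect_equal(as.matrix(tabs[, lin]), 2 * as.matrix(tab[, lin]))
  expect_equal(as.matrix(tabs[, ang]), as.matrix(tab[, ang]))
})

test_that("angles agree with the law of cosines applied to pairwise distances", {
  cohort <- make_test_cohort(n = 5L, seed = 41L)
  tab <- compute_first_dataset(cohort)
  reg <- measurement_registry()
  angles <- reg[reg$kind == "angle", ]
  for (i in seq_len(nrow(angles))) {
    a <- cohort$coords[, angles$lm1[i], ]
    v <- cohort$coords[, angles$lm2[i], ]
    b <- cohort$coords[, angles$lm3[i], ]
    d_av <- euclidean_distance(a, v)
    d_bv <- euclidean_distance(b, v)
    d_ab <- euclidean_distance(a, b)
    loc <- acos(pmin(1, pmax(-1, (d_av^2 + d_bv^2 - d_ab^2) /
                               (2 * d_av * d_bv)))) * 180 / pi
    expect_lt(max(abs(tab[[angles$name[i]]] - loc)), 1e-6)
  }
})
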