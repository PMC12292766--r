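#' Compute the 33-measurement battery (first dataset)
#'
#' Evaluates every measurement of [measurement_registry()] for each bone of a
#' complete cohort: linear measurements as Euclidean distances, heights as
#' point-to-line distances, angles as vertex angles in degrees.
#'
#' @param cohort a complete `landmark_cohort` (impute missing landmarks
#'   first; see [impute_cohort()]).
#' @return A data.frame: metadata columns (`individual_id`, `side`, `sex`,
#'   `age`, and `acquisition` when present) followed by the 33 measurement
#'   columns in table order.
#' @export
compute_first_dataset <- function(cohort) {
  check_complete(cohort)
  reg <- measurement_registry()
  co <- cohort$coords
  vals <- matrix(NA_real_, nrow = dim(co)[1L], ncol = nrow(reg),
                 dimnames = list(NULL, reg$name))
  for (i in seq_len(nrow(reg))) {
    p1 <- co[, reg$lm1[i], , drop = TRUE]
    p2 <- co[, reg$lm2[i], , drop = TRUE]
    p1 <- rbind3(p1); p2 <- rbind3(p2)
    vals[, i] <- switch(
      reg$kind[i],
      linear = euclidean_distance(p1, p2),
      height = point_line_height(p1, rbind3(co[, reg$lm2[i], , drop = TRUE]),
                                 rbind3(co[, reg$lm3[i], , drop = TRUE])),
      angle  = vertex_angle(p1, rbind3(co[, reg$lm2[i], , drop = TRUE]),
                            rbind3(co[, reg$lm3[i], , drop = TRUE]))
    )
  }
  cbind(cohort$meta, as.data.frame(vals))
}

#' Compute all 561 interlandmark distances (second dataset)
#'
#' @param cohort a complete `landmark_cohort`.
#' @return A data.frame: metadata columns followed by 561 distance columns
#'   named `"a-b"` in the canonical pair order of [ild_registry()].
#' @export
compute_ild_dataset <- function(cohort) {
  check_complete(cohort)
  reg <- ild_registry()
  co <- cohort$coords
  n <- dim(co)[1L]
  i1 <- match(reg$lm1, landmark_names())
  i2 <- match(reg$lm2, landmark_names())
  d2 <- (co[, i1, 1L, drop = FALSE] - co[, i2, 1L, drop = FALSE])^2 +
        (co[, i1, 2L, drop = FALSE] - co[, i2, 2L, drop = FALSE])^2 +
        (co[, i1, 3L, drop = FALSE] - co[, i2, 3L, drop = FALSE])^2
  vals <- sqrt(matrix(d2, nrow = n))
  colnames(vals) <- reg$name
  cbind(cohort$meta, as.data.frame(check.names = FALSE, vals))
}

check_complete <- function(cohort) {
  miss <- vapply(missing_landmarks(cohort), length, integer(1))
  if (any(miss > 0L))
    stop(sprintf(
      "%d record(s) have missing landmarks; run impute_cohort() first",
      sum(miss > 0L)))
  invisible(TRUE)
}

#' Measurement columns of a measurement table
#'
#' @param table a measurement table (data.frame from
#'   [compute_first_dataset()], [compute_ild_dataset()] or
#'   [generate_measurement_cohort()]).
#' @return Character vector of non-metadata column names.
#' @export
measurement_columns <- function(table) {
  setdiff(names(table), c(meta_columns(), "acquisition", "age_group"))
}

#' Write a measurement table to CSV
#' @param table measurement table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table from CSV
#' @param path CSV path written by [write_measurement_csv()].
#' @return data.frame with metadata and measurement columns.
#' @export
read_measurement_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
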