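#' Technical error of measurement (TEM)
#'
#' Multi-repeat anthropometric formula: with N subjects measured k times,
#' `TEM = sqrt( sum_i [ sum_j x_ij^2 - (sum_j x_ij)^2 / k ] / (N (k - 1)) )`,
#' i.e. the square root of the pooled within-subject variance of the repeats.
#'
#' @param values numeric N x k matrix: rows = subjects, columns = repeated
#'   acquisitions of one measurement.
#' @return TEM in the units of the measurement.
#' @export
tem <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (k < 2L) stop("tem: at least 2 repeats per subject are required")
  if (n < 1L) stop("tem: at least 1 subject is required")
  if (anyNA(values)) stop("tem: values must not contain missing cells")
  # centred evaluation of sum_j x^2 - (sum_j x)^2/k: algebraically identical,
  # avoids catastrophic cancellation when repeats are (nearly) identical
  ss <- rowSums((values - rowMeans(values))^2)
  sqrt(sum(ss) / (n * (k - 1L)))
}

#' Relative technical error of measurement (rTEM)
#'
#' @param tem_value TEM in measurement units.
#' @param grand_mean grand mean of all N x k values (must be positive).
#' @return rTEM as a percentage: `100 * TEM / grand_mean`.
#' @export
rtem <- function(tem_value, grand_mean) {
  if (!is.finite(grand_mean) || grand_mean <= 0)
    stop("rtem: grand mean must be positive")
  100 * tem_value / grand_mean
}

#' Intraobserver reliability study over repeated acquisitions
#'
#' Computes all 561 interlandmark distances for every acquisition of every
#' bone, then TEM and rTEM per distance per side, pooling subjects. With both
#' sides present this yields 2 x 561 = 1122 report rows. The interlandmark
#' battery is used because the named measurements either appear in it directly
#' or are derived from the same landmarks.
#'
#' @param repeat_cohort a `landmark_cohort` whose `meta` has an `acquisition`
#'   column; every (individual, side) must have the same number k >= 2 of
#'   acquisitions and complete landmarks.
#' @return A data.frame with columns `side`, `pair`, `grand_mean`, `tem_mm`,
#'   `rtem_pct`, one row per interlandmark distance per side.
#' @export
reliability_study <- function(repeat_cohort) {
  meta <- repeat_cohort$meta
  if (!"acquisition" %in% names(meta))
    stop("reliability_study: meta must contain an 'acquisition' column")
  ild <- compute_ild_dataset(repeat_cohort)
  pair_cols <- measurement_columns(ild)
  out <- list()
  for (sd_ in sort(unique(meta$side), decreasing = TRUE)) {
    sub <- ild[ild$side == sd_, , drop = FALSE]
    counts <- table(sub$individual_id)
    k <- unique(as.integer(counts))
    if (length(k) != 1L)
      stop("reliability_study: inconsistent repeat counts across subjects on side ", sd_)
    if (k < 2L)
      stop("reliability_study: at least 2 acquisitions per subject are required")
    subjects <- unique(sub$individual_id)
    tems <- numeric(length(pair_cols))
    means <- numeric(length(pair_cols))
    ord <- order(match(sub$individual_id, subjects), sub$acquisition)
    sub <- sub[ord, , drop = FALSE]
    for (j in seq_along(pair_cols)) {
      m <- matrix(sub[[pair_cols[j]]], nrow = length(subjects), byrow = TRUE)
      tems[j] <- tem(m)
      means[j] <- mean(m)
    }
    out[[sd_]] <- data.frame(side = sd_, pair = pair_cols,
                             grand_mean = means, tem_mm = tems,
                             rtem_pct = rtem_vec(tems, means),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

rtem_vec <- function(tems, means) {
  vapply(seq_along(tems), function(i) rtem(tems[i], means[i]), numeric(1))
}

#' Write a reliability report to CSV
#' @param report data.frame from [reliability_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reliability_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
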