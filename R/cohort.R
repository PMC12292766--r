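#' Construct a landmark cohort
#'
#' A landmark cohort holds one or more landmarked coxal bones: per-bone
#' metadata plus a bones x 34 x 3 array of millimetre coordinates in an
#' arbitrary (scanner) frame. Missingness is landmark-wise: a missing landmark
#' has all three coordinates `NA`.
#'
#' @param meta data.frame with columns `individual_id`, `side` ("right" or
#'   "left"), `sex` ("M", "F" or "unknown"), `age` (years); an optional
#'   `acquisition` column (integer) marks repeated acquisitions of the same
#'   bone for reliability studies.
#' @param coords numeric array of dimension `c(nrow(meta), 34, 3)`; the second
#'   dimension must be named with the registry abbreviations in registry
#'   order, the third `c("x", "y", "z")`.
#' @param provenance optional free-text provenance string.
#' @return An object of class `landmark_cohort`.
#' @export
landmark_cohort <- function(meta, coords, provenance = "") {
  stopifnot(is.data.frame(meta), is.array(coords), length(dim(coords)) == 3L)
  need <- c("individual_id", "side", "sex", "age")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("meta is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (dim(coords)[1L] != nrow(meta))
    stop("coords first dimension must match nrow(meta)")
  if (dim(coords)[2L] != 34L || dim(coords)[3L] != 3L)
    stop("coords must be bones x 34 landmarks x 3 axes")
  if (is.null(dimnames(coords)[[2L]]))
    dimnames(coords)[[2L]] <- landmark_names()
  if (!identical(dimnames(coords)[[2L]], landmark_names()))
    stop("coords landmark dimension must be named in registry order")
  dimnames(coords)[[3L]] <- c("x", "y", "z")
  bad_side <- !meta$side %in% c("right", "left")
  if (any(bad_side))
    stop("invalid side value(s): ", paste(unique(meta$side[bad_side]), collapse = ", "))
  bad_sex <- !meta$sex %in% c("M", "F", "unknown")
  if (any(bad_sex))
    stop("invalid sex value(s): ", paste(unique(meta$sex[bad_sex]), collapse = ", "))
  # per-axis partial missingness is not representable: a landmark is either
  # fully observed or fully missing
  na_cnt <- apply(is.na(coords), c(1L, 2L), sum)
  if (any(na_cnt %in% c(1L, 2L)))
    stop("missingness must be landmark-wise: found landmarks with 1 or 2 NA axes")
  structure(
    list(meta = meta, coords = coords, provenance = provenance),
    class = "landmark_cohort"
  )
}

#' @export
print.landmark_cohort <- function(x, ...) {
  n_missing <- sum(apply(is.na(x$coords[, , 1L, drop = FALSE]), 1L, any))
  cat(sprintf(
    "<landmark_cohort> %d bone record(s), %d individual(s); %d record(s) with missing landmarks\n",
    nrow(x$meta), length(unique(x$meta$individual_id)), n_missing))
  invisible(x)
}

#' Number of bone records in a cohort
#' @param cohort a `landmark_cohort`.
#' @return Integer count of rows (bone records).
#' @export
n_bones <- function(cohort) nrow(cohort$meta)

#' Missing landmarks per bone record
#' @param cohort a `landmark_cohort`.
#' @return A list (one element per record) of missing landmark abbreviations.
#' @export
missing_landmarks <- function(cohort) {
  miss <- is.na(cohort$coords[, , 1L, drop = FALSE])[, , 1L, drop = FALSE]
  lapply(seq_len(nrow(cohort$meta)), function(i) {
    landmark_names()[miss[i, , 1L]]
  })
}

#' Flatten cohort coordinates to a bones x 102 matrix
#'
#' Columns are ordered landmark-major (`mla_x`, `mla_y`, `mla_z`, `iit_x`,
#' ...), the layout used by the imputation model.
#' @param cohort a `landmark_cohort`.
#' @return Numeric matrix with 102 named columns.
#' @export
flatten_coords <- function(cohort) {
  co <- cohort$coords
  n <- dim(co)[1L]
  out <- matrix(aperm(co, c(1L, 3L, 2L)), nrow = n)
  colnames(out) <- as.vector(t(outer(landmark_names(), c("x", "y", "z"),
                                     paste, sep = "_")))
  out
}

#' Rebuild a coordinate array from a flat bones x 102 matrix
#' @param mat matrix as produced by [flatten_coords()].
#' @return bones x 34 x 3 array.
#' @export
unflatten_coords <- function(mat) {
  n <- nrow(mat)
  arr <- aperm(array(mat, dim = c(n, 3L, 34L)), c(1L, 3L, 2L))
  dimnames(arr) <- list(NULL, landmark_names(), c("x", "y", "z"))
  arr
}

#' Read a landmark cohort from long-format CSV
#'
#' The canonical interchange format: one row per observed landmark with header
#' columns `individual_id, side, sex, age, landmark, x, y, z` (and optionally
#' `acquisition`). Landmarks absent for a bone are recorded as missing.
#'
#' @param path path to the CSV file.
#' @return A `landmark_cohort`.
#' @export
read_landmark_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "side", "sex", "age", "landmark", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("landmark CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$landmark), landmark_names())
  if (length(bad))
    stop("unknown landmark abbreviation(s): ", paste(bad, collapse = ", "))
  has_acq <- "acquisition" %in% names(df)
  keycols <- c("individual_id", "side", if (has_acq) "acquisition")
  key <- do.call(paste, c(df[keycols], sep = "\r"))
  ukey <- unique(key)
  meta_rows <- match(ukey, key)
  meta <- df[meta_rows, c("individual_id", "side", "sex", "age",
                          if (has_acq) "acquisition"), drop = FALSE]
  rownames(meta) <- NULL
  coords <- array(NA_real_, dim = c(length(ukey), 34L, 3L),
                  dimnames = list(NULL, landmark_names(), c("x", "y", "z")))
  row_idx <- match(key, ukey)
  lm_idx <- match(df$landmark, landmark_names())
  dup <- duplicated(cbind(row_idx, lm_idx))
  if (any(dup)) {
    d <- df[dup, , drop = FALSE][1L, ]
    stop(sprintf("duplicate landmark '%s' for bone (%s, %s)",
                 d$landmark, d$individual_id, d$side))
  }
  coords[cbind(row_idx, lm_idx, 1L)] <- df$x
  coords[cbind(row_idx, lm_idx, 2L)] <- df$y
  coords[cbind(row_idx, lm_idx, 3L)] <- df$z
  landmark_cohort(meta, coords, provenance = paste0("read_landmark_csv:", path))
}

#' Write a landmark cohort to long-format CSV
#'
#' Missing landmarks are omitted (one row per observed landmark), so a
#' write/read round trip reproduces the cohort exactly.
#' @param cohort a `landmark_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(cohort, path) {
  co <- cohort$coords
  n <- dim(co)[1L]
  has_acq <- "acquisition" %in% names(cohort$meta)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    obs <- which(!is.na(co[i, , 1L]))
    m <- cohort$meta[i, , drop = FALSE]
    # %.17g guarantees the write/read round trip is bit-exact
    row <- data.frame(
      individual_id = m$individual_id, side = m$side, sex = m$sex, age = m$age,
      landmark = landmark_names()[obs],
      x = sprintf("%.17g", co[i, obs, 1L]),
      y = sprintf("%.17g", co[i, obs, 2L]),
      z = sprintf("%.17g", co[i, obs, 3L]),
      stringsAsFactors = FALSE
    )
    if (has_acq) row$acquisition <- m$acquisition
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one bone from a MeshLab PickedPoints (.pp) file
#'
#' Parses the XML dialect written by MeshLab's point-picking tool
#' (`<PickedPoints><point name=... x=... y=... z=... active=.../>`). Point
#' names are matched case-insensitively against the landmark registry;
#' landmarks without a point element are recorded as missing. Points with
#' `active="0"` are skipped.
#'
#' @param path path to the .pp file.
#' @param individual_id,side,sex,age metadata for the record; `sex` defaults
#'   to `"unknown"`.
#' @return A one-record `landmark_cohort`.
#' @export
read_picked_points <- function(path, individual_id, side,
                               sex = "unknown", age = NA_real_) {
  doc <- xml2::read_xml(path)
  pts <- xml2::xml_find_all(doc, ".//point")
  nm_raw <- xml2::xml_attr(pts, "name")
  active <- xml2::xml_attr(pts, "active")
  keep <- is.na(active) | active != "0"
  pts <- pts[keep]; nm_raw <- nm_raw[keep]
  nm <- tolower(nm_raw)
  bad <- setdiff(unique(nm), landmark_names())
  if (length(bad))
    stop("unknown landmark name(s) in PickedPoints file: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(nm))
    stop("repeated landmark name(s) in PickedPoints file: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  coords <- array(NA_real_, dim = c(1L, 34L, 3L),
                  dimnames = list(NULL, landmark_names(), c("x", "y", "z")))
  idx <- match(nm, landmark_names())
  coords[cbind(1L, idx, 1L)] <- as.numeric(xml2::xml_attr(pts, "x"))
  coords[cbind(1L, idx, 2L)] <- as.numeric(xml2::xml_attr(pts, "y"))
  coords[cbind(1L, idx, 3L)] <- as.numeric(xml2::xml_attr(pts, "z"))
  meta <- data.frame(individual_id = individual_id, side = side, sex = sex,
                     age = age, stringsAsFactors = FALSE)
  landmark_cohort(meta, coords, provenance = paste0("read_picked_points:", path))
}

#' Validate a landmark cohort
#'
#' Report-only data screening: flags records with more than 3 missing
#' landmarks (beyond the supported imputation regime), non-finite observed
#' coordinates, duplicate (individual, side) records, and sex/age metadata
#' that differs between the two sides of one individual. The cohort is not
#' modified.
#'
#' @param cohort a `landmark_cohort`.
#' @return A data.frame of findings with columns `individual_id`, `side`,
#'   `check`, `detail`; zero rows when the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  meta <- cohort$meta
  findings <- list()
  add <- function(id, side, check, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      individual_id = id, side = side, check = check, detail = detail,
      stringsAsFactors = FALSE)
  }
  miss <- missing_landmarks(cohort)
  for (i in seq_len(nrow(meta))) {
    k <- length(miss[[i]])
    if (k > 3L)
      add(meta$individual_id[i], meta$side[i], "exceeds_imputable_missingness",
          sprintf("%d missing landmarks (max 3 supported): %s",
                  k, paste(miss[[i]], collapse = ",")))
    slice <- cohort$coords[i, , , drop = FALSE]
    if (any(!is.finite(slice) & !is.na(slice)))
      add(meta$individual_id[i], meta$side[i], "nonfinite_coordinates",
          "observed coordinates contain Inf/NaN")
  }
  has_acq <- "acquisition" %in% names(meta)
  keycols <- c("individual_id", "side", if (has_acq) "acquisition")
  key <- do.call(paste, c(meta[keycols], sep = "\r"))
  for (k in unique(key[duplicated(key)])) {
    i <- which(key == k)[1L]
    add(meta$individual_id[i], meta$side[i], "duplicate_record",
        "duplicate (individual_id, side) record")
  }
  for (id in unique(meta$individual_id)) {
    rows <- meta[meta$individual_id == id, , drop = FALSE]
    if (length(unique(rows$sex)) > 1L)
      add(id, "both", "inconsistent_metadata", "sex differs between sides")
    if (length(unique(rows$age)) > 1L)
      add(id, "both", "inconsistent_metadata", "age differs between sides")
  }
  if (!length(findings))
    return(data.frame(individual_id = character(), side = character(),
                      check = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Combine landmark cohorts
#' @param ... `landmark_cohort` objects.
#' @return A single `landmark_cohort` with rows stacked in order.
#' @export
bind_cohorts <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, logical(1), "landmark_cohort")))
  meta <- do.call(rbind, lapply(xs, `[[`, "meta"))
  rownames(meta) <- NULL
  coords <- do.call(abind3, lapply(xs, `[[`, "coords"))
  landmark_cohort(meta, coords,
                  provenance = paste(vapply(xs, `[[`, "", "provenance"),
                                     collapse = " + "))
}

# bind 3d arrays along the first dimension
abind3 <- function(...) {
  xs <- list(...)
  ns <- vapply(xs, function(a) dim(a)[1L], integer(1))
  out <- array(NA_real_, dim = c(sum(ns), dim(xs[[1L]])[2L], dim(xs[[1L]])[3L]),
               dimnames = c(list(NULL), dimnames(xs[[1L]])[2:3]))
  at <- 0L
  for (a in xs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}
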