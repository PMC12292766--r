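# fixtures are generated in code: no data files

# a small non-degenerate cohort: jittered copies of the hand-built template
make_test_cohort <- function(n = 4L, seed = 1L, jitter_sd = 2) {
  set.seed(seed)
  tmpl <- base_template()
  coords <- array(NA_real_, dim = c(n, 34L, 3L),
                  dimnames = list(NULL, landmark_names(), c("x", "y", "z")))
  for (i in seq_len(n))
    coords[i, , ] <- tmpl + matrix(rnorm(102, 0, jitter_sd), 34L, 3L)
  meta <- data.frame(
    individual_id = sprintf("T%03d", seq_len(n)),
    side = rep(c("right", "left"), length.out = n),
    sex = rep(c("M", "F"), length.out = n),
    age = seq(30, 70, length.out = n),
    stringsAsFactors = FALSE)
  landmark_cohort(meta, coords)
}

# write a MeshLab PickedPoints XML file for one bone
write_pp_file <- function(path, coords, names = rownames(coords),
                          active = rep("1", nrow(coords))) {
  lines <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    "<!DOCTYPE PickedPoints>",
    "<PickedPoints>",
    " <DocumentData>",
    '  <DataFileName name="bone.stl"/>',
    " </DocumentData>",
    sprintf(' <point active="%s" name="%s" x="%.6f" y="%.6f" z="%.6f"/>',
            active, names, coords[, 1L], coords[, 2L], coords[, 3L]),
    "</PickedPoints>")
  writeLines(lines, path)
  path
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3L))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# apply an affine map to every bone of a cohort
transform_cohort <- function(cohort, A = diag(3), b = c(0, 0, 0)) {
  out <- cohort
  for (i in seq_len(n_bones(cohort))) {
    out$coords[i, , ] <- sweep(cohort$coords[i, , ] %*% t(A), 2L, -b)
  }
  out
}
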