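#' Euclidean distance between two 3D points
#'
#' Also accepts n x 3 matrices for row-wise evaluation.
#' @param p,q numeric 3-vectors (or n x 3 matrices) in mm.
#' @return Distance(s) in mm.
#' @export
euclidean_distance <- function(p, q) {
  p <- rbind3(p); q <- rbind3(q)
  if (any(!is.finite(p)) || any(!is.finite(q)))
    stop("euclidean_distance: non-finite input")
  drop(sqrt(rowSums((p - q)^2)))
}

#' Angle at a vertex between two arms, in degrees
#'
#' The angle between vectors `a - v` and `b - v`, computed as the arccosine of
#' their normalized dot product (clamped to `[-1, 1]` so collinear arms return
#' exactly 0 or 180 rather than NaN). Row-wise over n x 3 matrices.
#'
#' @param a,b arm endpoint coordinates.
#' @param v vertex coordinates.
#' @return Angle(s) in degrees, in `[0, 180]`.
#' @export
vertex_angle <- function(a, v, b) {
  a <- rbind3(a); v <- rbind3(v); b <- rbind3(b)
  u1 <- a - v
  u2 <- b - v
  n1 <- sqrt(rowSums(u1^2))
  n2 <- sqrt(rowSums(u2^2))
  if (any(n1 == 0 | n2 == 0))
    stop("vertex_angle: degenerate geometry (arm endpoint coincides with vertex)")
  cosang <- pmin(1, pmax(-1, rowSums(u1 * u2) / (n1 * n2)))
  drop(acos(cosang) * 180 / pi)
}

#' Perpendicular distance from a point to a line
#'
#' Distance from `apex` to the infinite line through `base1` and `base2`
#' (the triangle-height construction). Row-wise over n x 3 matrices.
#'
#' @param apex point coordinates.
#' @param base1,base2 two distinct points defining the line.
#' @return Distance(s) in mm.
#' @export
point_line_height <- function(apex, base1, base2) {
  apex <- rbind3(apex); base1 <- rbind3(base1); base2 <- rbind3(base2)
  d <- base2 - base1
  dn2 <- rowSums(d^2)
  if (any(dn2 == 0))
    stop("point_line_height: degenerate geometry (coincident baseline points)")
  w <- apex - base1
  t <- rowSums(w * d) / dn2
  proj <- base1 + d * t
  drop(sqrt(rowSums((apex - proj)^2)))
}

# coerce a 3-vector or n x 3 matrix to matrix form
rbind3 <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("expected 3 columns of coordinates")
    x
  } else {
    if (length(x) != 3L) stop("expected a 3-vector")
    matrix(as.numeric(x), nrow = 1L)
  }
}
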