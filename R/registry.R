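#' The 34-landmark coxal bone registry
#'
#' Returns the fixed, ordered schema of the 34 anatomical landmarks of the
#' coxal (hip) bone used throughout the package. The order is the canonical
#' column order of every coordinate matrix; all measurement definitions refer
#' to these abbreviations.
#'
#' @return A data.frame with columns `abbr` (unique landmark abbreviation) and
#'   `description` (anatomical definition), 34 rows, in registry order.
#' @examples
#' reg <- landmark_registry()
#' nrow(reg)  # 34
#' @export
landmark_registry <- function() {
  reg <- data.frame(
    abbr = c(
      "mla", "iit", "sps", "pss", "ass", "ais", "pis", "mli", "as", "asa",
      "ai", "ap", "lss", "sfo", "ifo", "mfo", "lfo", "pirt", "is", "ips",
      "iipr", "lit", "gsn", "lsn", "sij", "pgl", "pla", "plp", "mipr", "lsi",
      "maps", "mpps", "ain", "pin"
    ),
    description = c(
      "most lateral point of the iliac ala",
      "most inferior point of the ischial tuberosity",
      "superior point of the pubic symphysis",
      "posterior superior iliac spine",
      "anterior superior iliac spine",
      "anterior inferior iliac spine",
      "posterior inferior iliac spine",
      "most lateral point of the pelvic inlet",
      "superior point of the acetabulum at the pubic-iliac junction",
      "superior point of the acetabular margin at the base of the iliac ala",
      "inferior point of the acetabular margin",
      "posterior point of the acetabular margin",
      "most medial point of the superior portion of the lunate surface",
      "most superior point of the obturator foramen margin",
      "most inferior point of the obturator foramen margin",
      "most medial point of the obturator foramen",
      "most lateral point of the obturator foramen",
      "piriform tubercle",
      "ischial spine",
      "inferior point of the pubic symphysis",
      "inferior point of the ischiopubic ramus",
      "most lateral point of the ischial tuberosity",
      "deepest point of the greater sciatic notch",
      "deepest point of the lesser sciatic notch",
      "most anterior point of the sacroiliac joint on the pelvic inlet outline",
      "crossing point of the iliac crest and the posterior gluteal line",
      "anterior end of the pectineal line",
      "posterior end of the pectineal line",
      "mid-point of the ischiopubic ramus",
      "most medial point of the inferior portion of the lunate surface",
      "mid-anterior point of the pubic symphysis",
      "mid-posterior point of the pubic symphysis",
      "deepest point of the anterior interspinous notch",
      "deepest point of the posterior interspinous notch"
    ),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(reg) == 34L, !anyDuplicated(reg$abbr))
  reg
}

#' Landmark abbreviations in registry order
#' @return Character vector of length 34.
#' @export
landmark_names <- function() landmark_registry()$abbr

#' The 33-measurement battery (first dataset)
#'
#' Definitions of the standard coxal bone measurements: 27 linear interlandmark
#' distances, 3 point-to-line heights, and 3 vertex angles, in canonical table
#' order. Linear measurements name two landmarks; heights name the apex first
#' and then the two baseline landmarks; angles name the two arm endpoints with
#' the vertex in the middle.
#'
#' @return A data.frame with columns `name`, `kind` (one of `"linear"`,
#'   `"height"`, `"angle"`) and `lm1`, `lm2`, `lm3` (landmark abbreviations;
#'   `lm3` is `NA` for linear measurements).
#' @export
measurement_registry <- function() {
  def <- function(name, kind, a, b, c = NA_character_) {
    data.frame(name = name, kind = kind, lm1 = a, lm2 = b, lm3 = c,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    def("coxal_bone_height",                      "linear", "mla", "iit"),
    def("coxal_bone_breadth",                     "linear", "sps", "pss"),
    def("ala_breadth_superior_spines",            "linear", "ass", "pss"),
    def("ala_breadth_inferior_spines",            "linear", "ais", "pis"),
    def("ala_height",                             "linear", "mla", "mli"),
    def("pubic_length",                           "linear", "sps", "as"),
    def("vertical_acetabular_diameter",           "linear", "asa", "ai"),
    def("transversal_acetabular_diameter",        "linear", "ap",  "lss"),
    def("vertical_diameter_obturator_foramen",    "linear", "sfo", "ifo"),
    def("transversal_diameter_obturator_foramen", "linear", "mfo", "lfo"),
    def("greater_sciatic_notch_breadth",          "linear", "pirt", "is"),
    def("ischiopubic_ramus_length",               "linear", "ips", "iipr"),
    def("ischial_tuberosity_length",              "linear", "lit", "iipr"),
    def("intersciatic_distance",                  "linear", "gsn", "lsn"),
    def("anterior_interspinal_distance",          "linear", "ass", "ais"),
    def("posterior_interspinal_distance",         "linear", "pss", "pis"),
    def("spino_sciatic_distance",                 "linear", "ais", "gsn"),
    def("anterior_spino_auricular_distance",      "linear", "ais", "sij"),
    def("posterior_spino_auricular_distance",     "linear", "pis", "sij"),
    def("post_acetabular_ischium_distance",       "linear", "ap",  "iipr"),
    def("gluteo_sciatic_distance",                "linear", "pgl", "gsn"),
    def("pectineal_line_length",                  "linear", "pla", "plp"),
    def("lunate_ramus_distance",                  "linear", "mipr", "lsi"),
    def("greater_sciatic_acetabular_distance",    "linear", "gsn", "ap"),
    def("lesser_sciatic_acetabular_distance",     "linear", "lsn", "ai"),
    def("pubic_symphysis_height",                 "linear", "sps", "ips"),
    def("pubic_symphysis_width",                  "linear", "maps", "mpps"),
    def("greater_sciatic_notch_height",           "height", "gsn", "pirt", "is"),
    def("anterior_interspinal_height",            "height", "ain", "ass", "ais"),
    def("posterior_interspinal_height",           "height", "pin", "pss", "pis"),
    def("greater_sciatic_notch_angle",            "angle",  "pirt", "gsn", "is"),
    def("ischiopubic_angle",                      "angle",  "sps", "ips", "iipr"),
    def("ischial_angle",                          "angle",  "mipr", "iit", "lit")
  )
  lm_ok <- c(out$lm1, out$lm2, out$lm3[!is.na(out$lm3)]) %in% landmark_names()
  stopifnot(nrow(out) == 33L, all(lm_ok),
            sum(out$kind == "linear") == 27L,
            sum(out$kind == "angle") == 3L,
            sum(out$kind == "height") == 3L)
  out
}

#' All interlandmark distance pairs (second dataset)
#'
#' Canonical enumeration of the C(34, 2) = 561 unordered landmark pairs, each
#' named `"a-b"` with `a` preceding `b` in registry order.
#'
#' @return A data.frame with columns `name`, `lm1`, `lm2`; 561 rows.
#' @export
ild_registry <- function() {
  lm <- landmark_names()
  idx <- utils::combn(length(lm), 2L)
  data.frame(
    name = paste(lm[idx[1L, ]], lm[idx[2L, ]], sep = "-"),
    lm1 = lm[idx[1L, ]],
    lm2 = lm[idx[2L, ]],
    stringsAsFactors = FALSE
  )
}

#' Names of the measurement metadata columns
#' @return Character vector `c("individual_id", "side", "sex", "age")`.
#' @export
meta_columns <- function() c("individual_id", "side", "sex", "age")
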