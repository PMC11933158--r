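#' Severity grading of chronic mitral regurgitation
#'
#' Classifies a quantitative metric according to the American Society of
#' Echocardiography boundaries. RVol and EROa use the standard four grades
#' (mild, moderate, moderate-severe, severe); the vena contracta width uses
#' three. Class boundaries are closed on the lower edge (a value exactly on
#' a boundary belongs to the higher grade), except that the VCW moderate
#' band is the closed interval 0.3-0.7 cm as printed.
#'
#' \tabular{lllll}{
#'   metric \tab mild \tab moderate \tab moderate-severe \tab severe \cr
#'   RVol (ml) \tab < 30 \tab 30-44 \tab 45-59 \tab >= 60 \cr
#'   EROa (cm^2) \tab < 0.20 \tab 0.20-0.29 \tab 0.30-0.39 \tab >= 0.40 \cr
#'   VCW (cm) \tab < 0.3 \tab 0.3-0.7 \tab \tab > 0.7 \cr
#' }
#'
#' @param metric one of \code{"RVol"}, \code{"EROa"}, \code{"VCW"}.
#' @param value the measured value (ml, cm^2 or cm); non-negative,
#'   vectorized.
#' @return character vector of grades among \code{"mild"},
#'   \code{"moderate"}, \code{"moderate-severe"}, \code{"severe"}.
#' @examples
#' grade_severity("RVol", 35)     # "moderate"
#' grade_severity("EROa", 0.45)   # "severe"
#' @export
grade_severity <- function(metric = c("RVol", "EROa", "VCW"), value) {
  metric <- match.arg(metric)
  if (any(value < 0)) stop("'value' must be non-negative")
  if (metric == "VCW") {
    return(ifelse(value < 0.3, "mild",
                  ifelse(value <= 0.7, "moderate", "severe")))
  }
  breaks <- switch(metric, RVol = c(30, 45, 60), EROa = c(0.20, 0.30, 0.40))
  labels <- c("mild", "moderate", "moderate-severe", "severe")
  labels[findInterval(value, breaks) + 1L]
}
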