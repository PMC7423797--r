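#' @keywords internal
"_PACKAGE"

## Subgroup space: 9 age bands x 2 nodal categories x 2 pT stages x
## 2 sidedness levels (72 clinical subgroups), x 3 biomarker classes = 216.

#' Age bands of the modeled population
#'
#' The model covers ages 50-95 in nine 5-year bands. Patients younger than
#' 50 are outside the modeled population, so the youngest band is 50-54.
#'
#' @return Character vector of the nine ordered band labels.
#' @export
age_bands <- function() {
  c("50-54", "55-59", "60-64", "65-69", "70-74",
    "75-79", "80-84", "85-89", "90-95")
}

#' @rdname age_bands
#' @export
age_band_breaks <- function() seq(50, 95, by = 5)

#' Covariate levels of the subgroup space
#'
#' @name subgroup_levels
#' @return Character vectors of the factor levels used throughout the
#'   package. The first level of each is the reference level of the
#'   transition regressions (`LT10`, `pT3`, `right`).
NULL

#' @rdname subgroup_levels
#' @export
lymph_node_levels <- function() c("LT10", "GE10")

#' @rdname subgroup_levels
#' @export
pt_stage_levels <- function() c("pT3", "pT4")

#' @rdname subgroup_levels
#' @export
sidedness_levels <- function() c("right", "left")

#' @rdname subgroup_levels
#' @export
biomarker_levels <- function() c("MSI", "MSSdwt", "MSSmut")

#' Enumerate the model's subgroup cells
#'
#' @param biomarker If `TRUE` (default) cross the 72 clinical subgroups with
#'   the three biomarker classes, giving 216 cells; otherwise return the 72
#'   clinical subgroups.
#' @return A data.frame with columns `age_band`, `lymph_nodes`, `pt_stage`,
#'   `sidedness` and (optionally) `biomarker`, one row per cell.
#' @export
subgroup_grid <- function(biomarker = TRUE) {
  cols <- list(age_band = age_bands(),
               lymph_nodes = lymph_node_levels(),
               pt_stage = pt_stage_levels(),
               sidedness = sidedness_levels())
  if (biomarker) cols$biomarker <- biomarker_levels()
  g <- expand.grid(cols, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  class(g) <- c("subgroup_grid", "data.frame")
  g
}

#' Construct a single subgroup profile
#'
#' @param age_band One of [age_bands()].
#' @param lymph_nodes `"LT10"` (fewer than 10 nodes evaluated) or `"GE10"`.
#' @param pt_stage `"pT3"` or `"pT4"`.
#' @param sidedness `"right"` or `"left"` primary tumor location.
#' @param biomarker `"MSI"`, `"MSSdwt"` or `"MSSmut"`.
#' @return A named list of class `subgroup_profile`.
#' @export
subgroup_profile <- function(age_band, lymph_nodes = "LT10",
                             pt_stage = "pT3", sidedness = "right",
                             biomarker = "MSSdwt") {
  sg <- list(age_band = age_band, lymph_nodes = lymph_nodes,
             pt_stage = pt_stage, sidedness = sidedness,
             biomarker = biomarker)
  validate_subgroup(sg)
  class(sg) <- "subgroup_profile"
  sg
}

validate_subgroup <- function(sg) {
  stopifnot(sg$age_band %in% age_bands(),
            sg$lymph_nodes %in% lymph_node_levels(),
            sg$pt_stage %in% pt_stage_levels(),
            sg$sidedness %in% sidedness_levels(),
            sg$biomarker %in% biomarker_levels())
  invisible(sg)
}
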