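#' Default region-of-interest dictionary
#'
#' The 40-region bilateral scheme used throughout the package: 28 cortical
#' thickness ROIs (14 Desikan-Killiany cortical parcels per hemisphere) and
#' 12 mesiotemporal/subcortical volume ROIs (hippocampus, amygdala,
#' thalamus, caudate, pallidum, putamen per hemisphere).
#'
#' @return A `roi_dictionary` data frame with columns `region_name`,
#'   `hemisphere` (`left`/`right`) and `tissue_class`
#'   (`cortical_thickness`/`subcortical_volume`).
#' @export
#' @examples
#' d <- default_roi_dictionary()
#' table(d$tissue_class)
default_roi_dictionary <- function() {
  cortical <- c(
    "superior_frontal", "caudal_middle_frontal", "pars_triangularis",
    "precentral", "paracentral", "superior_temporal", "transverse_temporal",
    "middle_temporal", "inferior_temporal", "supramarginal", "precuneus",
    "posterior_cingulate", "lingual", "cuneus")
  subcortical <- c("hippocampus", "amygdala", "thalamus", "caudate",
                   "pallidum", "putamen")
  base <- c(cortical, subcortical)
  cls <- c(rep("cortical_thickness", length(cortical)),
           rep("subcortical_volume", length(subcortical)))
  d <- data.frame(
    region_name = c(paste0("left_", base), paste0("right_", base)),
    hemisphere = rep(c("left", "right"), each = length(base)),
    tissue_class = rep(cls, 2),
    stringsAsFactors = FALSE)
  roi_dictionary(d)
}

#' Construct and validate an ROI dictionary
#'
#' @param d data frame with columns `region_name`, `hemisphere`,
#'   `tissue_class`.
#' @return Validated `roi_dictionary`.
#' @export
roi_dictionary <- function(d) {
  stopifnot(is.data.frame(d),
            all(c("region_name", "hemisphere", "tissue_class") %in% names(d)))
  if (anyDuplicated(d$region_name))
    stop("duplicated region names in dictionary")
  if (!all(d$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  if (!all(d$tissue_class %in% c("cortical_thickness", "subcortical_volume")))
    stop("unknown tissue_class")
  # each left region must have a right counterpart with the same base name
  lf <- sub("^left_", "", d$region_name[d$hemisphere == "left"])
  rt <- sub("^right_", "", d$region_name[d$hemisphere == "right"])
  if (!setequal(lf, rt))
    stop("left/right regions are not paired")
  class(d) <- c("roi_dictionary", "data.frame")
  d
}

# base region name without the hemisphere prefix
roi_base_name <- function(region_name) {
  sub("^(left|right|ipsi|contra)_", "", region_name)
}
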