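TERRITORIES <- c("callosomarginal", "precentral", "central", "parietal",
                 "angular", "temporal", "posterior", "pericallosal",
                 "lenticular", "thalamus", "hippocampus", "cerebellum")

#' The 24 arterial territory identifiers
#'
#' Brain-perfusion SPECT ROIs are aggregated into 12 arterial
#' territories per hemisphere (callosomarginal, precentral, central,
#' parietal, angular, temporal, posterior, pericallosal, lenticular,
#' thalamus, hippocampus, cerebellum). Region identifiers are
#' `"{territory}_{hemisphere}"` in lowercase snake_case, right before
#' left within each territory, giving a stable 1..24 region numbering.
#'
#' @return character vector of the 24 legal region names.
#' @export
territory_names <- function() {
  as.vector(t(outer(TERRITORIES, c("right", "left"), paste, sep = "_")))
}

#' Mapping from region identifiers to display names
#'
#' @return a data.frame with `region_id` (1-24), `region` (snake_case
#'   identifier), `territory`, `hemisphere`, and `display` (the
#'   conventional figure label, e.g. "R cal. marginal").
#' @export
territory_display_map <- function() {
  regions <- territory_names()
  territory <- sub("_(right|left)$", "", regions)
  hemisphere <- sub("^.*_", "", regions)
  display_base <- c(
    callosomarginal = "cal. marginal", precentral = "precentral",
    central = "central", parietal = "parietal", angular = "angular",
    temporal = "temporal", posterior = "posterior",
    pericallosal = "pericallosal", lenticular = "lenticular",
    thalamus = "thalamus", hippocampus = "hippocampus",
    cerebellum = "cerebellum")
  data.frame(
    region_id = seq_along(regions),
    region = regions,
    territory = territory,
    hemisphere = hemisphere,
    display = paste(ifelse(hemisphere == "right", "R", "L"),
                    display_base[territory]),
    stringsAsFactors = FALSE)
}
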