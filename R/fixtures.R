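#' The MS basal recipe
#'
#' Murashige-Skoog mineral salts (mg/L) with the standard MS vitamins kept
#' as passthrough metadata.
#'
#' @return A [medium_recipe()] of the 14 MS mineral salts.
#' @export
ms_recipe <- function() {
  standard_media()$MS
}

#' Bundled reference media
#'
#' The five media of the validation experiment: the optimized `R` medium and
#' the MS, B5, St and Ha standards, as printed recipes (minerals in mg/L;
#' vitamins carried as passthrough).
#'
#' @return Named list of [medium_recipe()] objects (`R`, `MS`, `B5`, `St`,
#'   `Ha`).
#' @export
standard_media <- function() {
  tab <- utils::read.csv(pm_extdata("standard_media_table8.csv"),
                         check.names = FALSE)
  media <- setdiff(names(tab), c("component", "type"))
  out <- lapply(media, function(m) {
    minerals <- tab$type == "mineral" & !is.na(tab[[m]])
    vits <- tab$type == "vitamin" & !is.na(tab[[m]])
    medium_recipe(
      stats::setNames(tab[[m]][minerals], tab$component[minerals]),
      label = m,
      passthrough = stats::setNames(as.character(tab[[m]][vits]),
                                    tab$component[vits]))
  })
  stats::setNames(out, media)
}

#' The 36-treatment study design
#'
#' The five-factor design actually run in the study: 33 generated runs
#' (including three replicate pairs) plus three MS control rows. Shipped as
#' a fixture: the exact 33 runs come from closed-source design software and
#' are not a generation target of [d_optimal()].
#'
#' @return Data frame with factor columns (multiplier units) plus
#'   `replicate_of` and `is_control`.
#' @export
kiwi_design <- function() {
  d <- utils::read.csv(pm_extdata("design_table2.csv"))
  d$is_control <- as.logical(d$is_control)
  d
}

#' Printed ion table and responses of the study
#'
#' The 34-row treatment table as printed: 18 ion concentrations (mM) and
#' mean/SD of the six shoot responses (SN, SL, LA, SQ, BC, H) per medium
#' (treatments 1-33 plus the MS control mean).
#'
#' @return Data frame with `media`, the 18 ion columns, and
#'   `<response>_mean` / `<response>_sd` columns.
#' @export
kiwi_responses <- function() {
  utils::read.csv(pm_extdata("ion_table3_printed.csv"), check.names = FALSE)
}

#' Response names
#' @return Character vector of the six modeled responses.
#' @export
response_names <- function() c("SN", "SL", "LA", "SQ", "BC", "H")

#' Recomputed full-precision ion table of the study
#'
#' The 34 x 18 ion matrix recomputed from the design multipliers and the MS
#' recipe at full precision (one row per medium: treatments 1-33 and MS; the
#' three printed MS control rows collapse to one, matching the printed
#' response table).
#'
#' @return Numeric matrix, 34 x 18, rownames the media labels.
#' @export
kiwi_ion_table <- function() {
  d <- kiwi_design()
  d34 <- d[1:34, ]  # controls 34-36 are identical MS rows
  X <- design_to_ion_table(d34[, names(factor_groups())])
  rownames(X) <- c(as.character(1:33), "MS")
  X
}

#' Printed fuzzy dominance ranges of the study
#'
#' The per-ion, per-output low/mid/high dominance intervals as printed,
#' used as comparison fixture for [fuzzy_partition()] geometry.
#'
#' @return Data frame with columns `ion`, `output`, `level`, `lo`, `hi`.
#' @export
kiwi_fuzzy_ranges <- function() {
  utils::read.csv(pm_extdata("fuzzy_ranges_table9.csv"))
}

#' Validation experiment summaries
#'
#' Mean, SD and group size of each response under the five reference media
#' in the validation experiment (n = 45 explants per medium), plus the
#' printed Tukey letter groupings where the source reported them.
#'
#' @return Data frame with columns `response`, `medium`, `mean`, `sd`, `n`,
#'   `letters`.
#' @export
kiwi_validation <- function() {
  utils::read.csv(pm_extdata("validation_table8.csv"),
                  colClasses = c(letters = "character"))
}
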