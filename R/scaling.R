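#' Scale per-woman savings to the national population
#'
#' Eligible women per year = `round(annual_births x p_suspected x
#' p_preterm_presentation)` (rounded to the nearest woman before
#' multiplying); annual saving = eligible women x per-woman saving with the
#' test cost included.  With 646,794 births, 10% investigated for suspected
#' pre-eclampsia, 30% presenting preterm and a GBP 149 per-woman saving this
#' gives 19,404 women and GBP 2,891,196 per year.
#'
#' @param annual_births live births per year.
#' @param p_suspected fraction of pregnancies investigated for suspected
#'   pre-eclampsia.
#' @param p_preterm_presentation fraction of those presenting before 37
#'   weeks.
#' @param per_woman_saving_gbp net saving per woman tested (GBP, test cost
#'   included).
#' @return list with `eligible_women` (integer count) and
#'   `annual_saving_gbp`.
#' @examples
#' scale_to_population(646794, 0.10, 0.30, 149)
#' @export
scale_to_population <- function(annual_births, p_suspected,
                                p_preterm_presentation,
                                per_woman_saving_gbp) {
  stopifnot(annual_births >= 0,
            p_suspected >= 0, p_suspected <= 1,
            p_preterm_presentation >= 0, p_preterm_presentation <= 1)
  eligible <- round(annual_births * p_suspected * p_preterm_presentation)
  list(eligible_women = eligible,
       annual_saving_gbp = eligible * per_woman_saving_gbp)
}
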