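# The published cohort's univariate counts, shipped as a fixture.
# Counts are transcribed from the printed association table (n = 2395,
# 370 AKI); reference-group rows not printed for binary variables, and
# the normonatremia/normokalemia rows, are derived by subtraction from
# the column totals.

#' Published cohort counts as contingency tables
#'
#' Returns the printed per-variable counts of the 2395-patient cohort
#' (370 AKI episodes) as \code{\link{contingency_table}}s keyed by
#' variable, including the derived reference rows (e.g. normokalemia:
#' 2395 - 333 - 24 = 2038 patients, 370 - 122 - 20 = 228 AKI). Every
#' table column-sums to 2395 total / 370 AKI.
#'
#' @return Named list of \code{contingency_table}s.
#' @export
table1_fixture <- function() {
  reg <- variable_registry()
  mk <- function(var, aki, non_aki) {
    contingency_table(reg[[var]]$levels, aki, non_aki,
                      reference = reg[[var]]$reference,
                      ordinal = reg[[var]]$ordinal)
  }
  list(
    age_band       = mk("age_band", c(57, 78, 172, 63), c(156, 461, 1064, 344)),
    gender         = mk("gender", c(184, 186), c(1191, 834)),
    hypertension   = mk("hypertension", c(295, 75), c(1627, 398)),
    diabetes       = mk("diabetes", c(211, 159), c(1370, 655)),
    hm_category    = mk("hm_category", c(261, 48, 61), c(1680, 153, 192)),
    admission_type = mk("admission_type", c(329, 41), c(1903, 122)),
    treatment      = mk("treatment", c(23, 334, 13), c(286, 1702, 37)),
    alt_high       = mk("alt_high", c(335, 35), c(1910, 115)),
    ast_high       = mk("ast_high", c(308, 62), c(1817, 208)),
    tbil_high      = mk("tbil_high", c(353, 17), c(1952, 73)),
    scr_high       = mk("scr_high", c(291, 79), c(1991, 34)),
    egfr_band      = mk("egfr_band", c(170, 110, 90), c(1480, 486, 57)),
    sua_band       = mk("sua_band", c(198, 58, 40, 74), c(1421, 340, 160, 104)),
    albumin_low    = mk("albumin_low", c(214, 156), c(1597, 428)),
    hemoglobin_low = mk("hemoglobin_low", c(73, 297), c(984, 1041)),
    wbc_high       = mk("wbc_high", c(268, 102), c(1721, 304)),
    sodium_band    = mk("sodium_band", c(135, 220, 15), c(190, 1809, 26)),
    potassium_band = mk("potassium_band", c(122, 228, 20), c(211, 1810, 4))
  )
}
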