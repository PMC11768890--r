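#' Convert a mass concentration to micromolar
#'
#' Exact arithmetic, no hidden rounding: uM = (ug/mL) / (g/mol) * 1000.
#'
#' @param mass_conc mass concentration in micrograms per millilitre.
#' @param molar_mass molar mass in grams per mole.
#' @return Molar concentration in micromolar.
#' @examples
#' micromolar(1.7945, 975.12)  # madecassoside at extract-equivalent dose
#' @export
micromolar <- function(mass_conc, molar_mass) {
  if (any(mass_conc <= 0) || any(molar_mass <= 0))
    stop("mass_conc and molar_mass must be positive")
  mass_conc / molar_mass * 1000
}

#' Load and validate the treatment compound panel
#'
#' The default shipped panel holds the twelve compounds of the nested
#' treatment design: four pentacyclic triterpenes (TT) and eight mono- and
#' di-caffeoylquinic acids (CQA), each at the mass concentration matching
#' its content in the 50 ug/mL full-extract solution. Molar masses are
#' package-supplied reference constants (they accompany, rather than come
#' from, the measured concentrations). When the table carries an
#' \code{expected_um} column, the computed molarity is compared against it
#' compound by compound.
#'
#' @param path TSV with columns name, compound_class, mass_conc_ug_ml,
#'   molar_mass_g_mol, and optionally expected_um. Defaults to the
#'   shipped panel.
#' @param signif_digits significant digits used for the display rounding
#'   of computed molarities (raw values are kept unrounded).
#' @return data.frame of class \code{"compound_panel"} with computed
#'   \code{molar_conc_um}, \code{molar_conc_display}, and, if expected
#'   values are present, \code{abs_diff} between display value and
#'   expectation.
#' @export
load_panel <- function(path = system.file("extdata", "compound_panel.tsv",
                                          package = "phytointeract"),
                       signif_digits = 3) {
  panel <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
  need <- c("name", "compound_class", "mass_conc_ug_ml", "molar_mass_g_mol")
  if (nrow(panel) == 0 || !all(need %in% names(panel)))
    stop("panel file must contain columns: ", paste(need, collapse = ", "))
  n_tt <- sum(panel$compound_class == "TT")
  n_cqa <- sum(panel$compound_class == "CQA")
  if (n_tt != 4 || n_cqa != 8)
    stop("panel must contain 4 TT and 8 CQA compounds (got ",
         n_tt, " TT, ", n_cqa, " CQA)")
  panel$molar_conc_um <- micromolar(panel$mass_conc_ug_ml,
                                    panel$molar_mass_g_mol)
  panel$molar_conc_display <- signif(panel$molar_conc_um, signif_digits)
  if ("expected_um" %in% names(panel)) {
    panel$abs_diff <- abs(panel$molar_conc_display - panel$expected_um)
  }
  class(panel) <- c("compound_panel", "data.frame")
  panel
}

#' Treatment membership of the compound panel
#'
#' @param panel a \code{\link{load_panel}} result.
#' @return Named list of compound names: TT (4), CQA (8), and their union
#'   TTCQA (12).
#' @export
panel_treatments <- function(panel) {
  tt <- panel$name[panel$compound_class == "TT"]
  cqa <- panel$name[panel$compound_class == "CQA"]
  list(TT = tt, CQA = cqa, TTCQA = c(tt, cqa))
}
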