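#' The 24 top-level FunCat functional categories
#'
#' Returns the catalogue of the 24 top-level FunCat functional categories
#' used as the label space for all predictors in this package. Category
#' indices are stable identifiers (1 to 24) and appear throughout in
#' annotation files, potential profiles and evaluation reports.
#'
#' @return A data frame with columns `index` (integer, 1..24) and `name`
#'   (character, the category description).
#' @examples
#' cat24 <- funcat_catalog()
#' cat24$name[cat24$index == 15]  # "CELL FATE"
#' @export
funcat_catalog <- function() {
  data.frame(
    index = 1:24,
    name = c(
      "METABOLISM",
      "ENERGY",
      "CELL CYCLE AND DNA PROCESSING",
      "TRANSCRIPTION",
      "PROTEIN SYNTHESIS",
      "PROTEIN FATE (folding, modification, destination)",
      "PROTEIN WITH BINDING FUNCTION OR COFACTOR REQUIREMENT (structural or catalytic)",
      "REGULATION OF METABOLISM AND PROTEIN FUNCTION",
      "CELLULAR TRANSPORT, TRANSPORT FACILITIES AND TRANSPORT ROUTES",
      "CELLULAR COMMUNICATION/SIGNAL TRANSDUCTION MECHANISM",
      "CELL RESCUE, DEFENSE AND VIRULENCE",
      "INTERACTION WITH THE ENVIRONMENT",
      "SYSTEMIC INTERACTION WITH THE ENVIRONMENT",
      "TRANSPOSABLE ELEMENTS, VIRAL AND PLASMID PROTEINS",
      "CELL FATE",
      "DEVELOPMENT (Systemic)",
      "BIOGENESIS OF CELLULAR COMPONENTS",
      "CELL TYPE DIFFERENTIATION",
      "TISSUE DIFFERENTIATION",
      "ORGAN DIFFERENTIATION",
      "SUBCELLULAR LOCALIZATION",
      "CELL TYPE LOCALIZATION",
      "TISSUE LOCALIZATION",
      "ORGAN LOCALIZATION"
    ),
    stringsAsFactors = FALSE
  )
}
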