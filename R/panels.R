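#' The 105-name lipoprotein subfraction schema
#'
#' Four-letter codes combine a particle prefix with a content suffix. The
#' prefixes are TP (total plasma), V1-V5 (VLDL subfractions 1-5; VLDL 6 is
#' excluded from the panel for poor model reliability), ID (IDL), L1-L6 (LDL
#' subfractions) and H1-H4 (HDL subfractions). Contents are TG
#' (triglycerides), CH (cholesterol), FC (free cholesterol), PL
#' (phospholipids) and the apolipoproteins A1, A2 and AB. Apolipoproteins
#' A1/A2 are not reported for VLDL subfractions and apolipoprotein B is not
#' reported for HDL subfractions, yielding exactly 105 variables (e.g. V4PL =
#' VLDL-4 phospholipids, TPTG = total plasma triglycerides).
#'
#' @return character vector of 105 codes, grouped by particle class
#' @examples
#' length(lipoprotein_schema())  # 105
#' @export
lipoprotein_schema <- function() {
  contents <- c("TG", "CH", "FC", "PL", "A1", "A2", "AB")
  prefixes <- c("TP", paste0("V", 1:5), "ID", paste0("L", 1:6), paste0("H", 1:4))
  grid <- expand.grid(content = contents, prefix = prefixes,
                      stringsAsFactors = FALSE)
  nm <- paste0(grid$prefix, grid$content)
  drop <- (grepl("^V[1-5]", nm) & grepl("(A1|A2)$", nm)) |
          (grepl("^H[1-4]", nm) & grepl("AB$", nm))
  nm[!drop]
}

#' Particle class of each lipoprotein code
#' @param names codes from [lipoprotein_schema()]
#' @return factor with levels TP, VLDL, IDL, LDL, HDL
#' @keywords internal
lipoprotein_class <- function(names) {
  cls <- rep(NA_character_, length(names))
  cls[grepl("^TP", names)] <- "TP"
  cls[grepl("^V[1-6]", names)] <- "VLDL"
  cls[grepl("^ID", names)] <- "IDL"
  cls[grepl("^L[1-6]", names)] <- "LDL"
  cls[grepl("^H[1-4]", names)] <- "HDL"
  factor(cls, levels = c("TP", "VLDL", "IDL", "LDL", "HDL"))
}

#' The 30 NMR-quantified serum metabolites
#'
#' The semi-quantified CPMG panel: 28 small-molecule signals plus two broad
#' lipid signals, lipid1 (methyl protons, 0.8-0.9 ppm) and lipid2 (methylene
#' beta-carbon protons, 1.55-1.60 ppm), arising mainly from triglycerides and
#' esterified cholesterol in lipoprotein particles.
#'
#' @return character vector of 30 names, in spectral display order
#' @export
mrs_panel <- function() {
  c("lipid1", "leucine", "valine", "isoleucine", "methylglutarate_2",
    "alanine", "lipid2", "lysine", "acetate", "glutamine_glutamate",
    "acetoacetate", "hydroxybutyrate_3", "glutamate", "pyruvate",
    "glutamine", "citrate", "methionine", "creatine", "creatinine",
    "ornithine", "proline_betaine", "dimethyl_sulfone", "unknown_2_83",
    "histidine", "glucose", "glycine", "lactate", "tyrosine",
    "phenylalanine", "formate")
}

#' The raw 188-metabolite targeted-MS kit panel
#'
#' Mirrors the composition of a broad targeted kit: 40 acylcarnitines, 21
#' amino acids, 21 biogenic amines (including kynurenine, ADMA and
#' alpha-aminoadipic acid), 14 lysophosphatidylcholines, 38 diacyl and 38
#' acyl-alkyl phosphatidylcholines, 15 sphingomyelins and total hexoses.
#' Lipid side chains are labelled CX:Y (X carbons, Y double bonds).
#'
#' @return data.frame with columns `name` and `class` (188 rows)
#' @export
ms_panel <- function() {
  ac_chains <- c("C0", "C2", "C3", "C3:1", "C3-OH", "C4", "C4:1", "C4-OH",
    "C5", "C5:1", "C5-OH", "C5-DC", "C5:1-DC", "C5-M-DC", "C6", "C6:1",
    "C7-DC", "C8", "C9", "C10", "C10:1", "C10:2", "C12", "C12:1", "C12-DC",
    "C14", "C14:1", "C14:1-OH", "C14:2", "C14:2-OH", "C16", "C16:1",
    "C16:1-OH", "C16:2", "C16:2-OH", "C16-OH", "C18", "C18:1", "C18:1-OH",
    "C18:2")
  aa <- c("Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His",
    "Ile", "Leu", "Lys", "Met", "Orn", "Phe", "Pro", "Ser", "Thr", "Trp",
    "Tyr", "Val")
  amines <- c("ADMA", "alpha_AAA", "carnosine", "creatinine_ms", "histamine",
    "kynurenine", "met_SO", "nitrotyrosine", "OH_proline", "PEA", "putrescine",
    "sarcosine", "SDMA", "serotonin", "spermidine", "spermine", "taurine",
    "total_DMA", "dopamine", "DOPA", "acetylornithine")
  lpc <- paste0("lysoPC_a_", c("C14:0", "C16:0", "C16:1", "C17:0", "C18:0",
    "C18:1", "C18:2", "C20:3", "C20:4", "C24:0", "C26:0", "C26:1", "C28:0",
    "C28:1"))
  pc_aa <- paste0("PC_aa_", c("C24:0", "C26:0", "C28:1", "C30:0", "C32:0",
    "C32:1", "C32:2", "C32:3", "C34:1", "C34:2", "C34:3", "C34:4", "C36:0",
    "C36:1", "C36:2", "C36:3", "C36:4", "C36:5", "C36:6", "C38:0", "C38:1",
    "C38:3", "C38:4", "C38:5", "C38:6", "C40:1", "C40:2", "C40:3", "C40:4",
    "C40:5", "C40:6", "C42:0", "C42:1", "C42:2", "C42:4", "C42:5", "C42:6",
    "C30:2"))
  pc_ae <- paste0("PC_ae_", c("C30:0", "C30:1", "C30:2", "C32:1", "C32:2",
    "C34:0", "C34:1", "C34:2", "C34:3", "C36:0", "C36:1", "C36:2", "C36:3",
    "C36:4", "C36:5", "C38:0", "C38:1", "C38:2", "C38:3", "C38:4", "C38:5",
    "C38:6", "C40:1", "C40:2", "C40:3", "C40:4", "C40:5", "C40:6", "C42:1",
    "C42:2", "C42:3", "C42:4", "C42:5", "C44:3", "C44:4", "C44:5", "C44:6",
    "C40:0"))
  sm <- c(paste0("SM_", c("C16:0", "C16:1", "C18:0", "C18:1", "C20:2",
    "C22:3", "C24:0", "C24:1", "C26:0", "C26:1")),
    paste0("SM_OH_", c("C14:1", "C16:1", "C22:1", "C22:2", "C24:1")))
  panel <- rbind(
    data.frame(name = paste0("AC_", ac_chains), class = "acylcarnitine"),
    data.frame(name = aa, class = "amino_acid"),
    data.frame(name = amines, class = "biogenic_amine"),
    data.frame(name = lpc, class = "lysoPC"),
    data.frame(name = pc_aa, class = "PC_aa"),
    data.frame(name = pc_ae, class = "PC_ae"),
    data.frame(name = sm, class = "sphingomyelin"),
    data.frame(name = "hexoses", class = "sugar"))
  stopifnot(nrow(panel) == 188L, !anyDuplicated(panel$name))
  rownames(panel) <- NULL
  panel
}
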