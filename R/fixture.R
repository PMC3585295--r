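#' The 31 CAD biomarkers grouped into 7 pathways
#'
#' The biomarker panel used throughout the package examples: 31 genes
#' covering inflammation (12), coagulation (10), cell adhesion (2),
#' obesity (2), oxidative stress (1), stress (3) and renal function (1).
#' Gene identifiers are HGNC-style symbols with a few conventional
#' biomarker labels (`PAI1` for SERPINE1, `SPLA2` for PLA2G2A, `HSP27`/
#' `HSP60`/`HSP70` for the heat-shock proteins, `PDGF` for the platelet
#' derived growth factor marker).
#'
#' @return a [PathwayMap-class] with 7 pathways over 31 genes.
#' @examples
#' pathwayNames(cadPathways())
#' @export
cadPathways <- function() {
  pathwayMap(list(
    inflammation = c("IL6", "IL8", "IL10", "IL12A", "IL12B", "IL18",
                     "CCL2", "CRP", "IFNG", "MMP9", "SPLA2", "GGT5"),
    coagulation = c("F7", "FGA", "FGB", "FGG", "F2", "PAI1", "PLG",
                    "F3", "VWF", "PDGF"),
    cell_adhesion = c("CLU", "SELP"),
    obesity = c("ADIPOQ", "LEP"),
    oxidative_stress = "MPO",
    stress = c("HSP27", "HSP60", "HSP70"),
    renal_function = "CST3"
  ))
}

#' Curated binding-site counts for the five CAD core regulators
#'
#' A 5 TF x 31 biomarker [BindingCountMatrix-class] holding the reported
#' per-promoter binding-site counts of the five core CAD transcription
#' factors PPARG, EGR1, ETV1, KLF7 and ESRRA across the 31-biomarker
#' panel of [cadPathways()]; promoters without a reported count hold 0.
#'
#' The per-promoter ETV1 counts sum to 42 although the narrative total for
#' ETV1 is 43; this matrix stores the per-promoter values verbatim, and
#' `claimedTotals` preserves the narrative totals so the discrepancy stays
#' visible instead of being silently reconciled.
#'
#' @return list with components:
#'   \describe{
#'     \item{matrix}{the [BindingCountMatrix-class] of counts.}
#'     \item{pathways}{[cadPathways()].}
#'     \item{familyOf}{named character vector TF -> family.}
#'     \item{claimedTotals}{named numeric vector of narrative per-TF
#'       totals (ETV1 = 43).}
#'     \item{totalDiscrepancies}{named numeric vector, claimed minus
#'       tabulated total per TF (non-zero only for ETV1).}
#'   }
#' @examples
#' fx <- coreTfBindingCounts()
#' tfTotals(fx$matrix)                 # PPARG 76, EGR1 52, ETV1 42, ...
#' fx$totalDiscrepancies["ETV1"]       # 1
#' coreTFs(fx$matrix, fx$pathways, mode = "pathway")  # "EGR1"
#' @export
coreTfBindingCounts <- function() {
  pmap <- cadPathways()
  genes <- unique(unlist(pathwayGenes(pmap)))
  tfs <- c("PPARG", "EGR1", "ETV1", "KLF7", "ESRRA")
  m <- matrix(0L, length(tfs), length(genes), dimnames = list(tfs, genes))
  put <- function(tf, ...) {
    v <- c(...)
    m[tf, names(v)] <<- as.integer(v)
  }
  put("PPARG",
      CLU = 7, SELP = 1,
      FGB = 7, PAI1 = 5, PLG = 1, F2 = 5, VWF = 7,
      CRP = 4, IL10 = 2, IL12B = 5, IL18 = 4, IL6 = 2, IFNG = 2,
      MMP9 = 3, SPLA2 = 7,
      ADIPOQ = 1, LEP = 1,
      MPO = 7,
      HSP60 = 3, HSP70 = 2)
  put("EGR1",
      CLU = 7,
      PAI1 = 2, PDGF = 8, PLG = 3, F2 = 1, F3 = 5, VWF = 2,
      CCL2 = 1, CRP = 1, IL10 = 1, IL12A = 1, IL6 = 1, MMP9 = 5,
      LEP = 3,
      MPO = 2,
      CST3 = 1,
      HSP27 = 5, HSP60 = 2, HSP70 = 1)
  put("ETV1",
      CLU = 7, SELP = 2,
      F7 = 2, PDGF = 5, PLG = 2, F2 = 1, VWF = 4,
      CCL2 = 2, CRP = 1, IL10 = 2, IL12B = 1, IL18 = 2, IL8 = 2,
      MMP9 = 3, SPLA2 = 1,
      LEP = 1,
      MPO = 4)
  put("KLF7",
      F7 = 1, PAI1 = 1, PDGF = 4, PLG = 1, F3 = 1, VWF = 1,
      IL10 = 1, IL12A = 2, MMP9 = 6,
      LEP = 3,
      MPO = 1,
      HSP27 = 2, HSP60 = 1)
  put("ESRRA",
      CLU = 2, SELP = 1,
      F2 = 2, VWF = 4,
      CCL2 = 1, CRP = 2, GGT5 = 1, IL18 = 1, IL6 = 1, MMP9 = 4,
      SPLA2 = 2,
      MPO = 1,
      CST3 = 1)
  bcm <- bindingCountMatrix(m)
  claimed <- c(PPARG = 76, EGR1 = 52, ETV1 = 43, KLF7 = 25, ESRRA = 23)
  list(matrix = bcm,
       pathways = pmap,
       familyOf = c(PPARG = "nuclear_receptor", EGR1 = "EGR_zinc_finger",
                    ETV1 = "ETS", KLF7 = "Kruppel_like",
                    ESRRA = "nuclear_receptor"),
       claimedTotals = claimed,
       totalDiscrepancies = claimed - tfTotals(bcm)[names(claimed)])
}
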