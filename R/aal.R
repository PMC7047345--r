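#' Node labels for the 90-region AAL parcellation
#'
#' Returns the conventional abbreviations of the 90 cortical and subcortical
#' regions of the automated anatomical labeling (AAL) atlas, in the standard
#' atlas order (left/right interleaved, `.L` before `.R` within each region).
#' These are the node labels used throughout the package; cerebellar regions
#' are excluded, as is usual for whole-brain tractography connectomes.
#'
#' @return Character vector of length 90.
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
}

#' Default rich-club hub regions
#'
#' The 13 regions (15% of 90 nodes) reported as rich-club members in
#' FA-weighted glioma connectome cohorts: bilateral precuneus, putamen,
#' calcarine and superior occipital cortex, plus left middle temporal,
#' left middle occipital, right precentral, left median cingulate and
#' right dorsolateral superior frontal gyrus.
#'
#' @return Character vector of length 13, a subset of [aal90_labels()].
#' @export
default_hub_labels <- function() {
  c("PCUN.L", "PCUN.R", "PUT.L", "PUT.R", "CAL.L", "CAL.R",
    "MTG.L", "MOG.L", "SOG.L", "SOG.R", "PreCG.R", "DCG.L", "SFGdor.R")
}
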