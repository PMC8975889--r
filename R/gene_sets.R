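#' Default arteriovenous marker genes
#'
#' The 13 arterial and 3 venous markers used for the arteriovenous feature
#' score in embryonic mouse VECs. Arterial: Bmx, Cxcr4, Dll4, Efnb2, Epas1,
#' Gja4, Gja5, Hey1, Igfbp3, Mecom, Nrp1, Unc5b, Vegfc. Venous: Aplnr, Nr2f2,
#' Nrp2. For other species, supply homologous symbols instead.
#'
#' @return list with character vectors `arterial` (13) and `venous` (3).
#' @export
av_marker_genes <- function() {
  list(
    arterial = c("Bmx", "Cxcr4", "Dll4", "Efnb2", "Epas1", "Gja4", "Gja5",
                 "Hey1", "Igfbp3", "Mecom", "Nrp1", "Unc5b", "Vegfc"),
    venous = c("Aplnr", "Nr2f2", "Nrp2")
  )
}

#' Core cell-cycle gene sets
#'
#' The widely used core sets of 43 G1/S-phase and 54 G2/M-phase genes
#' (human symbols; title-case them for mouse data) used for cell-cycle phase
#' scoring.
#'
#' @return list with character vectors `g1s` (43 genes) and `g2m` (54 genes).
#' @export
cell_cycle_genes <- function() {
  list(
    g1s = c("MCM5", "PCNA", "TYMS", "FEN1", "MCM2", "MCM4", "RRM1", "UNG",
            "GINS2", "MCM6", "CDCA7", "DTL", "PRIM1", "UHRF1", "MLF1IP",
            "HELLS", "RFC2", "RPA2", "NASP", "RAD51AP1", "GMNN", "WDR76",
            "SLBP", "CCNE2", "UBR7", "POLD3", "MSH2", "ATAD2", "RAD51",
            "RRM2", "CDC45", "CDC6", "EXO1", "TIPIN", "DSCC1", "BLM",
            "CASP8AP2", "USP1", "CLSPN", "POLA1", "CHAF1B", "BRIP1", "E2F8"),
    g2m = c("HMGB2", "CDK1", "NUSAP1", "UBE2C", "BIRC5", "TPX2", "TOP2A",
            "NDC80", "CKS2", "NUF2", "CKS1B", "MKI67", "TMPO", "CENPF",
            "TACC3", "FAM64A", "SMC4", "CCNB2", "CKAP2L", "CKAP2", "AURKB",
            "BUB1", "KIF11", "ANP32E", "TUBB4B", "GTSE1", "KIF20B", "HJURP",
            "CDCA3", "HN1", "CDC20", "TTK", "CDC25C", "KIF2C", "RANGAP1",
            "NCAPD2", "DLGAP5", "CDCA2", "CDCA8", "ECT2", "KIF23", "HMMR",
            "AURKA", "PSRC1", "ANLN", "LBR", "CKAP5", "CENPE", "CTCF",
            "NEK2", "G2E3", "GAS2L3", "CBX5", "CENPA")
  )
}

#' Bundle signature gene sets for scoring
#'
#' Validates and bundles the arterial/venous markers and cell-cycle sets used
#' by [av_scores()] and [cell_cycle_scores()]. Arterial and venous sets must
#' be disjoint.
#'
#' @param arterial,venous,g1s,g2m character vectors of gene symbols; defaults
#'   are [av_marker_genes()] and [cell_cycle_genes()].
#' @return list of class `SignatureSet`.
#' @export
signature_set <- function(arterial = av_marker_genes()$arterial,
                          venous = av_marker_genes()$venous,
                          g1s = cell_cycle_genes()$g1s,
                          g2m = cell_cycle_genes()$g2m) {
  arterial <- unique(arterial); venous <- unique(venous)
  if (length(intersect(arterial, venous)))
    stop("arterial and venous signatures overlap: ",
         paste(intersect(arterial, venous), collapse = ", "))
  structure(list(arterial = arterial, venous = venous,
                 g1s = unique(g1s), g2m = unique(g2m)),
            class = "SignatureSet")
}
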