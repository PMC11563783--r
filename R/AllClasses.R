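#' @import methods
NULL

#' Symbolic model of the RCCX locus
#'
#' Encodes the reference structure used throughout the package: the ordered
#' informative-site map of the CYP21A2 region plus the TNXB probe landmarks,
#' the chimeric-gene catalogue (CYP21A1P/CYP21A2 CH1-CH9 and TNXA/TNXB
#' CAH-X CH1-CH3), the variant severity table, the pseudogene-derived
#' microconversion token set, the variant-to-site lookup, and the MLPA probe
#' panel. Sites are symbolic landmarks ordered 5'->3', not genomic
#' coordinates: chimera junctions are reasoned about entirely in terms of
#' exon and landmark intervals.
#'
#' @slot sites data.frame with columns \code{site_id}, \code{order_index},
#'   \code{region} (one of promoter, exon, intron_site, tnxb), strictly
#'   increasing in \code{order_index}.
#' @slot chimeras named list of chimera definitions (span boundary site,
#'   junction interval, I2G / 8-bp-deletion carriage, TNXB signature,
#'   observed flag).
#' @slot severity named character: canonical variant token -> severity class
#'   in Null/A/B/C. Tokens absent from the table are treated as
#'   unknown-effect (class D) by \code{\link{severityOfAllele}}.
#' @slot pseudogeneSet canonical tokens transferable from CYP21A1P by
#'   microconversion.
#' @slot variantSites named character: canonical token -> site_id housing it.
#' @slot unknownLocation tokens explicitly registered as location-unknown.
#' @slot probePanel list with \code{a2_probe_sites}, \code{a1p_probe_count},
#'   \code{tnxb_probe_sites}, \code{tnxb_probe_mult}, \code{reference_area}.
#' @seealso \code{\link{loadLocusModel}}
#' @exportClass LocusModel
setClass("LocusModel", representation(
  sites = "data.frame",
  chimeras = "list",
  severity = "character",
  pseudogeneSet = "character",
  variantSites = "character",
  unknownLocation = "character",
  probePanel = "list"
))

.GENE_SITE_IDS <- c("UTR5", "E1", "E2", "I2G_SITE", "DEL8BP_SITE",
                    paste0("E", 3:10))

setValidity("LocusModel", function(object) {
  s <- object@sites
  msgs <- character(0)
  need <- c("site_id", "order_index", "region")
  if (!all(need %in% names(s))) {
    return("sites must have columns site_id, order_index, region")
  }
  if (any(diff(s$order_index) <= 0)) {
    msgs <- c(msgs, "site order_index must be strictly increasing")
  }
  exon_ids <- s$site_id[grepl("^E[0-9]+$", s$site_id)]
  if (!identical(sort(exon_ids), sort(paste0("E", 1:10)))) {
    msgs <- c(msgs, "locus must carry exactly the 10 exon sites E1..E10")
  }
  idx <- function(id) match(id, s$site_id)
  if (!(idx("I2G_SITE") > idx("E2") && idx("I2G_SITE") < idx("E3"))) {
    msgs <- c(msgs, "I2G_SITE must lie between E2 and E3")
  }
  if (!(idx("DEL8BP_SITE") > idx("I2G_SITE") && idx("DEL8BP_SITE") < idx("E4"))) {
    msgs <- c(msgs, "DEL8BP_SITE must lie within exon 3, after I2G_SITE")
  }
  pp <- object@probePanel
  tn <- pp$tnxb_probe_sites
  bad <- grepl("^TNXB_E4[0-9]$|^TNXB_E44$", tn)
  if (any(bad)) {
    msgs <- c(msgs, paste0("probe panel may not probe TNXB exons 40-44: ",
                           paste(tn[bad], collapse = ", ")))
  }
  if (!all(pp$a2_probe_sites %in% s$site_id)) {
    msgs <- c(msgs, "a2_probe_sites must be declared locus sites")
  }
  carriers <- c("CH1", "CH2", "CH3", "CH5", "CH6", "CH7", "CH8")
  for (id in carriers) {
    ch <- object@chimeras[[id]]
    if (!is.null(ch) && !isTRUE(ch$carries_I2G)) {
      msgs <- c(msgs, paste0(id, " must carry I2G"))
    }
  }
  for (id in c("CH4", "CH9")) {
    ch <- object@chimeras[[id]]
    if (!is.null(ch) && isTRUE(ch$carries_I2G)) {
      msgs <- c(msgs, paste0(id, " must not carry I2G"))
    }
  }
  ch6 <- object@chimeras[["CH6"]]
  if (!is.null(ch6) && isTRUE(ch6$carries_8bp_del)) {
    msgs <- c(msgs, "CH6 excludes the exon-3 8 bp deletion")
  }
  if (length(msgs)) msgs else TRUE
})

#' One haplotype's marker vector
#'
#' Ordered gene-vs-pseudogene origin calls, one per informative site of the
#' CYP21A2 region, standing in for a phased long read spanning the whole
#' gene. TNXB-side evidence observed on the same haplotype travels as a
#' token set rather than per-site calls, mirroring how CAH-X chimeras are
#' recognised by signature variants.
#'
#' @slot calls character vector of GENE/PSEUDO/ABSENT/UNKNOWN, named by
#'   site_id in locus order.
#' @slot tnxbSignature character token set (e.g. TNXB_E35_120bp_del).
#' @seealso \code{\link{markerVector}}, \code{\link{callJunction}}
#' @exportClass MarkerVector
setClass("MarkerVector", representation(
  calls = "character",
  tnxbSignature = "character"
))

setValidity("MarkerVector", function(object) {
  ok <- object@calls %in% c("GENE", "PSEUDO", "ABSENT", "UNKNOWN")
  if (!all(ok)) return("calls must be GENE, PSEUDO, ABSENT or UNKNOWN")
  if (is.null(names(object@calls))) return("calls must be named by site_id")
  TRUE
})

#' One classified haplotype
#'
#' @slot category one of MICROCONVERSION, NOVEL_VARIANT, DELETION,
#'   DUPLICATION.
#' @slot subtype chimera/structure identifier (CH1..CH9, CAHX_CH1..3,
#'   DEL_SOLO, DUP_E7E8) or NONE for point-variant alleles.
#' @slot variants variant tokens carried on the haplotype, as written.
#' @slot copies per-copy token lists; length > 1 only for trimodular
#'   duplication alleles (an intact copy plus the exon 7-8 integrated copy).
#' @seealso \code{\link{classifyAllele}}, \code{\link{parseAllele}}
#' @exportClass AlleleSpec
setClass("AlleleSpec", representation(
  category = "character",
  subtype = "character",
  variants = "character",
  copies = "list"
))

setValidity("AlleleSpec", function(object) {
  cats <- c("MICROCONVERSION", "NOVEL_VARIANT", "DELETION", "DUPLICATION")
  if (!(length(object@category) == 1L && object@category %in% cats)) {
    return("category must be one of MICROCONVERSION, NOVEL_VARIANT, DELETION, DUPLICATION")
  }
  if (object@category == "DELETION" &&
      !grepl("^(DEL_SOLO|CAHX_CH[1-3]|CH[1-9])$", object@subtype)) {
    return("DELETION subtype must be DEL_SOLO, CAHX_CH1..3 or CH1..CH9")
  }
  if (object@category == "DUPLICATION" && object@subtype != "DUP_E7E8") {
    return("DUPLICATION subtype must be DUP_E7E8")
  }
  if (object@category %in% c("MICROCONVERSION", "NOVEL_VARIANT") &&
      length(object@variants) == 0L) {
    return("point-variant alleles must carry at least one token")
  }
  TRUE
})

#' A diploid 21-OHD cohort
#'
#' Patient-level table plus the two structurally resolved alleles per
#' patient. The table keeps the recorded conventional (MLPA + Long-PCR)
#' result strings and free-text notes carrying recorded dataset facts used
#' by \code{\link{compareReports}}.
#'
#' @slot patients data.frame with columns patient_id, sex, age_years,
#'   phenotype, extra_copy, conv_allele1, conv_allele2, notes.
#' @slot alleles list (one element per patient) of two-element lists of
#'   \code{AlleleSpec}.
#' @seealso \code{\link{readCohort}}, \code{\link{table3Cohort}}
#' @exportClass CahCohort
setClass("CahCohort", representation(
  patients = "data.frame",
  alleles = "list"
))

setValidity("CahCohort", function(object) {
  if (nrow(object@patients) != length(object@alleles)) {
    return("one allele pair required per patient row")
  }
  ph <- object@patients$phenotype
  if (!all(ph %in% c("SW", "SV", "NC", "UNKNOWN"))) {
    return("phenotype must be SW, SV, NC or UNKNOWN")
  }
  if (anyDuplicated(object@patients$patient_id)) {
    return("patient_id must be unique")
  }
  TRUE
})

#' Simulated conventional (MLPA + Long-PCR) report for one patient
#'
#' @slot patientId patient identifier.
#' @slot calls length-2 character, the reported string per allele. The
#'   attribution to alleles mirrors the study's paternal/maternal layout
#'   even though the assay itself is unphased; \code{phaseKnown} records
#'   that limitation.
#' @slot dropout named integer copy-dosage vector over probed sites.
#' @slot phaseKnown always FALSE unless parental genomes are supplied.
#' @exportClass ConventionalReport
setClass("ConventionalReport", representation(
  patientId = "character",
  calls = "character",
  dropout = "integer",
  phaseKnown = "logical"
))

setValidity("ConventionalReport", function(object) {
  if (length(object@calls) != 2L) return("calls must have length 2")
  TRUE
})

#' Cohort-level summary statistics
#'
#' @slot alleleCounts data.frame of per-allele-type counts and rates.
#' @slot categoryProportions named numeric fractions over the taxonomy.
#' @slot crosstab 4x3 genotype-group by phenotype count matrix (group-D
#'   patients excluded).
#' @slot nClassified patients entering the cross-tab.
#' @slot concordance fraction of classified patients whose phenotype equals
#'   the group-expected phenotype.
#' @slot ppv named numeric, per-group positive predictive rate.
#' @slot rho tie-corrected Spearman rank correlation between genotype group
#'   and phenotype severity.
#' @seealso \code{\link{cohortStats}}
#' @exportClass CohortStats
setClass("CohortStats", representation(
  alleleCounts = "data.frame",
  categoryProportions = "numeric",
  crosstab = "matrix",
  nClassified = "integer",
  concordance = "numeric",
  ppv = "numeric",
  rho = "numeric"
))

setValidity("CohortStats", function(object) {
  ct <- object@crosstab
  if (!identical(dim(ct), c(4L, 3L))) return("crosstab must be 4x3")
  if (any(ct < 0)) return("crosstab cells must be non-negative")
  if (sum(ct) != object@nClassified) {
    return("nClassified must equal the crosstab total")
  }
  TRUE
})
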