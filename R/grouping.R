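# Severity grouping. Classes are ordered Null < A < B < C by increasing
# residual 21-hydroxylase activity; D (unknown effect) is incomparable and
# dominates any pairing. The diploid group is set by the milder allele.

.SEVERITY_ORDER <- c(Null = 1L, A = 2L, B = 3L, C = 4L)

#' Severity class of one allele
#'
#' Structural rules first: solo deletions, TNXA/TNXB (CAH-X) chimeras and
#' every I2G-carrying CYP21A1P/CYP21A2 chimera (CH1-CH3, CH5-CH8) are Null;
#' the promoter+p.P31L chimeras CH4/CH9 are C; exon 7-8 integration
#' duplication alleles are C (the haplotype retains a near-intact gene
#' copy, leaving non-classic-range residual activity). Point-variant
#' alleles take the most severe class among their tokens; a token missing
#' from the severity table makes the allele unknown-effect (D) unless a
#' Null-class token is already present (nothing can be more severe than
#' Null, so the unknown token cannot change the call).
#'
#' @param spec an \code{\linkS4class{AlleleSpec}}.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return one of \code{"Null"}, \code{"A"}, \code{"B"}, \code{"C"},
#'   \code{"D"}.
#' @examples
#' m <- loadLocusModel()
#' severityOfAllele(parseAllele("micro:p.L308Ffs*6+p.Q319X"), m)
#' severityOfAllele(parseAllele("chimera:CH4"), m)
#' @export
severityOfAllele <- function(spec, model = loadLocusModel()) {
  if (spec@category == "DELETION") {
    if (spec@subtype %in% c("CH4", "CH9")) return("C")
    return("Null")
  }
  if (spec@category == "DUPLICATION") return("C")
  canon <- normalizeToken(spec@variants)
  known <- model@severity[canon]
  ranks <- .SEVERITY_ORDER[known[!is.na(known)]]
  if (any(is.na(known))) {
    if (length(ranks) && min(ranks) == 1L) return("Null")
    return("D")
  }
  if (!length(ranks)) return("D")
  names(.SEVERITY_ORDER)[min(ranks)]
}

#' Combine two allele classes into the genotype group
#'
#' The milder-allele rule: the phenotype is driven by the allele with more
#' residual activity, so the genotype group is the milder (larger in the
#' Null < A < B < C order) of the two classes. Any unknown-effect allele
#' makes the genotype group D. Symmetric in its arguments.
#'
#' @param class1,class2 severity classes
#'   (\code{"Null"}/\code{"A"}/\code{"B"}/\code{"C"}/\code{"D"}).
#' @return the genotype group, same coding.
#' @examples
#' assignGroup("A", "Null")   # "A"
#' assignGroup("B", "D")      # "D"
#' @export
assignGroup <- function(class1, class2) {
  stopifnot(class1 %in% c(names(.SEVERITY_ORDER), "D"),
            class2 %in% c(names(.SEVERITY_ORDER), "D"))
  if (class1 == "D" || class2 == "D") return("D")
  names(.SEVERITY_ORDER)[max(.SEVERITY_ORDER[class1],
                             .SEVERITY_ORDER[class2])]
}

#' Phenotype expected for a genotype group
#'
#' @param group genotype group (\code{"Null"}, \code{"A"}, \code{"B"},
#'   \code{"C"} or \code{"D"}); vectorized.
#' @return \code{"SW"}, \code{"SV"}, \code{"NC"} or \code{"UNKNOWN"}.
#' @examples
#' expectedPhenotype(c("Null", "A", "B", "C", "D"))
#' @export
expectedPhenotype <- function(group) {
  map <- c(Null = "SW", A = "SW", B = "SV", C = "NC", D = "UNKNOWN")
  out <- map[group]
  if (anyNA(out)) stop("unknown genotype group", call. = FALSE)
  unname(out)
}

#' Genotype group of every patient in a cohort
#'
#' @param cohort a \code{\linkS4class{CahCohort}}.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return character vector of groups, named by patient_id.
#' @examples
#' groups <- genotypeGroups(table3Cohort())
#' table(groups)
#' @export
genotypeGroups <- function(cohort, model = loadLocusModel()) {
  out <- vapply(cohort@alleles, function(pair) {
    assignGroup(severityOfAllele(pair[[1]], model),
                severityOfAllele(pair[[2]], model))
  }, character(1))
  stats::setNames(out, cohort@patients$patient_id)
}
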