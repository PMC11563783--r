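# In-silico model of the conventional assay: MLPA probe dosage over the
# probed sites plus Long-PCR point-variant reporting, with the masking
# rules that explain the method discordances (no probes on CYP21A2 exons
# 2/5/8-10 or TNXB exons 40-44; promoter conversions invisible; the fused
# exon 7-8 copy hides p.V282L from Long-PCR).

# Gene-origin presence (0/1) of one allele copy at every probed site.
.copyPresence <- function(tokens, structural, model) {
  pp <- model@probePanel
  a2 <- stats::setNames(rep(1L, length(pp$a2_probe_sites)),
                        pp$a2_probe_sites)
  tn <- stats::setNames(rep(1L, length(pp$tnxb_probe_sites)),
                        pp$tnxb_probe_sites)
  if (!is.null(structural)) {
    if (structural %in% c("DEL_SOLO", "CAHX_CH1", "CAHX_CH2", "CAHX_CH3")) {
      a2[] <- 0L
      if (structural == "CAHX_CH1") tn["TNXB_E35"] <- 0L
    } else {
      ch <- model@chimeras[[structural]]
      if (!is.null(ch) && isTRUE(ch$observed) && !is.na(ch$span_end)) {
        cut <- .siteIndex(model, ch$span_end)
        conv <- .siteIndex(model, names(a2)) < cut
        a2[conv] <- 0L
      }
    }
  } else if ("V282L" %in% normalizeToken(tokens) && "E7" %in% names(a2)) {
    # fused exon 7-8 copy: the exon-7 differential site is pseudogene-origin
    a2["E7"] <- 0L
  }
  c(a2, tn)
}

.allelePresence <- function(spec, model) {
  if (spec@category == "DELETION") {
    return(.copyPresence(character(0), spec@subtype, model))
  }
  if (spec@category == "DUPLICATION") {
    copies <- if (length(spec@copies)) spec@copies else list(spec@variants)
    mats <- lapply(copies, function(tk) {
      if (!length(tk)) .copyPresence(character(0), NULL, model)  # intact
      else .copyPresence(tk, NULL, model)
    })
    return(Reduce(`+`, mats))
  }
  .copyPresence(spec@variants, NULL, model)
}

#' Simulate the diploid MLPA copy-dosage vector
#'
#' Dosage at each probed site is the number of haplotype copies retaining
#' gene-origin sequence there: pseudogene-converted or deleted spans
#' contribute 0, the intact copy of a trimodular duplication allele adds 1,
#' and only the CAH-X CH1 structure (120 bp deletion in TNXB exon 35)
#' reduces the TNXB_E35 probe.
#'
#' @param allele1,allele2 \code{\linkS4class{AlleleSpec}} objects.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return named integer vector over the probed sites
#'   (CYP21A2 area then TNXB area).
#' @examples
#' m <- loadLocusModel()
#' wt <- parseAllele("micro:I2G")  # any point allele is dosage-neutral
#' simulateProbeDropout(parseAllele("chimera:CH1"), wt, m)
#' @export
simulateProbeDropout <- function(allele1, allele2, model = loadLocusModel()) {
  .allelePresence(allele1, model) + .allelePresence(allele2, model)
}

.CANONICAL_DELETION_CALL <- c(
  DEL_SOLO = "Exon 1-10 Del",
  CAHX_CH1 = "Exon 1-10 Del",
  CAHX_CH2 = "Exon 1-10 Del",
  CAHX_CH3 = "Exon 1-10 Del",
  CH1 = "Exon 1-3 Del",
  CH2 = "Exon 1-4 Del",
  CH3 = "Exon 1-7 Del",
  CH8 = "Exon 1-10 Del")

#' Deletion string the conventional assay reports for a structural allele
#'
#' Reproduces the canonical reported-span mapping: whole-gene losses (solo
#' deletion and every CAH-X type) and CH8 come back as "Exon 1-10 Del" --
#' for CH8 an inference from the absence of every probed exon, since no
#' probe exists on exons 8-10 -- while CH1/CH2/CH3 come back as the span
#' from the first through the last missing probed exon ("Exon 1-3 Del",
#' "Exon 1-4 Del", "Exon 1-7 Del"). A structure outside the canonical
#' catalogue falls back to a verbatim per-probe listing of the missing
#' exons (no span inference).
#'
#' @param spec a DELETION-category \code{\linkS4class{AlleleSpec}}.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return a single reported string, or \code{NA_character_} for the two
#'   structures the assay reports as point calls instead (CH4, CH6; see
#'   \code{\link{renderLongPcrCall}}).
#' @export
renderDeletionCall <- function(spec, model = loadLocusModel()) {
  stopifnot(spec@category == "DELETION")
  if (spec@subtype %in% c("CH4", "CH6")) return(NA_character_)
  hit <- .CANONICAL_DELETION_CALL[spec@subtype]
  if (!is.na(hit)) return(unname(hit))
  pres <- .allelePresence(spec, model)
  a2 <- pres[model@probePanel$a2_probe_sites]
  missing_ex <- sub("^E", "", names(a2)[a2 == 0L & grepl("^E", names(a2))])
  if (!length(missing_ex)) return(NA_character_)
  paste0("Exon ", paste(missing_ex, collapse = ", "), " Del")
}

#' Point variants the Long-PCR arm reports for an allele
#'
#' Echoes the allele's tokens with the assay's masking rules applied:
#' promoter/UTR5 conversions are never reported (no coverage upstream of
#' exon 1); the CH4 chimera surfaces only as p.P31L and CH6 only as I2G
#' (the deleted/converted exon-level content goes unseen); and fused exon
#' 7-8 duplication alleles lose p.V282L. Idempotent on its own output.
#'
#' @param spec an \code{\linkS4class{AlleleSpec}}.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return character vector of reported tokens (possibly empty).
#' @examples
#' renderLongPcrCall(parseAllele("dup:E7E8[p.V282L,p.L308Ffs*6,p.Q319X]+WT"))
#' @export
renderLongPcrCall <- function(spec, model = loadLocusModel()) {
  if (spec@category == "DELETION") {
    if (spec@subtype == "CH4") return("p.P31L")
    if (spec@subtype == "CH6") return("I2G")
    return(character(0))
  }
  toks <- spec@variants
  canon <- normalizeToken(toks)
  if (spec@category == "DUPLICATION") {
    return(toks[canon != "V282L"])
  }
  toks[canon != "UTR5"]
}

#' Simulate the full conventional report for one diploid genotype
#'
#' @param allele1,allele2 \code{\linkS4class{AlleleSpec}} objects.
#' @param patientId identifier carried into the report.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return a \code{\linkS4class{ConventionalReport}} (allele-attributed
#'   strings; \code{phaseKnown} is FALSE -- the assay cannot phase without
#'   parental genomes).
#' @examples
#' m <- loadLocusModel()
#' simulateConventional(parseAllele("micro:I2G"), parseAllele("cahx:CH2"),
#'                      "pt1", m)
#' @export
simulateConventional <- function(allele1, allele2, patientId = "",
                                 model = loadLocusModel()) {
  renderOne <- function(spec) {
    if (spec@category == "DELETION") {
      masked <- renderLongPcrCall(spec, model)
      if (length(masked)) return(paste(masked, collapse = ", "))
      return(renderDeletionCall(spec, model))
    }
    toks <- renderLongPcrCall(spec, model)
    if (!length(toks)) return("negative")
    paste(toks, collapse = ", ")
  }
  new("ConventionalReport",
      patientId = as.character(patientId),
      calls = c(renderOne(allele1), renderOne(allele2)),
      dropout = simulateProbeDropout(allele1, allele2, model),
      phaseKnown = FALSE)
}

# Canonical claim string of the true (long-read) allele call, in the same
# normalized space as normalizeReportString() output, so the two assays'
# claims are directly comparable.
.alleleClaim <- function(spec) {
  if (spec@category == "DELETION") {
    if (spec@subtype == "DEL_SOLO") return("EXON_DEL(1,10)")
    if (grepl("^CAHX_", spec@subtype)) return(spec@subtype)
    return(paste0("CHIMERA_", spec@subtype))
  }
  canon <- sort(setdiff(normalizeToken(spec@variants), "UTR5"))
  if (!length(canon)) return("NEGATIVE")
  paste0("TOKENS(", paste(canon, collapse = "|"), ")")
}

.parseNotes <- function(notes) {
  out <- list(force = integer(0), suppress = integer(0),
              phase_unavailable = integer(0))
  if (is.null(notes) || is.na(notes) || !nzchar(notes)) return(out)
  for (part in strsplit(notes, ";", fixed = TRUE)[[1]]) {
    kv <- strsplit(trimws(part), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    idx <- as.integer(kv[2])
    if (kv[1] == "missed_point_call") out$force <- c(out$force, idx)
    if (kv[1] == "phase_unavailable") {
      out$force <- c(out$force, idx)
      out$phase_unavailable <- c(out$phase_unavailable, idx)
    }
    if (kv[1] == "recorded_concordant") out$suppress <- c(out$suppress, idx)
  }
  out
}

#' Flag allele-level discordances between truth and a conventional report
#'
#' One flag per allele: TRUE when the normalized conventional call string
#' does not match the canonical claim of the true allele. Recorded dataset
#' facts not predictable from the assay model are injected through
#' \code{overrides} (a notes string): \code{missed_point_call:k} and
#' \code{phase_unavailable:k} force allele k discordant,
#' \code{recorded_concordant:k} forces it concordant.
#'
#' @param allele1,allele2 true \code{\linkS4class{AlleleSpec}} objects.
#' @param conv a \code{\linkS4class{ConventionalReport}} or a length-2
#'   character of reported strings.
#' @param overrides optional notes string (see above).
#' @param patientId truth-side patient id, checked against the report's.
#' @return logical vector of length 2.
#' @examples
#' m <- loadLocusModel()
#' compareReports(parseAllele("micro:I2G"), parseAllele("cahx:CH2"),
#'                c("I2G", "Exon 1-10 Del"))
#' @export
compareReports <- function(allele1, allele2, conv, overrides = NULL,
                           patientId = NULL) {
  if (is(conv, "ConventionalReport")) {
    if (!is.null(patientId) && nzchar(conv@patientId) &&
        as.character(patientId) != conv@patientId) {
      stop("patient id mismatch: truth '", patientId, "' vs report '",
           conv@patientId, "'", call. = FALSE)
    }
    conv <- conv@calls
  }
  stopifnot(length(conv) == 2L)
  flags <- c(
    .alleleClaim(allele1) != normalizeReportString(conv[1]),
    .alleleClaim(allele2) != normalizeReportString(conv[2])
  )
  ov <- .parseNotes(overrides)
  flags[ov$force] <- TRUE
  flags[ov$suppress] <- FALSE
  flags
}

#' Count discordant allele-level results over a cohort
#'
#' With \code{source = "recorded"} the recorded conventional strings in the
#' cohort table are compared against the true allele calls (reproducing the
#' study's own comparison); with \code{source = "simulated"} the assay model
#' generates the conventional report first, so the count separates what the
#' probe-panel/masking model predicts from recorded dataset facts.
#'
#' @param cohort a \code{\linkS4class{CahCohort}}.
#' @param source \code{"recorded"} or \code{"simulated"}.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @param applyOverrides apply the note-recorded dataset facts (missed
#'   calls, unavailable parental genome, recorded-concordant annotations).
#' @return list with \code{flags} (2 x n logical matrix) and \code{total}.
#' @examples
#' cohortDiscordance(table3Cohort())$total
#' @export
cohortDiscordance <- function(cohort, source = c("recorded", "simulated"),
                              model = loadLocusModel(),
                              applyOverrides = TRUE) {
  source <- match.arg(source)
  pts <- cohort@patients
  flags <- vapply(seq_len(nrow(pts)), function(i) {
    pair <- cohort@alleles[[i]]
    conv <- if (source == "recorded") {
      c(pts$conv_allele1[i], pts$conv_allele2[i])
    } else {
      simulateConventional(pair[[1]], pair[[2]], pts$patient_id[i], model)
    }
    compareReports(pair[[1]], pair[[2]], conv,
                   overrides = if (applyOverrides) pts$notes[i],
                   patientId = pts$patient_id[i])
  }, logical(2))
  list(flags = flags, total = sum(flags))
}

setMethod("show", "ConventionalReport", function(object) {
  cat("ConventionalReport",
      if (nzchar(object@patientId)) paste0("[", object@patientId, "]"),
      "\n  calls:", paste(object@calls, collapse = " / "),
      "\n  phase known:", object@phaseKnown, "\n")
})
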