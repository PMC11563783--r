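# Haplotype classification: junction calling on marker vectors and mapping
# into the allele taxonomy. A marker vector is the site-level abstraction of
# one phased long read: per informative site, does the sequence look like
# the functional gene (GENE), the pseudogene (PSEUDO), is it missing
# entirely (ABSENT), or uncalled (UNKNOWN). All catalogued
# CYP21A1P/CYP21A2 chimeras are single-junction: pseudogene-derived 5'
# content up to one transition point, gene-derived 3' of it.

#' Construct a marker vector
#'
#' @param calls character vector of GENE/PSEUDO/ABSENT/UNKNOWN. If unnamed
#'   it must cover the CYP21A2-region sites of \code{model} in order; if
#'   named, names must equal that site list.
#' @param tnxbSignature TNXB-side signature tokens seen on the haplotype.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return a \code{\linkS4class{MarkerVector}}.
#' @examples
#' m <- loadLocusModel()
#' wt <- markerVector(rep("GENE", 13), model = m)
#' @export
markerVector <- function(calls, tnxbSignature = character(0),
                         model = loadLocusModel()) {
  sites <- .geneSites(model)
  if (is.null(names(calls))) {
    if (length(calls) != length(sites)) {
      stop("marker vector must have one call per CYP21A2-region site (",
           length(sites), ")", call. = FALSE)
    }
    names(calls) <- sites
  } else if (!identical(names(calls), sites)) {
    stop("marker vector call names must match the locus site list in order",
         call. = FALSE)
  }
  new("MarkerVector", calls = calls, tnxbSignature = tnxbSignature)
}

#' Synthesize the marker vector of a catalogued structure
#'
#' Builds the haplotype a given chimera (or whole-gene deletion) would
#' produce: PSEUDO calls over the converted span, GENE calls downstream,
#' ABSENT everywhere for whole-gene losses, plus the CAH-X TNXB signature
#' where one is defined.
#'
#' @param chimera_id catalogue identifier (CH1..CH8 with defined spans,
#'   CAHX_CH1..3, DEL_SOLO).
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return a \code{\linkS4class{MarkerVector}}.
#' @export
markerVectorForChimera <- function(chimera_id, model = loadLocusModel()) {
  ch <- model@chimeras[[chimera_id]]
  if (is.null(ch)) stop("unknown catalogue entry: ", chimera_id, call. = FALSE)
  sites <- .geneSites(model)
  if (chimera_id %in% c("DEL_SOLO", "CAHX_CH1", "CAHX_CH2", "CAHX_CH3")) {
    return(markerVector(stats::setNames(rep("ABSENT", length(sites)), sites),
                        tnxbSignature = ch$tnxb_signature, model = model))
  }
  if (!isTRUE(ch$observed) || is.na(ch$span_end)) {
    stop("catalogue entry ", chimera_id,
         " has no defined junction span", call. = FALSE)
  }
  cut <- match(ch$span_end, sites)
  calls <- stats::setNames(
    c(rep("PSEUDO", cut - 1L), rep("GENE", length(sites) - cut + 1L)),
    sites)
  markerVector(calls, model = model)
}

#' Call the pseudogene-to-gene junction of a haplotype
#'
#' Finds the tightest interval containing the single 5'-pseudogene to
#' 3'-gene transition: the last site with a PSEUDO/ABSENT call and the
#' first site with a GENE call. UNKNOWN calls are unconstrained. A
#' haplotype with a GENE call upstream of a PSEUDO/ABSENT call lies outside
#' the single-junction model and raises an error naming both offending
#' sites.
#'
#' @param mv a \code{\linkS4class{MarkerVector}}.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return a list with elements \code{left}, \code{right} (site ids; both
#'   \code{NA} when there is no junction), \code{none} (TRUE when the
#'   haplotype is all-GENE or all-ABSENT) and \code{wholeGeneAbsent}.
#' @examples
#' m <- loadLocusModel()
#' callJunction(markerVectorForChimera("CH1", m), m)
#' @export
callJunction <- function(mv, model = loadLocusModel()) {
  calls <- mv@calls
  known <- calls != "UNKNOWN"
  if (!any(known)) stop("marker vector has no informative call", call. = FALSE)
  isGene <- calls == "GENE" & known
  isPseudoSide <- calls %in% c("PSEUDO", "ABSENT") & known
  if (!any(isPseudoSide)) {
    return(list(left = NA_character_, right = NA_character_,
                none = TRUE, wholeGeneAbsent = FALSE))
  }
  if (!any(isGene)) {
    return(list(left = NA_character_, right = NA_character_, none = TRUE,
                wholeGeneAbsent = all(calls[known] == "ABSENT")))
  }
  firstGene <- which(isGene)[1]
  lastPseudo <- max(which(isPseudoSide))
  if (lastPseudo > firstGene) {
    stop("non-canonical haplotype: GENE call at ",
         names(calls)[firstGene], " upstream of ",
         calls[lastPseudo], " call at ", names(calls)[lastPseudo],
         " (outside the single-junction model)", call. = FALSE)
  }
  list(left = names(calls)[lastPseudo], right = names(calls)[firstGene],
       none = FALSE, wholeGeneAbsent = FALSE)
}

#' Type a chimera from its junction interval
#'
#' Whole-gene-absent haplotypes are typed by TNXB signature (CAH-X CH1-CH3,
#' or DEL_SOLO with an empty signature). Otherwise the junction interval is
#' matched against the catalogue; junctions inside the exon 1-3 region are
#' disambiguated by I2G and 8-bp-deletion carriage (both carried with the
#' span running through exon 3: CH1; I2G carried without the 8 bp deletion:
#' CH6; span covering only UTR5 and exon 1: CH4). A junction matching no
#' catalogue entry yields an unclassified result carrying the interval, not
#' an error.
#'
#' @param junction result of \code{\link{callJunction}}.
#' @param mv the \code{\linkS4class{MarkerVector}} the junction came from.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return a list with \code{chimera_id} (or \code{NA} when unclassified)
#'   and \code{junction}.
#' @export
classifyChimera <- function(junction, mv, model = loadLocusModel()) {
  if (isTRUE(junction$wholeGeneAbsent)) {
    sig <- sort(mv@tnxbSignature)
    for (id in c("CAHX_CH1", "CAHX_CH2", "CAHX_CH3")) {
      if (identical(sort(model@chimeras[[id]]$tnxb_signature), sig) &&
          length(sig)) {
        return(list(chimera_id = id, junction = junction))
      }
    }
    if (!length(sig)) return(list(chimera_id = "DEL_SOLO",
                                  junction = junction))
    return(list(chimera_id = NA_character_, junction = junction))
  }
  if (isTRUE(junction$none)) {
    stop("haplotype has no junction to classify", call. = FALSE)
  }
  for (id in paste0("CH", 1:9)) {
    ch <- model@chimeras[[id]]
    if (!isTRUE(ch$observed)) next
    if (identical(unname(ch$junction), c(junction$left, junction$right))) {
      # cross-check the I2G / 8 bp carriage implied by the marker vector
      carried <- mv@calls["I2G_SITE"] == "PSEUDO"
      del8 <- mv@calls["DEL8BP_SITE"] == "PSEUDO"
      if (!is.na(ch$carries_I2G) && carried != ch$carries_I2G) next
      if (!is.na(ch$carries_8bp_del) && del8 != ch$carries_8bp_del) next
      return(list(chimera_id = id, junction = junction))
    }
  }
  list(chimera_id = NA_character_, junction = junction)
}

#' Classify one haplotype into the allele taxonomy
#'
#' Structural evidence dominates: a marker vector showing whole-gene
#' absence or a pseudogene-to-gene junction yields a DELETION allele typed
#' by \code{\link{classifyChimera}}; declared extra copies yield a
#' DUPLICATION. Otherwise the variant token list decides: every token in
#' the pseudogene-derived set gives MICROCONVERSION, any other token gives
#' NOVEL_VARIANT (the token list is preserved either way). The result is
#' deterministic and invariant to token order.
#'
#' @param variants character vector of variant tokens (possibly empty).
#' @param mv optional \code{\linkS4class{MarkerVector}}.
#' @param extraCopies optional list of per-copy token vectors for
#'   duplication alleles (the fused exon 7-8 copy's tokens; an intact copy
#'   is an empty element).
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return an \code{\linkS4class{AlleleSpec}}.
#' @examples
#' m <- loadLocusModel()
#' classifyAllele("I2G", model = m)
#' classifyAllele(character(0), markerVectorForChimera("CAHX_CH1", m),
#'                model = m)
#' @export
classifyAllele <- function(variants = character(0), mv = NULL,
                           extraCopies = NULL, model = loadLocusModel()) {
  if (!length(variants) && is.null(mv) && is.null(extraCopies)) {
    stop("classifyAllele needs variants, a marker vector or copy structure",
         call. = FALSE)
  }
  if (!is.null(extraCopies)) {
    toks <- unique(unlist(extraCopies))
    return(newAlleleSpec("DUPLICATION", "DUP_E7E8",
                         variants = as.character(toks),
                         copies = extraCopies))
  }
  if (!is.null(mv)) {
    j <- callJunction(mv, model)
    if (!j$none || j$wholeGeneAbsent) {
      cls <- classifyChimera(j, mv, model)
      if (is.na(cls$chimera_id)) {
        stop("junction (", j$left, ", ", j$right,
             ") matches no catalogue entry", call. = FALSE)
      }
      return(newAlleleSpec("DELETION", cls$chimera_id))
    }
    # wild-type marker vector: classification must come from the tokens
    if (!length(variants)) {
      stop("inconsistent evidence: wild-type marker vector and no variants",
           call. = FALSE)
    }
  }
  canon <- normalizeToken(variants)
  if (all(canon %in% model@pseudogeneSet)) {
    newAlleleSpec("MICROCONVERSION", variants = variants,
                  copies = list(variants))
  } else {
    newAlleleSpec("NOVEL_VARIANT", variants = variants,
                  copies = list(variants))
  }
}

# Rebuild the raw evidence (tokens / marker vector / copies) an allele spec
# implies -- used to close the loop in tests and by the cohort generator.
.alleleEvidence <- function(spec, model) {
  switch(spec@category,
    DELETION = list(variants = character(0),
                    mv = markerVectorForChimera(spec@subtype, model),
                    extraCopies = NULL),
    DUPLICATION = list(variants = character(0), mv = NULL,
                       extraCopies = spec@copies),
    list(variants = spec@variants, mv = NULL, extraCopies = NULL)
  )
}

setMethod("show", "MarkerVector", function(object) {
  cat("MarkerVector (", length(object@calls), " sites )\n")
  abbrev <- c(GENE = "G", PSEUDO = "P", ABSENT = "-", UNKNOWN = "?")
  cat(" ", paste(abbrev[object@calls], collapse = ""), "\n")
  if (length(object@tnxbSignature)) {
    cat("  TNXB signature:", paste(object@tnxbSignature, collapse = ", "),
        "\n")
  }
})
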