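# The allele mini-grammar used in cohort files:
#   micro:TOK[+TOK...]   microconversion allele
#   novel:TOK[+TOK...]   allele with >=1 non-pseudogene-derived token
#   del:solo             solo whole-gene deletion
#   cahx:CH1|CH2|CH3     TNXA/TNXB chimera (whole-gene loss + TNXB signature)
#   chimera:CH1..CH9     CYP21A1P/CYP21A2 chimera
#   dup:E7E8[TOK,...]    single fused CYP21A2/CYP21A1P copy
#   dup:E7E8[TOK,...]+WT trimodular allele: fused copy plus an intact copy
# Parser and serializer are exact inverses on canonical strings.

newAlleleSpec <- function(category, subtype = "NONE",
                          variants = character(0), copies = list()) {
  new("AlleleSpec", category = category, subtype = subtype,
      variants = variants, copies = copies)
}

#' Parse an allele string
#'
#' @param s a single allele string in the mini-grammar.
#' @return an \code{\linkS4class{AlleleSpec}}.
#' @examples
#' parseAllele("micro:I2G+p.G111Vfs*21")
#' parseAllele("dup:E7E8[p.V282L,p.L308Ffs*6,p.Q319X]+WT")
#' @export
parseAllele <- function(s) {
  s0 <- trimws(s)
  if (!nzchar(s0)) stop("empty allele string", call. = FALSE)
  m <- regmatches(s0, regexec("^([a-z]+):(.*)$", s0))[[1]]
  if (length(m) != 3L) {
    stop("allele string '", s0, "' does not match production ",
         "'<kind>:<body>'", call. = FALSE)
  }
  kind <- m[2]; body <- m[3]
  switch(kind,
    micro = {
      toks <- .splitGrammarTokens(body)
      if (!length(toks)) stop("micro allele needs >=1 token", call. = FALSE)
      newAlleleSpec("MICROCONVERSION", variants = toks,
                    copies = list(toks))
    },
    novel = {
      toks <- .splitGrammarTokens(body)
      if (!length(toks)) stop("novel allele needs >=1 token", call. = FALSE)
      newAlleleSpec("NOVEL_VARIANT", variants = toks, copies = list(toks))
    },
    del = {
      if (body != "solo") {
        stop("allele string '", s0, "' does not match production 'del:solo'",
             call. = FALSE)
      }
      newAlleleSpec("DELETION", "DEL_SOLO")
    },
    cahx = {
      if (!grepl("^CH[1-3]$", body)) {
        stop("allele string '", s0,
             "' does not match production 'cahx:CH1|CH2|CH3'", call. = FALSE)
      }
      newAlleleSpec("DELETION", paste0("CAHX_", body))
    },
    chimera = {
      if (!grepl("^CH[1-9]$", body)) {
        stop("allele string '", s0,
             "' does not match production 'chimera:CH1..CH9'", call. = FALSE)
      }
      newAlleleSpec("DELETION", body)
    },
    dup = {
      mm <- regmatches(body,
                       regexec("^E7E8\\[([^]]*)\\](\\+WT)?$", body))[[1]]
      if (length(mm) != 3L) {
        stop("allele string '", s0,
             "' does not match production 'dup:E7E8[TOK,...]'",
             call. = FALSE)
      }
      toks <- .splitTokens(mm[2])
      copies <- if (nzchar(mm[3])) list(character(0), toks) else list(toks)
      newAlleleSpec("DUPLICATION", "DUP_E7E8", variants = toks,
                    copies = copies)
    },
    stop("unknown allele production '", kind, ":' in '", s0, "'",
         call. = FALSE)
  )
}

#' Serialize an allele back to its grammar string
#'
#' Exact inverse of \code{\link{parseAllele}} on canonical strings.
#'
#' @param spec an \code{\linkS4class{AlleleSpec}}.
#' @return a single character string.
#' @export
formatAllele <- function(spec) {
  stopifnot(is(spec, "AlleleSpec"))
  switch(spec@category,
    MICROCONVERSION = paste0("micro:", paste(spec@variants, collapse = "+")),
    NOVEL_VARIANT   = paste0("novel:", paste(spec@variants, collapse = "+")),
    DELETION = {
      if (spec@subtype == "DEL_SOLO") "del:solo"
      else if (grepl("^CAHX_", spec@subtype))
        paste0("cahx:", sub("^CAHX_", "", spec@subtype))
      else paste0("chimera:", spec@subtype)
    },
    DUPLICATION = {
      base <- paste0("dup:E7E8[", paste(spec@variants, collapse = ","), "]")
      if (length(spec@copies) > 1L) paste0(base, "+WT") else base
    }
  )
}

#' @describeIn classifyAllele allele category accessor
#' @export
alleleCategory <- function(spec) spec@category

#' @describeIn classifyAllele structural subtype accessor (\code{"NONE"} for
#'   point-variant alleles)
#' @export
alleleSubtype <- function(spec) spec@subtype

#' @describeIn classifyAllele variant token accessor
#' @export
alleleVariants <- function(spec) spec@variants

#' @describeIn classifyAllele number of gene(-derived) copies the allele
#'   carries (2 for trimodular duplication alleles, 1 otherwise)
#' @export
alleleCopies <- function(spec) max(1L, length(spec@copies))

setMethod("show", "AlleleSpec", function(object) {
  cat("AlleleSpec:", formatAllele(object), "\n")
  cat("  category:", object@category,
      if (object@subtype != "NONE") paste0("(", object@subtype, ")"), "\n")
  if (length(object@variants)) {
    cat("  variants:", paste(object@variants, collapse = ", "), "\n")
  }
})
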