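# Variant-token normalization. Table-3-style strings mix legacy and current
# residue numbering (p.V281L vs p.V282L), optional "p." prefixes, and
# frameshift length suffixes ("p.L308Ffs*6" vs "p.L308Ffs*"); everything
# funnels through one canonical spelling before counting or comparison.

.TOKEN_SYNONYMS <- c(
  "V281L"      = "V282L",
  "P453S"      = "P454S",
  "G110fs"     = "G111Vfs",
  "Leu308fs"   = "L308Ffs",
  "L308fs"     = "L308Ffs",
  "IG2"        = "I2G",
  "E6cluster"  = "E6_CLUSTER",
  "E6 cluster" = "E6_CLUSTER",
  "Cluster6E"  = "E6_CLUSTER",
  "E6_CLUSTER" = "E6_CLUSTER",
  "c.293-13A/C>G" = "I2G",
  "c.293-13A>G"   = "I2G",
  "c.293-13C>G"   = "I2G"
)

#' Normalize a single variant token to its canonical spelling
#'
#' Trims whitespace, drops a leading \code{p.}, strips frameshift-length
#' suffixes (\code{*6}, \code{*58}, a bare trailing \code{*}), collapses
#' whitespace inside cDNA-style names, resolves legacy/current residue
#' numbering through the synonym table, and reduces any
#' \code{UTR5(...)} promoter-conversion spelling to the bare \code{UTR5}
#' token. Idempotent.
#'
#' @param token character vector of variant tokens.
#' @return character vector of canonical tokens.
#' @examples
#' normalizeToken(c("p.L308Ffs*6", "p.V281L", "R357W", "UTR5(-103,-110)"))
#' @export
normalizeToken <- function(token) {
  vapply(token, function(tk) {
    tk <- trimws(tk)
    tk <- gsub("\u2212", "-", tk)         # unicode minus
    if (grepl("^c\\.", tk)) {
      tk <- gsub("\\s+", "", tk)             # "c.292 + 1G > A"
    } else {
      tk <- sub("^[pP]\\.", "", tk)
      tk <- sub("\\*[0-9]*$", "", tk)        # fs length suffix or bare *
    }
    if (grepl("^UTR5\\s*\\(", tk)) tk <- "UTR5"
    hit <- match(tk, names(.TOKEN_SYNONYMS))
    if (!is.na(hit)) tk <- unname(.TOKEN_SYNONYMS[hit])
    tk
  }, character(1), USE.NAMES = FALSE)
}

# Split a comma-separated token list (dup grammar bodies, recorded
# conventional strings).
.splitTokens <- function(s) {
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

# Split a "+"-separated grammar token list. Tokens never start with a
# digit, so a fragment that does belongs to the previous token (cDNA names
# like c.292+1G>A contain a literal "+").
.splitGrammarTokens <- function(body) {
  parts <- strsplit(body, "+", fixed = TRUE)[[1]]
  out <- character(0)
  for (p in parts) {
    if (length(out) && grepl("^[0-9]", p)) {
      out[length(out)] <- paste0(out[length(out)], "+", p)
    } else {
      out <- c(out, p)
    }
  }
  out
}
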