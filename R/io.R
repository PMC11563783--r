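# Cohort schema I/O and report-string normalization. The cohort file is a
# UTF-8 TSV (or JSON) with columns patient_id, sex, age_years, phenotype,
# allele1, allele2, extra_copy, conv_allele1, conv_allele2, notes; allele
# columns use the mini-grammar, conv_* keep the conventional assay's
# reported strings verbatim, notes carries recorded dataset facts in
# "key:allele_index" form.

.COHORT_COLUMNS <- c("patient_id", "sex", "age_years", "phenotype",
                     "allele1", "allele2", "extra_copy",
                     "conv_allele1", "conv_allele2", "notes")

#' Normalize a conventional-assay report string
#'
#' Maps the free-text strings of the study's result columns onto canonical
#' claims so two reports can be compared: exon-span deletions become
#' \code{EXON_DEL(a,b)} (a full-gene "del (CYP21A2)" is \code{EXON_DEL(1,10)}),
#' structural calls become \code{CAHX_CHk} / \code{CHIMERA_CHk}, "negative"
#' (or an em-dash) becomes \code{NEGATIVE}, a donor-sperm/IVF annotation
#' becomes \code{UNAVAILABLE}, and anything else is treated as a point-call
#' token list: tokens are canonicalized (\code{\link{normalizeToken}}),
#' promoter/UTR5 tokens -- outside the conventional assay's reportable
#' domain -- are dropped, and the sorted set becomes
#' \code{TOKENS(tok|tok|...)}. Idempotent: canonical forms map to
#' themselves.
#'
#' @param s character vector of report strings.
#' @return character vector of canonical claims.
#' @examples
#' normalizeReportString(c("Exon 1-10 Del", "p.L308Ffs*6, p.Q319X",
#'                         "del (CAH-X-CH1)", "negative"))
#' @export
normalizeReportString <- function(s) {
  vapply(s, .normalizeReportOne, character(1), USE.NAMES = FALSE)
}

.normalizeReportOne <- function(s) {
  if (is.na(s)) return("NEGATIVE")
  s <- trimws(s)
  s <- gsub("\u2014|\u2013", "-", s)   # em/en dash
  if (!nzchar(s) || s == "-" || tolower(s) == "negative" ||
      s == "NEGATIVE") {
    return("NEGATIVE")
  }
  if (s == "UNAVAILABLE" || grepl("sperm|ivf|in vitro fertilization",
                                  s, ignore.case = TRUE)) {
    return("UNAVAILABLE")
  }
  if (grepl("^EXON_DEL\\([0-9]+,[0-9]+\\)$", s) ||
      grepl("^EXON_DEL_SITES\\([0-9,]+\\)$", s) ||
      grepl("^CAHX_CH[1-3]$", s) || grepl("^CHIMERA_CH[1-9]$", s)) {
    return(s)
  }
  if (grepl("^TOKENS\\(.*\\)$", s)) {
    inner <- sub("^TOKENS\\((.*)\\)$", "\\1", s)
    return(.canonTokenClaim(strsplit(inner, "|", fixed = TRUE)[[1]]))
  }
  m <- regmatches(s, regexec(
    "^[Ee]xon[s]?\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*[Dd]el[a-z]*$", s))[[1]]
  if (length(m) == 3L) {
    return(paste0("EXON_DEL(", as.integer(m[2]), ",", as.integer(m[3]), ")"))
  }
  m <- regmatches(s, regexec(
    "^[Ee]xon[s]?\\s*([0-9]+(\\s*,\\s*[0-9]+)+)\\s*[Dd]el[a-z]*$", s))[[1]]
  if (length(m) >= 2L) {
    ex <- gsub("\\s", "", m[2])
    return(paste0("EXON_DEL_SITES(", ex, ")"))
  }
  if (grepl("^del\\s*\\(\\s*CYP21A2\\s*\\)$", s, ignore.case = TRUE)) {
    return("EXON_DEL(1,10)")
  }
  m <- regmatches(s, regexec("CAH[- ]?X[- ]?CH\\s*([1-3])", s,
                             ignore.case = TRUE))[[1]]
  if (length(m) == 2L) return(paste0("CAHX_CH", m[2]))
  m <- regmatches(s, regexec("\\(\\s*CH([1-9])\\s*\\)", s))[[1]]
  if (length(m) == 2L) return(paste0("CHIMERA_CH", m[2]))
  .canonTokenClaim(.splitTokens(s))
}

.canonTokenClaim <- function(tokens) {
  canon <- sort(unique(setdiff(normalizeToken(tokens), "UTR5")))
  if (!length(canon)) return("NEGATIVE")
  paste0("TOKENS(", paste(canon, collapse = "|"), ")")
}

#' Read a cohort file
#'
#' @param path TSV (any other extension) or JSON (\code{.json}) cohort file
#'   following the package schema. Parse failures are reported with the
#'   offending row number and grammar production.
#' @return a \code{\linkS4class{CahCohort}}.
#' @examples
#' cohort <- table3Cohort()
#' cohort
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            fileEncoding = "UTF-8", check.names = TRUE)
  }
  missing_cols <- setdiff(c("patient_id", "sex", "age_years", "phenotype",
                            "allele1", "allele2"), names(df))
  if (length(missing_cols)) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (opt in setdiff(.COHORT_COLUMNS, names(df))) {
    df[[opt]] <- character(nrow(df))
  }
  df <- df[, .COHORT_COLUMNS]
  df$age_years <- as.numeric(df$age_years)
  bad_ph <- which(!(df$phenotype %in% c("SW", "SV", "NC", "UNKNOWN")))
  if (length(bad_ph)) {
    stop("row ", bad_ph[1], ": phenotype '", df$phenotype[bad_ph[1]],
         "' is not one of SW, SV, NC", call. = FALSE)
  }
  alleles <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    alleles[[i]] <- tryCatch(
      list(parseAllele(df$allele1[i]), parseAllele(df$allele2[i])),
      error = function(e) {
        stop("row ", i, " (patient ", df$patient_id[i], "): ",
             conditionMessage(e), call. = FALSE)
      })
  }
  new("CahCohort", patients = df, alleles = alleles)
}

#' Write a cohort back to TSV
#'
#' Inverse of \code{\link{readCohort}} for TSV input: writing a cohort read
#' from a canonical file reproduces it byte for byte.
#'
#' @param cohort a \code{\linkS4class{CahCohort}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  df <- cohort@patients
  df$allele1 <- vapply(cohort@alleles, function(p) formatAllele(p[[1]]),
                       character(1))
  df$allele2 <- vapply(cohort@alleles, function(p) formatAllele(p[[2]]),
                       character(1))
  df$age_years <- as.character(df$age_years)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  invisible(path)
}

#' The digitized 67-patient study cohort
#'
#' Loads the packaged fixture transcribing the study's per-patient results
#' table: both structurally resolved long-read allele calls per patient (in
#' the allele mini-grammar), the recorded MLPA + Long-PCR result strings,
#' and notes carrying the recorded dataset facts (the donor-sperm IVF
#' patient whose paternal allele origin the conventional assay could not
#' determine; the paternally inherited p.R357W the conventional assay
#' missed; one CH1 comparison the study recorded as concordant).
#'
#' @return a \code{\linkS4class{CahCohort}} of 67 patients.
#' @examples
#' nPatients(table3Cohort())
#' @export
table3Cohort <- function() {
  readCohort(system.file("extdata", "table3_cohort.tsv",
                         package = "rccxtyper", mustWork = TRUE))
}

#' @describeIn readCohort number of patients
#' @param cohort a \code{\linkS4class{CahCohort}}.
#' @export
nPatients <- function(cohort) nrow(cohort@patients)

#' @describeIn readCohort patient-level table accessor
#' @export
patientData <- function(cohort) cohort@patients

#' @describeIn readCohort list of per-patient allele pairs
#' @export
cohortAlleles <- function(cohort) cohort@alleles

#' @describeIn readCohort phenotype vector, named by patient id
#' @export
phenotypes <- function(cohort) {
  stats::setNames(cohort@patients$phenotype, cohort@patients$patient_id)
}

setMethod("show", "CahCohort", function(object) {
  df <- object@patients
  cat("CahCohort:", nrow(df), "patients,", 2L * nrow(df), "alleles\n")
  if (nrow(df)) {
    cat("  sex:", sum(df$sex == "M"), "M /", sum(df$sex == "F"), "F;",
        "phenotypes:", paste(names(table(df$phenotype)),
                             table(df$phenotype), collapse = ", "), "\n")
  }
})

setMethod("length", "CahCohort", function(x) nrow(x@patients))

#' Subset a cohort by patient index
#' @param x a \code{\linkS4class{CahCohort}}
#' @param i numeric or logical index over patients
#' @param j,...,drop ignored
#' @export
setMethod("[", "CahCohort", function(x, i, j, ..., drop = FALSE) {
  new("CahCohort", patients = x@patients[i, , drop = FALSE],
      alleles = x@alleles[i])
})
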