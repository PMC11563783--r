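# Cohort-level statistics: the allele frequency spectrum, taxonomy
# category proportions, the genotype-group x phenotype cross-tab with its
# concordance and per-group positive predictive rates, and the
# tie-corrected Spearman rank correlation between group and phenotype
# severity. The allele denominator is 2 x n_patients (alleles, not gene
# copies: a trimodular duplication haplotype still counts once).

.GROUP_LEVELS <- c("Null", "A", "B", "C")
.PHENO_LEVELS <- c("SW", "SV", "NC")

# Type key used for frequency rows: structural subtype for structural
# alleles, the sorted canonical token set for point alleles, DUP_E7E8 for
# every duplication allele (the study tallies all four together).
.alleleTypeKey <- function(spec) {
  if (spec@category %in% c("DELETION")) return(spec@subtype)
  if (spec@category == "DUPLICATION") return("DUP_E7E8")
  paste(sort(normalizeToken(spec@variants)), collapse = "+")
}

#' Allele frequency table
#'
#' Per-type allele counts and rates over the cohort, denominator
#' 2 x n_patients.
#'
#' @param cohort a \code{\linkS4class{CahCohort}}.
#' @return data.frame with columns \code{type}, \code{category},
#'   \code{count}, \code{rate}, sorted by decreasing count.
#' @examples
#' head(alleleFrequencyTable(table3Cohort()))
#' @export
alleleFrequencyTable <- function(cohort) {
  specs <- unlist(cohort@alleles, recursive = FALSE)
  if (!length(specs)) {
    return(data.frame(type = character(0), category = character(0),
                      count = integer(0), rate = numeric(0)))
  }
  keys <- vapply(specs, .alleleTypeKey, character(1))
  cats <- vapply(specs, alleleCategory, character(1))
  tab <- table(keys)
  denom <- 2L * nPatients(cohort)
  out <- data.frame(type = names(tab),
                    category = cats[match(names(tab), keys)],
                    count = as.integer(tab),
                    rate = as.integer(tab) / denom,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$type), ]
  rownames(out) <- NULL
  out
}

#' Taxonomy category proportions
#'
#' Fractions of alleles per taxonomy category, with the deletion category
#' split into complete gene loss (solo deletion + TNXA/TNXB chimeras) and
#' partial loss (CYP21A1P/CYP21A2 chimeras).
#'
#' @param cohort a \code{\linkS4class{CahCohort}}.
#' @return named numeric: microconversion, novel_variant, deletion,
#'   deletion_complete, deletion_partial, duplication.
#' @examples
#' round(categoryProportions(table3Cohort()) * 100, 1)
#' @export
categoryProportions <- function(cohort) {
  specs <- unlist(cohort@alleles, recursive = FALSE)
  n <- length(specs)
  if (!n) {
    return(c(microconversion = NA_real_, novel_variant = NA_real_,
             deletion = NA_real_, deletion_complete = NA_real_,
             deletion_partial = NA_real_, duplication = NA_real_))
  }
  cats <- vapply(specs, alleleCategory, character(1))
  subs <- vapply(specs, alleleSubtype, character(1))
  complete <- cats == "DELETION" &
    (subs == "DEL_SOLO" | grepl("^CAHX_", subs))
  partial <- cats == "DELETION" & !complete
  c(microconversion = sum(cats == "MICROCONVERSION") / n,
    novel_variant = sum(cats == "NOVEL_VARIANT") / n,
    deletion = sum(cats == "DELETION") / n,
    deletion_complete = sum(complete) / n,
    deletion_partial = sum(partial) / n,
    duplication = sum(cats == "DUPLICATION") / n)
}

#' Genotype-group by phenotype cross-tabulation
#'
#' 4 x 3 count table over the classifiable groups (Null/A/B/C); group-D
#' patients (unknown-effect alleles) are excluded, as are patients with
#' unknown phenotype.
#'
#' @param cohort a \code{\linkS4class{CahCohort}}.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return integer matrix, rows Null/A/B/C, columns SW/SV/NC.
#' @examples
#' crosstabGroupPhenotype(table3Cohort())
#' @export
crosstabGroupPhenotype <- function(cohort, model = loadLocusModel()) {
  groups <- genotypeGroups(cohort, model)
  pheno <- cohort@patients$phenotype
  keep <- groups %in% .GROUP_LEVELS & pheno %in% .PHENO_LEVELS
  ct <- table(factor(groups[keep], levels = .GROUP_LEVELS),
              factor(pheno[keep], levels = .PHENO_LEVELS))
  m <- matrix(as.integer(ct), nrow = 4, dimnames = dimnames(ct))
  names(dimnames(m)) <- c("group", "phenotype")
  m
}

#' Genotype-phenotype concordance rate
#'
#' Fraction of classified patients whose phenotype equals the phenotype
#' expected for their genotype group (Null/A -> SW, B -> SV, C -> NC).
#'
#' @param crosstab a 4 x 3 matrix from \code{\link{crosstabGroupPhenotype}}.
#' @return a fraction in [0, 1].
#' @examples
#' concordanceRate(crosstabGroupPhenotype(table3Cohort()))
#' @export
concordanceRate <- function(crosstab) {
  n <- sum(crosstab)
  if (n == 0) stop("concordance undefined for an empty cross-tab",
                   call. = FALSE)
  hits <- sum(vapply(.GROUP_LEVELS, function(g) {
    crosstab[g, expectedPhenotype(g)]
  }, numeric(1)))
  hits / n
}

#' Positive predictive rate of a genotype group
#'
#' Fraction of patients in the group whose phenotype equals the group's
#' expected phenotype.
#'
#' @param crosstab a 4 x 3 matrix from \code{\link{crosstabGroupPhenotype}}.
#' @param group one of \code{"Null"}, \code{"A"}, \code{"B"}, \code{"C"}.
#' @return a fraction in [0, 1].
#' @examples
#' positivePredictiveRate(crosstabGroupPhenotype(table3Cohort()), "Null")
#' @export
positivePredictiveRate <- function(crosstab, group) {
  stopifnot(group %in% .GROUP_LEVELS)
  rowTotal <- sum(crosstab[group, ])
  if (rowTotal == 0) {
    stop("positive predictive rate undefined: empty row for group ", group,
         call. = FALSE)
  }
  crosstab[group, expectedPhenotype(group)] / rowTotal
}

# Mid-ranks by definition: rank of x_i = (# strictly smaller) + (ties + 1)/2.
.midRanks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

#' Tie-corrected Spearman rank correlation
#'
#' Computed from the definition: both margins are converted to mid-ranks
#' (ties receive the average of the ranks they span) and the product-moment
#' correlation of the two rank vectors is evaluated directly from its sums.
#' This is the standard tie-corrected Spearman coefficient; with many ties
#' -- as with a handful of ordinal genotype groups and three phenotypes --
#' the classic 1 - 6*sum(d^2)/(n(n^2-1)) shortcut is not valid, which is
#' why the mid-rank route is used.
#'
#' @param x,y equal-length numeric/ordinal vectors (n >= 2). For the
#'   genotype-phenotype analysis the codings are group Null=1..C=4 and
#'   phenotype SW=1, SV=2, NC=3; any strictly increasing recoding gives the
#'   same value.
#' @return rho in [-1, 1].
#' @examples
#' spearmanTieCorrected(c(1, 2, 2, 3), c(1, 1, 2, 3))
#' @export
spearmanTieCorrected <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("need at least two pairs", call. = FALSE)
  rx <- .midRanks(x)
  ry <- .midRanks(y)
  dx <- rx - sum(rx) / n
  dy <- ry - sum(ry) / n
  sxx <- sum(dx * dx)
  syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0) {
    stop("rank correlation undefined: zero variance in a margin",
         call. = FALSE)
  }
  sum(dx * dy) / sqrt(sxx * syy)
}

# Expand a cross-tab into (group, phenotype) ordinal pairs.
.crosstabPairs <- function(crosstab) {
  g <- integer(0); p <- integer(0)
  for (i in seq_along(.GROUP_LEVELS)) {
    for (j in seq_along(.PHENO_LEVELS)) {
      k <- crosstab[i, j]
      g <- c(g, rep(i, k))
      p <- c(p, rep(j, k))
    }
  }
  list(group = g, phenotype = p)
}

#' Full cohort summary
#'
#' Computes every cohort-level result in one pass: the allele frequency
#' table, category proportions, the group x phenotype cross-tab, the
#' concordance rate, per-group positive predictive rates, and the
#' tie-corrected Spearman correlation between genotype group and phenotype
#' severity.
#'
#' @param cohort a \code{\linkS4class{CahCohort}}.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return a \code{\linkS4class{CohortStats}}.
#' @examples
#' cohortStats(table3Cohort())
#' @export
cohortStats <- function(cohort, model = loadLocusModel()) {
  ct <- crosstabGroupPhenotype(cohort, model)
  pairs <- .crosstabPairs(ct)
  new("CohortStats",
      alleleCounts = alleleFrequencyTable(cohort),
      categoryProportions = categoryProportions(cohort),
      crosstab = ct,
      nClassified = as.integer(sum(ct)),
      concordance = concordanceRate(ct),
      ppv = vapply(.GROUP_LEVELS, positivePredictiveRate,
                   numeric(1), crosstab = ct),
      rho = spearmanTieCorrected(pairs$group, pairs$phenotype))
}

#' Serialize cohort statistics to JSON
#'
#' @param stats a \code{\linkS4class{CohortStats}}.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to \code{path}).
#' @export
statsToJson <- function(stats, path = NULL) {
  ct <- stats@crosstab
  doc <- list(
    allele_counts = stats@alleleCounts,
    category_proportions = as.list(stats@categoryProportions),
    crosstab = stats::setNames(
      lapply(seq_len(nrow(ct)), function(i) as.list(ct[i, ])),
      rownames(ct)),
    n_classified = stats@nClassified,
    concordance = stats@concordance,
    ppv = as.list(stats@ppv),
    spearman_rho = stats@rho)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

setMethod("show", "CohortStats", function(object) {
  cat("CohortStats\n")
  cat("  alleles:", sum(object@alleleCounts$count), "of",
      nrow(object@alleleCounts), "types\n")
  cp <- round(100 * object@categoryProportions, 1)
  cat("  categories (%): micro", cp[["microconversion"]],
      "| novel", cp[["novel_variant"]],
      "| del", cp[["deletion"]],
      "| dup", cp[["duplication"]], "\n")
  cat("  group x phenotype (n =", object@nClassified, "):\n")
  print(object@crosstab)
  cat("  concordance:", sprintf("%.1f%%", 100 * object@concordance),
      " PPV:", paste(names(object@ppv),
                     sprintf("%.1f%%", 100 * object@ppv), collapse = ", "),
      "\n")
  cat("  Spearman rho (tie-corrected):", sprintf("%.3f", object@rho), "\n")
})
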