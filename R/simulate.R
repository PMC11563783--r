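# Synthetic cohorts with the statistical structure of the study: allele
# draws from the observed frequency spectrum, independent diploid pairing,
# phenotype drawn from the group-conditional phenotype distribution, and
# conventional-assay reports from the assay model with optional reporting
# artifacts (missed point calls, unavailable parental phase).

#' Build a simulation configuration
#'
#' Defaults reproduce the study conditions: the allele frequency spectrum
#' and the phenotype-given-group distribution are taken from the packaged
#' cohort (counts / 134 and the row-normalized group x phenotype table),
#' and artifact rates are zero.
#'
#' @param n_patients number of diploid patients to simulate.
#' @param seed integer seed; every random draw flows from it.
#' @param allele_freqs named numeric, probability per allele grammar
#'   string; must sum to 1 (tolerance 1e-9).
#' @param phenotype_given_group 5 x 3 matrix (rows Null/A/B/C/D, columns
#'   SW/SV/NC) of conditional phenotype probabilities; each row must sum
#'   to 1. The default D row is uniform: the study gives no phenotype
#'   distribution for unknown-effect genotypes, and D patients are excluded
#'   from the statistics anyway.
#' @param artifact_rates list with \code{missed_point_call} and
#'   \code{phase_unavailable} probabilities (default 0).
#' @return a validated list of class \code{rccx_sim_config}.
#' @examples
#' cfg <- simConfig(n_patients = 50, seed = 1)
#' @export
simConfig <- function(n_patients, seed,
                      allele_freqs = NULL,
                      phenotype_given_group = NULL,
                      artifact_rates = list(missed_point_call = 0,
                                            phase_unavailable = 0)) {
  stopifnot(n_patients >= 0, is.numeric(seed))
  if (is.null(allele_freqs)) {
    allele_freqs <- .defaultAlleleFreqs()
  }
  if (abs(sum(allele_freqs) - 1) > 1e-9) {
    stop("configuration error: allele_freqs must sum to 1", call. = FALSE)
  }
  if (any(allele_freqs < 0)) {
    stop("configuration error: allele_freqs must be non-negative",
         call. = FALSE)
  }
  if (is.null(phenotype_given_group)) {
    phenotype_given_group <- .defaultPhenotypeGivenGroup()
  }
  if (!all(c(.GROUP_LEVELS, "D") %in% rownames(phenotype_given_group)) ||
      !identical(colnames(phenotype_given_group), .PHENO_LEVELS)) {
    stop("configuration error: phenotype_given_group needs rows ",
         "Null/A/B/C/D and columns SW/SV/NC", call. = FALSE)
  }
  if (any(abs(rowSums(phenotype_given_group) - 1) > 1e-9)) {
    stop("configuration error: each phenotype_given_group row must sum to 1",
         call. = FALSE)
  }
  ar <- utils::modifyList(list(missed_point_call = 0, phase_unavailable = 0),
                          artifact_rates)
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 allele_freqs = allele_freqs,
                 phenotype_given_group = phenotype_given_group,
                 artifact_rates = ar),
            class = "rccx_sim_config")
}

.defaultAlleleFreqs <- function() {
  cohort <- table3Cohort()
  strs <- vapply(unlist(cohort@alleles, recursive = FALSE), formatAllele,
                 character(1))
  tab <- table(strs)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

.defaultPhenotypeGivenGroup <- function() {
  ct <- crosstabGroupPhenotype(table3Cohort())
  cond <- rbind(ct / rowSums(ct),
                D = rep(1 / 3, 3))
  rownames(cond) <- c(.GROUP_LEVELS, "D")
  cond
}

#' Draw alleles from the configured frequency spectrum
#'
#' @param cfg an \code{rccx_sim_config}.
#' @param n number of alleles to draw.
#' @return a list of \code{\linkS4class{AlleleSpec}} (length \code{n}).
#'   Draws consume the current RNG stream; seed via
#'   \code{\link{generateCohort}} or \code{set.seed} for reproducibility.
#' @export
sampleAllele <- function(cfg, n = 1) {
  strs <- sample(names(cfg$allele_freqs), size = n, replace = TRUE,
                 prob = cfg$allele_freqs)
  lapply(strs, parseAllele)
}

#' Generate a synthetic cohort with paired conventional reports
#'
#' Each patient receives two independent allele draws (a Hardy-Weinberg
#' style pairing; the study gives no mating or ascertainment structure),
#' the genotype group via the milder-allele rule, a phenotype drawn from
#' the group-conditional distribution (group D: uniform, flagged in notes),
#' and a conventional report from the assay model with artifacts injected
#' at the configured rates. Fully reproducible from \code{cfg$seed}; the
#' caller's RNG state is restored on exit.
#'
#' @param cfg an \code{rccx_sim_config} from \code{\link{simConfig}}.
#' @param model a \code{\linkS4class{LocusModel}}.
#' @return a \code{\linkS4class{CahCohort}} whose \code{conv_allele*}
#'   columns hold the simulated conventional strings.
#' @examples
#' sim <- generateCohort(simConfig(n_patients = 20, seed = 7))
#' genotypeGroups(sim)[1:5]
#' @export
generateCohort <- function(cfg, model = loadLocusModel()) {
  stopifnot(inherits(cfg, "rccx_sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(cfg$seed)
  n <- cfg$n_patients
  if (n == 0L) {
    df <- data.frame(matrix(character(0), nrow = 0,
                            ncol = length(.COHORT_COLUMNS),
                            dimnames = list(NULL, .COHORT_COLUMNS)),
                     stringsAsFactors = FALSE)
    df$age_years <- numeric(0)
    return(new("CahCohort", patients = df, alleles = list()))
  }
  a1 <- sampleAllele(cfg, n)
  a2 <- sampleAllele(cfg, n)
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(44, 23) / 67)
  age <- round(stats::runif(n, 0.01, 11.5), 2)
  pheno <- character(n)
  conv1 <- character(n); conv2 <- character(n); notes <- character(n)
  for (i in seq_len(n)) {
    grp <- assignGroup(severityOfAllele(a1[[i]], model),
                       severityOfAllele(a2[[i]], model))
    pheno[i] <- sample(.PHENO_LEVELS, 1,
                       prob = cfg$phenotype_given_group[grp, ])
    note <- if (grp == "D") "group_D_phenotype:0" else ""
    rep <- simulateConventional(a1[[i]], a2[[i]], paste0("S", i), model)
    calls <- rep@calls
    for (k in 1:2) {
      spec <- if (k == 1) a1[[i]] else a2[[i]]
      pointish <- alleleCategory(spec) %in%
        c("MICROCONVERSION", "NOVEL_VARIANT")
      if (pointish &&
          stats::runif(1) < cfg$artifact_rates$missed_point_call) {
        calls[k] <- "negative"
        note <- paste(c(note[nzchar(note)],
                        paste0("missed_point_call:", k)), collapse = ";")
      }
    }
    if (stats::runif(1) < cfg$artifact_rates$phase_unavailable) {
      calls[1] <- "UNAVAILABLE"
      note <- paste(c(note[nzchar(note)], "phase_unavailable:1"),
                    collapse = ";")
    }
    conv1[i] <- calls[1]; conv2[i] <- calls[2]; notes[i] <- note
  }
  df <- data.frame(
    patient_id = paste0("S", seq_len(n)),
    sex = sex,
    age_years = age,
    phenotype = pheno,
    allele1 = vapply(a1, formatAllele, character(1)),
    allele2 = vapply(a2, formatAllele, character(1)),
    extra_copy = vapply(a1, function(s) {
      if (alleleCopies(s) > 1L) "E7E8_integration" else ""
    }, character(1)),
    conv_allele1 = conv1,
    conv_allele2 = conv2,
    notes = notes,
    stringsAsFactors = FALSE)
  # extra_copy reflects either haplotype carrying a trimodular allele
  extra2 <- vapply(a2, function(s) alleleCopies(s) > 1L, logical(1))
  df$extra_copy[extra2 & !nzchar(df$extra_copy)] <- "E7E8_integration"
  new("CahCohort", patients = df,
      alleles = mapply(function(x, y) list(x, y), a1, a2,
                       SIMPLIFY = FALSE))
}
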