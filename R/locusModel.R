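# The default locus model: sites, chimera catalogue, severity table, probe
# panel. All of it is symbolic -- junctions are typed by which landmark
# interval they fall into, so nothing here carries genomic coordinates.

.defaultSites <- function() {
  ids <- c(.GENE_SITE_IDS,
           "TNXB_E19", "TNXB_E20", "TNXB_E29", "TNXB_E31", "TNXB_E35",
           "TNXB_E40", "TNXB_E41", "TNXB_E43")
  region <- c("promoter", "exon", "exon", "intron_site", "exon",
              rep("exon", 8),
              rep("tnxb", 8))
  data.frame(site_id = ids,
             order_index = seq_along(ids),
             region = region,
             stringsAsFactors = FALSE)
}

# span_end: first site NOT pseudogene-derived (half-open span over
# order_index, always anchored at UTR5); junction: the interval the
# transition falls into. CH5/CH7/CH9 breakpoints are not pinned down by the
# junction-vs-I2G rule alone; they stay in the catalogue flagged unobserved
# and are never emitted by the classifier.
.defaultChimeras <- function() {
  ch <- function(span_end, junction, i2g, del8, observed = TRUE,
                 tnxb_signature = character(0)) {
    list(span_end = span_end, junction = junction,
         carries_I2G = i2g, carries_8bp_del = del8,
         observed = observed, tnxb_signature = tnxb_signature)
  }
  list(
    CH1 = ch("E4", c("E3", "E4"), TRUE, TRUE),
    CH2 = ch("E6", c("E5", "E6"), TRUE, TRUE),
    CH3 = ch("E8", c("E7", "E8"), TRUE, TRUE),   # junction within exon 8
    CH4 = ch("E2", c("E1", "E2"), FALSE, FALSE),
    CH5 = ch(NA_character_, c(NA_character_, NA_character_), TRUE, NA,
             observed = FALSE),
    CH6 = ch("DEL8BP_SITE", c("I2G_SITE", "DEL8BP_SITE"), TRUE, FALSE),
    CH7 = ch(NA_character_, c(NA_character_, NA_character_), TRUE, NA,
             observed = FALSE),
    CH8 = ch("E9", c("E8", "E9"), TRUE, TRUE),
    CH9 = ch(NA_character_, c(NA_character_, NA_character_), FALSE, NA,
             observed = FALSE),
    CAHX_CH1 = ch(NA_character_, c(NA_character_, NA_character_), NA, NA,
                  tnxb_signature = "TNXB_E35_120bp_del"),
    CAHX_CH2 = ch(NA_character_, c(NA_character_, NA_character_), NA, NA,
                  tnxb_signature = "TNXB_E40_C4058W"),
    CAHX_CH3 = ch(NA_character_, c(NA_character_, NA_character_), NA, NA,
                  tnxb_signature = c("TNXB_E41_R4073H", "TNXB_E43_D4172N",
                                     "TNXB_E43_S4175N")),
    DEL_SOLO = ch(NA_character_, c(NA_character_, NA_character_), NA, NA),
    DUP_E7E8 = ch(NA_character_, c(NA_character_, NA_character_), NA, NA)
  )
}

# In-vitro residual-activity tiers for the common alleles. Tokens not listed
# are unknown-effect (class D). Whole-gene deletions / I2G-carrying chimeras
# are scored structurally in severityOfAllele, not through this table.
.defaultSeverity <- function() {
  c(I2G        = "A",
    I173N      = "B",
    P31L       = "C",
    P454S      = "C",
    V282L      = "C",
    G111Vfs    = "Null",
    E6_CLUSTER = "Null",
    Q319X      = "Null",
    R357W      = "Null",
    R484Pfs    = "Null",
    L308Ffs    = "Null")
}

.defaultPseudogeneSet <- function() {
  c("I2G", "G111Vfs", "L308Ffs", "Q319X", "P31L", "I173N", "R357W",
    "E6_CLUSTER", "UTR5")
}

# Canonical token -> landmark site. Novel variants are positioned by codon
# number against the 10-exon layout.
.defaultVariantSites <- function() {
  c(UTR5       = "UTR5",
    P31L       = "E1",
    I2G        = "I2G_SITE",
    G111Vfs    = "E3",
    S126X      = "E3",
    I173N      = "E4",
    E6_CLUSTER = "E6",
    E247Gfs    = "E6",
    V282L      = "E7",
    L308Ffs    = "E7",
    V306F      = "E7",
    Q319X      = "E8",
    R355H      = "E8",
    R357W      = "E8",
    G423_C424delinsVCL = "E10",
    P454S      = "E10",
    R484Pfs    = "E10",
    R484Q      = "E10")
}

.defaultProbePanel <- function() {
  list(a2_probe_sites = c("E1", "E3", "E4", "E6", "E7", "I2G_SITE"),
       a1p_probe_count = 4L,
       tnxb_probe_sites = c("TNXB_E35", "TNXB_E19", "TNXB_E20",
                            "TNXB_E29", "TNXB_E31"),
       tnxb_probe_mult = c(TNXB_E35 = 2L, TNXB_E19 = 1L, TNXB_E20 = 1L,
                           TNXB_E29 = 1L, TNXB_E31 = 1L),
       reference_area = TRUE)
}

#' Load the RCCX locus model
#'
#' Returns the validated locus model: informative-site map, chimera
#' catalogue, severity table, pseudogene-derived token set, variant-site
#' lookup and MLPA probe panel. An optional YAML configuration can override
#' parts of the default (probe panel sites, severity entries, variant-site
#' entries); the merged model is re-validated, so a configuration that
#' breaks a structural invariant is rejected with a message naming it.
#'
#' @param config optional path to a YAML document with any of the keys
#'   \code{probe_panel} (sub-keys \code{a2_probe_sites},
#'   \code{tnxb_probe_sites}), \code{severity} (token -> class map) and
#'   \code{variant_sites} (token -> site map).
#' @return a \code{\linkS4class{LocusModel}}.
#' @examples
#' model <- loadLocusModel()
#' siteForVariant(model, "p.Q319X")
#' @export
loadLocusModel <- function(config = NULL) {
  model <- new("LocusModel",
               sites = .defaultSites(),
               chimeras = .defaultChimeras(),
               severity = .defaultSeverity(),
               pseudogeneSet = .defaultPseudogeneSet(),
               variantSites = .defaultVariantSites(),
               unknownLocation = "c.292+1G>A",
               probePanel = .defaultProbePanel())
  if (!is.null(config)) {
    if (!file.exists(config)) {
      stop("locus model configuration not found: ", config)
    }
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$probe_panel)) {
      pp <- model@probePanel
      for (k in intersect(names(cfg$probe_panel),
                          c("a2_probe_sites", "tnxb_probe_sites"))) {
        pp[[k]] <- as.character(cfg$probe_panel[[k]])
      }
      model@probePanel <- pp
    }
    if (!is.null(cfg$severity)) {
      sev <- unlist(cfg$severity)
      if (!all(sev %in% c("Null", "A", "B", "C"))) {
        stop("configuration error: severity classes must be Null, A, B or C")
      }
      model@severity[names(sev)] <- sev
    }
    if (!is.null(cfg$variant_sites)) {
      vs <- unlist(cfg$variant_sites)
      if (!all(vs %in% model@sites$site_id)) {
        stop("configuration error: variant_sites must map to declared sites")
      }
      model@variantSites[names(vs)] <- vs
    }
    ok <- validObject(model, test = TRUE)
    if (!isTRUE(ok)) stop("configuration error: ", paste(ok, collapse = "; "))
  }
  model
}

#' Serialize a locus model to YAML
#'
#' @param model a \code{\linkS4class{LocusModel}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLocusModel <- function(model, path) {
  doc <- list(
    sites = model@sites,
    severity = as.list(model@severity),
    pseudogene_set = model@pseudogeneSet,
    variant_sites = as.list(model@variantSites),
    probe_panel = model@probePanel[c("a2_probe_sites", "tnxb_probe_sites")]
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Locate the site housing a variant token
#'
#' @param model a \code{\linkS4class{LocusModel}}.
#' @param token a variant token (any accepted spelling).
#' @return one-row data.frame from the site map (site_id, order_index,
#'   region).
#' @examples
#' siteForVariant(loadLocusModel(), "I2G")
#' @export
siteForVariant <- function(model, token) {
  tk <- normalizeToken(token)
  if (tk %in% model@unknownLocation) {
    stop("variant '", token, "' is registered as location-unknown",
         call. = FALSE)
  }
  site <- model@variantSites[tk]
  if (is.na(site)) {
    stop("unknown variant token: '", token, "'", call. = FALSE)
  }
  model@sites[model@sites$site_id == site, , drop = FALSE]
}

#' @describeIn loadLocusModel ordered site map accessor
#' @param model a \code{\linkS4class{LocusModel}}.
#' @export
siteMap <- function(model) model@sites

#' @describeIn loadLocusModel chimera catalogue accessor
#' @export
chimeraCatalog <- function(model) model@chimeras

#' @describeIn loadLocusModel severity lookup table accessor
#' @export
severityTable <- function(model) model@severity

#' @describeIn loadLocusModel MLPA probe panel accessor
#' @export
probePanel <- function(model) model@probePanel

#' @describeIn loadLocusModel pseudogene-derived (microconversion) token set
#' @export
pseudogeneTokens <- function(model) model@pseudogeneSet

# site ids of the CYP21A2 region (the marker-vector domain), in order
.geneSites <- function(model) {
  s <- model@sites
  s$site_id[s$region != "tnxb"]
}

.siteIndex <- function(model, site_id) {
  match(site_id, model@sites$site_id)
}

setMethod("show", "LocusModel", function(object) {
  s <- object@sites
  obs <- sum(vapply(object@chimeras, function(x) isTRUE(x$observed),
                    logical(1)))
  cat("LocusModel: RCCX symbolic site map\n")
  cat("  ", sum(s$region != "tnxb"), "CYP21A2-region sites,",
      sum(s$region == "tnxb"), "TNXB landmarks\n")
  cat("  ", length(object@chimeras), "catalogued structures (",
      obs, "with defined junctions )\n")
  cat("  severity table:", length(object@severity), "tokens;",
      "probe panel:", length(object@probePanel$a2_probe_sites),
      "CYP21A2 +", length(object@probePanel$tnxb_probe_sites),
      "TNXB probed sites\n")
})
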