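# Shared fixtures and independent oracles.

testModel <- function() loadLocusModel()

# Brute-force junction oracle: enumerate every cut position k (first k
# sites on the pseudogene/absent side) and keep the feasible ones; the
# tightest interval runs from the site before the smallest feasible cut to
# the site at the largest feasible cut. Independent of the scan used by
# callJunction().
oracleJunction <- function(calls) {
  n <- length(calls)
  feasible <- vapply(0:n, function(k) {
    left <- if (k > 0) calls[seq_len(k)] else character(0)
    right <- if (k < n) calls[(k + 1):n] else character(0)
    all(left %in% c("PSEUDO", "ABSENT", "UNKNOWN")) &&
      all(right %in% c("GENE", "UNKNOWN"))
  }, logical(1))
  ks <- (0:n)[feasible]
  if (!length(ks)) return(NULL)  # no single-junction explanation
  kmin <- min(ks); kmax <- max(ks)
  if (kmin == 0 || kmax == n) return(list(none = TRUE))
  list(none = FALSE, left = names(calls)[kmin], right = names(calls)[kmax + 1])
}

# Random single-junction marker vector with UNKNOWN dropout noise.
randomJunctionVector <- function(model, p_unknown = 0.15) {
  sites <- siteMap(model)$site_id[siteMap(model)$region != "tnxb"]
  n <- length(sites)
  cut <- sample(1:(n - 1), 1)  # at least one pseudo and one gene call
  calls <- c(rep("PSEUDO", cut), rep("GENE", n - cut))
  mask <- runif(n) < p_unknown
  # never mask every informative call on either side
  if (all(mask[seq_len(cut)])) mask[sample(seq_len(cut), 1)] <- FALSE
  if (all(mask[(cut + 1):n])) mask[cut + sample(seq_len(n - cut), 1)] <- FALSE
  calls[mask] <- "UNKNOWN"
  names(calls) <- sites
  calls
}

# Mid-rank Spearman oracle via base R, kept separate from the package's
# from-scratch implementation.
oracleSpearman <- function(x, y) stats::cor(rank(x), rank(y))

# Genotype-group column as printed in the study's per-patient table.
table3ExpectedGroups <- function() {
  c("A", "D", "Null", "Null", "A", "D", "B", "C", "Null", "A",
    "A", "C", "B", "C", "A", "A", "A", "A", "A", "B",
    "B", "Null", "D", "B", "B", "D", "B", "C", "Null", "D",
    "B", "Null", "B", "D", "D", "B", "B", "D", "B", "A",
    "D", "B", "A", "B", "C", "C", "Null", "A", "A", "B",
    "Null", "D", "A", "A", "Null", "Null", "A", "Null", "Null", "B",
    "C", "C", "B", "A", "D", "A", "A")
}
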