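# Builders for small in-code fixtures.

# CleanSeries straight from a counts matrix (all days valid, full wear).
cleanFromCounts <- function(counts, wear = NULL, id = "T1") {
  if (is.vector(counts))
    counts <- matrix(counts, ncol = 1440, byrow = TRUE)
  if (is.null(wear)) wear <- matrix(TRUE, nrow(counts), ncol(counts))
  new("CleanSeries", subjectId = id, counts = counts, wear = wear,
      nValid = nrow(counts))
}

# A day vector of zeros with specified nonzero positions.
dayWithRuns <- function(zeroRuns, fill = 500) {
  x <- rep(fill, 1440)
  for (r in zeroRuns) x[r] <- 0
  x
}

# Exhaustive bout-enumeration oracle for ASTP/SATP on a binary sequence
# (TRUE = active), full wear: transition counts over adjacent pairs.
fragOracle <- function(states) {
  n <- length(states)
  as_ <- sum(states[-n] & !states[-1])
  sa <- sum(!states[-n] & states[-1])
  c(SATP = if (sum(!states) > 0) sa / sum(!states) else NA_real_,
    ASTP = if (sum(states) > 0) as_ / sum(states) else NA_real_)
}

# Brute-force M10/L5: evaluate every circular window directly.
windowOracle <- function(profile, width, what = c("max", "min")) {
  what <- match.arg(what)
  n <- length(profile)
  means <- vapply(seq_len(n), function(s) {
    idx <- ((s - 1) + 0:(width - 1)) %% n + 1
    mean(profile[idx])
  }, numeric(1))
  if (what == "max") max(means) else min(means)
}

groupContrastForTest <- function(rec) ifelse(rec$group == "PMS", 1L, 0L)

# Small synthetic covariate table for association tests.
makeRecords <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("RRMS-Stable", "RRMS-Suspected", "PMS"), length.out = n),
    age = rnorm(n, 55, 8), sex = sample(c("female", "male"), n, TRUE),
    bmi = rnorm(n, 28, 5),
    ipaq_met_min = rlnorm(n, 7, 0.5),
    stringsAsFactors = FALSE)
}

## constructed two-block data with known joint / individual subspaces
makeJiveData <- function(n = 250, p1 = 20, p2 = 15, noise = 0.1,
                         seed = 1) {
  set.seed(seed)
  ## subject score vectors: mutually orthogonal, centered (orthogonal to
  ## the constant vector, since features are centered downstream), with
  ## unit-RMS entries so per-feature signal dominates the noise
  orth <- function(v, basis) {
    for (b in basis) v <- v - sum(v * b) * b
    v / sqrt(sum(v^2))
  }
  one <- rep(1, n) / sqrt(n)
  vJ <- orth(rnorm(n), list(one))
  v1 <- orth(rnorm(n), list(one, vJ))
  v2 <- orth(rnorm(n), list(one, vJ, v1))
  sJ <- vJ * sqrt(n); s1 <- v1 * sqrt(n); s2 <- v2 * sqrt(n)
  X1 <- outer(rnorm(p1, 0, 3), sJ) + outer(rnorm(p1, 0, 2), s1) +
    matrix(rnorm(p1 * n, 0, noise), p1, n)
  X2 <- outer(rnorm(p2, 0, 3), sJ) + outer(rnorm(p2, 0, 2), s2) +
    matrix(rnorm(p2 * n, 0, noise), p2, n)
  b1 <- featureBlock(t(X1), "PA")
  b2 <- featureBlock(t(X2), "CR")
  list(blocks = list(b1, b2), vJ = vJ, v1 = v1, v2 = v2)
}

principalAngleDeg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}
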