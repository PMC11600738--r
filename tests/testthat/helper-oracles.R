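# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation (enumeration / closed form), kept free of any package
# code path it checks.

options(bandscape.log_level = "warn")

# Brute-force band-status rule: uniform non-missing -> mapped label,
# mixed -> ambiguous, empty -> missing.
band_status_oracle <- function(v) {
  lab <- c(`-2` = "deep_loss", `-1` = "loss", `0` = "neutral",
           `1` = "gain", `2` = "amplification")
  v <- v[!is.na(v)]
  if (length(v) == 0) return("missing")
  if (length(unique(v)) > 1) return("ambiguous")
  lab[[as.character(v[1])]]
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (probability-ordering definition, with the
# standard relative tolerance for ties).
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + b          # anchor-positive margin
  n2 <- c_ + d
  k <- a + c_         # feature-positive margin
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# BH step-up by direct definition: q_i = min over j >= rank(i) of
# m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Product-limit by hand for tiny inputs.
km_oracle <- function(times, events) {
  s <- 1
  out <- numeric(0)
  for (t in sort(unique(times))) {
    n <- sum(times >= t)
    d <- sum(times == t & events == 1)
    if (d > 0) s <- s * (1 - d / n)
    out <- c(out, s)
  }
  out
}

# Small genome shared by several tests: 2 chromosomes ("1" and "13"),
# 4 bands each, so the anchor band 13q14.2 exists.
small_cfg <- function(seed = 1, n_samples = 100, ...) {
  sim_config(seed = seed, n_samples = n_samples, n_chroms = 2,
             bands_per_chrom = 4, genes_per_band = 5, ...)
}

toy_annotation <- function() {
  bands <- data.frame(
    chrom = c("1", "1", "13"),
    start = c(0L, 150L, 0L),
    end = c(150L, 300L, 400L),
    band_name = c("1q11.1", "1q12.1", "13q14.2"),
    stain = "gneg", stringsAsFactors = FALSE)
  genes <- data.frame(
    gene_id = c("GA", "GB", "GC", "GM"),
    chrom = c("1", "1", "13", "M"),
    start = c(100L, 10L, 50L, 0L),
    end = c(200L, 40L, 350L, 10L), stringsAsFactors = FALSE)
  genome_annotation(genes, bands)
}
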