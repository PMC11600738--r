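assoc_from_counts_public <- function(a, b, c_, d) {
  anchor <- rep(c(1, 1, 0, 0), c(a, b, c_, d))
  feature <- rep(c(1, 0, 1, 0), c(a, b, c_, d))
  fisher_association(anchor, feature)
}

test_that("binary anchor keeps loss and neutral, excludes the rest", {
  st <- c(S1 = "loss", S2 = "deep_loss", S3 = "neutral", S4 = "gain")
  a <- binary_anchor(st)
  expect_identical(as.integer(a), c(1L, 1L, 0L))
  expect_identical(names(a), c("S1", "S2", "S3"))
  expect_identical(attr(a, "excluded"), "S4")
  expect_error(binary_anchor(c(S1 = "neutral", S2 = "neutral")),
               "degenerate anchor")
  expect_error(binary_anchor(c(S1 = "ambiguous", S2 = "ambiguous")),
               "degenerate anchor")
})

test_that("fisher association reproduces enumerable examples", {
  # (3,0,0,3): two of the C(6,3) = 20 equiprobable tables are as extreme
  r <- fisher_association(rep(c(1, 0), each = 3), rep(c(1, 0), each = 3))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_gt(r$direction, 0)
  expect_identical(r$call, "not_significant")  # 0.1 > alpha

  # perfectly balanced table: OR 1, direction 0, score 0
  r2 <- assoc_from_counts_public(10, 10, 10, 10)
  expect_equal(r2$odds_ratio, 1)
  expect_identical(r2$direction, 0)
  expect_identical(r2$score, 0)

  # Haldane-Anscombe correction on a zero cell
  r3 <- assoc_from_counts_public(10, 0, 10, 10)
  expect_equal(r3$odds_ratio, 21, tolerance = 1e-12)
  expect_equal(r3$direction, log2(21), tolerance = 1e-12)

  expect_error(fisher_association(c(0, 1), c(0, 1, 1)), "length")
})

test_that("fisher p equals hypergeometric enumeration for tables with n <= 40", {
  set.seed(7)
  for (i in 1:250) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    r <- assoc_from_counts_public(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$p_value,
                 fisher_p_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("swapping anchor labels flips direction and score, keeps p", {
  set.seed(8)
  for (i in 1:25) {
    anchor <- rbinom(60, 1, 0.5)
    feature <- rbinom(60, 1, 0.4)
    if (length(unique(anchor)) < 2 || length(unique(feature)) < 2) next
    r <- fisher_association(anchor, feature)
    rs <- fisher_association(1 - anchor, feature)
    expect_equal(rs$p_value, r$p_value, tolerance = 1e-12)
    expect_equal(rs$direction, -r$direction, tolerance = 1e-9)
    expect_equal(rs$score, -r$score, tolerance = 1e-9)
  }
})

test_that("feature screen drops low-prevalence features and ranks by |score|", {
  set.seed(9)
  n <- 300
  anchor <- stats::setNames(rbinom(n, 1, 0.5), sprintf("S%03d", 1:n))
  rare <- rbinom(n, 1, 0.01)
  rare[1:2] <- 1  # ~1% prevalence, below the 2% rule
  feats <- cbind(RARE = rare, COMMON = rbinom(n, 1, 0.3))
  rownames(feats) <- names(anchor)
  res <- screen_features(anchor, feats)
  expect_false("RARE" %in% res$feature_id)
  expect_true("COMMON" %in% res$feature_id)
  expect_true(all(diff(abs(res$score)) <= 1e-12))

  expect_warning(screen_features(anchor, feats, min_prevalence = 0.99),
                 "prevalence")
})

test_that("planted associations are recovered with the right call and sign", {
  cfg <- small_cfg(seed = 31, n_samples = 800, n_null_features = 5)
  sim <- simulate_cn_profiles(cfg)
  mut <- simulate_mutations(cfg, sim$truth$anchor)
  st <- band_status_table(sim$cn, sim$annotation)
  anchor <- binary_anchor(st[cfg$anchor_band, ])
  res <- screen_features(anchor, mut$features)
  tp53 <- res[res$feature_id == "TP53", ]
  pik <- res[res$feature_id == "PIK3CA", ]
  expect_identical(tp53$call, "co_occurring")
  expect_gt(tp53$score, 0)
  expect_identical(pik$call, "mutually_exclusive")
  expect_lt(pik$score, 0)
})

test_that("cross-cohort consistency keeps only same-signed significant calls", {
  ra <- data.frame(feature_id = c("A", "B", "C"),
                   call = c("co_occurring", "co_occurring",
                            "mutually_exclusive"),
                   score = c(5, 4, -3), stringsAsFactors = FALSE)
  rb <- data.frame(feature_id = c("A", "B", "C"),
                   call = c("co_occurring", "not_significant",
                            "mutually_exclusive"),
                   score = c(6, 0.5, -2), stringsAsFactors = FALSE)
  cons <- cross_cohort_consistency(ra, rb)
  expect_setequal(cons$feature_id, c("A", "C"))
  expect_warning(
    empty <- cross_cohort_consistency(
      ra, data.frame(feature_id = "Z", call = "co_occurring", score = 1)),
    "no shared")
  expect_identical(nrow(empty), 0L)
})

test_that("stratified screen recovers opposite planted effects per stratum", {
  set.seed(10)
  n <- 600
  ids <- sprintf("S%03d", 1:n)
  grp <- rep(c("LumA", "Basal"), each = n / 2)
  anchor <- stats::setNames(rbinom(n, 1, 0.5), ids)
  # co-occurring in LumA, mutually exclusive in Basal
  p_feat <- ifelse(grp == "LumA",
                   ifelse(anchor == 1, 0.6, 0.2),
                   ifelse(anchor == 1, 0.2, 0.6))
  feats <- matrix(rbinom(n, 1, p_feat), ncol = 1,
                  dimnames = list(ids, "FLIP"))
  clinical <- data.frame(sample_id = ids, pam50 = grp,
                         stringsAsFactors = FALSE)
  out <- stratified_screen(anchor, feats, clinical, "pam50")
  expect_identical(out$results$LumA$call, "co_occurring")
  expect_identical(out$results$Basal$call, "mutually_exclusive")

  # a stratum with a one-class anchor is untestable, not an error
  clinical2 <- clinical
  anchor2 <- anchor
  anchor2[clinical2$pam50 == "Basal"] <- 0L
  out2 <- stratified_screen(anchor2, feats, clinical2, "pam50")
  expect_identical(out2$untestable, "Basal")

  # a single level equals the unstratified screen
  clinical3 <- clinical; clinical3$pam50 <- "all"
  out3 <- stratified_screen(anchor, feats, clinical3, "pam50")
  expect_equal(out3$results$all, screen_features(anchor, feats))
})
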