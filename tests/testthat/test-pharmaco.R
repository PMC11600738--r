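test_that("Glass' delta matches its definition on enumerable inputs", {
  g <- glass_delta(c(-3, -2, -1), c(0, 1, 2))
  expect_equal(g$mean_diff, -3)
  expect_equal(g$delta_pos, 3)
  expect_equal(g$delta_neg, 3)
  same <- glass_delta(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$delta_pos, 0)
  const <- glass_delta(c(2, 2, 2), c(0, 1, 2))
  expect_true(const$untestable)
})

test_that("effect sizes match brute-force formula evaluations to 1e-12", {
  set.seed(17)
  for (i in 1:30) {
    pos <- rnorm(sample(5:30, 1)); neg <- rnorm(sample(5:30, 1))
    g <- glass_delta(pos, neg)
    md <- sum(pos) / length(pos) - sum(neg) / length(neg)
    expect_equal(g$mean_diff, md, tolerance = 1e-12)
    expect_equal(g$delta_pos,
                 abs(md) / sqrt(sum((pos - mean(pos))^2) / (length(pos) - 1)),
                 tolerance = 1e-12)
    ind <- c(rep(1, length(pos)), rep(0, length(neg)))
    v <- c(pos, neg)
    pb <- point_biserial(ind, v)
    r_brute <- sum((ind - mean(ind)) * (v - mean(v))) /
      sqrt(sum((ind - mean(ind))^2) * sum((v - mean(v))^2))
    expect_equal(pb$r, r_brute, tolerance = 1e-12)
  }
})

test_that("point-biserial r, CI and magnitude labels follow the boundaries", {
  pb <- point_biserial(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(round(pb$r, 3), 0.894)
  expect_identical(pb$magnitude, "large")
  expect_true(pb$ci_low < pb$r && pb$r < pb$ci_high)
  expect_identical(bandscape:::r_magnitude(0.30), "medium")
  expect_identical(bandscape:::r_magnitude(0.05), "negligible")
  expect_identical(bandscape:::r_magnitude(-0.15), "small")
  expect_identical(bandscape:::r_magnitude(0.37), "large")
  # n = 3: r defined, CI not
  pb3 <- point_biserial(c(0, 1, 1), c(1, 2, 3))
  expect_false(is.na(pb3$r))
  expect_true(is.na(pb3$ci_low))
})

test_that("null point-biserial r concentrates near zero", {
  set.seed(18)
  ok <- 0L
  for (i in 1:100) {
    ind <- rbinom(1000, 1, 0.5)
    v <- rnorm(1000)
    if (abs(point_biserial(ind, v)$r) < 0.08) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("Mann-Whitney wrapper is exact when small and symmetric one-sided", {
  expect_equal(mw_group_test(c(1, 2, 3), c(4, 5, 6)), 0.1,
               tolerance = 1e-12)
  expect_equal(mw_group_test(2, 2), 1)
  p2 <- mw_group_test(c(1, 2, 3), c(4, 5, 6), "two_sided")
  p1 <- mw_group_test(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(p1, p2 / 2, tolerance = 1e-12)
})

test_that("elastic net recovers a planted effect and handles degeneracies", {
  set.seed(19)
  cl <- sprintf("CL%02d", 1:40)
  x <- matrix(rbinom(40, 1, 0.5), 40, 1, dimnames = list(cl, "anchor"))
  y <- stats::setNames(-2 * x[, 1] + rnorm(40, 0, 0.1), cl)
  coefs <- elastic_net_screen(y, x)
  expect_lt(coefs["anchor"], 0)
  expect_true(abs(coefs["anchor"]) >= 1 && abs(coefs["anchor"]) <= 2)

  # duplicated predictors: coefficients split, fitted values unchanged
  # (the split identity is exact for the lasso limit of the penalty; the
  # ridge component redistributes shrinkage across the duplicates)
  x2 <- cbind(a1 = x[, 1], a2 = x[, 1])
  rownames(x2) <- cl
  set.seed(20); c1 <- elastic_net_screen(y, x2, mixing = 1)
  set.seed(20); c0 <- elastic_net_screen(y, x, mixing = 1)
  fit1 <- x2 %*% c1
  fit0 <- x %*% c0
  expect_equal(as.vector(fit1), as.vector(fit0), tolerance = 1e-6)

  expect_warning(z <- elastic_net_screen(stats::setNames(rep(1, 40), cl), x),
                 "constant response")
  expect_true(all(z == 0))
})

make_screen <- function(seed, effect = 0, n_cl = 50, n_drugs = 60,
                        planted = 5) {
  set.seed(seed)
  cl <- sprintf("CL%03d", seq_len(n_cl))
  anchor <- rep(c(1L, 0L), length.out = n_cl)
  drugs <- sprintf("D%03d", seq_len(n_drugs))
  recs <- do.call(rbind, lapply(seq_along(drugs), function(i) {
    eff <- if (i <= planted) effect * anchor else 0
    data.frame(cell_line = cl, drug = drugs[i], screen = "screen1",
               log10_ic50 = rnorm(1) + eff + rnorm(n_cl),
               stringsAsFactors = FALSE)
  }))
  list(responses = recs,
       features = matrix(anchor, ncol = 1,
                         dimnames = list(cl, "anchor_loss")),
       planted = drugs[seq_len(planted)])
}

test_that("interaction screen recovers planted sensitivity hits", {
  sc <- make_screen(21, effect = -2)
  hits <- interaction_screen(sc$responses, sc$features)
  found <- hits$drug[hits$hit]
  expect_gte(length(intersect(found, sc$planted)), 4L)
  expect_true(all(hits$direction[hits$hit] == "sensitivity"))
  # untestable when a genotype class is too small
  few <- sc$features; few[, 1] <- 0L; few[1:2, 1] <- 1L
  h2 <- interaction_screen(sc$responses, few)
  expect_true(all(h2$untestable))
  expect_false(any(h2$hit))
  expect_error(interaction_screen(sc$responses, NULL), "empty feature")
})

test_that("negating responses mirrors every effect and keeps p values", {
  sc <- make_screen(22, effect = -2)
  h1 <- interaction_screen(sc$responses, sc$features)
  neg <- sc$responses
  neg$log10_ic50 <- -neg$log10_ic50
  h2 <- interaction_screen(neg, sc$features)
  key <- paste(h1$drug, h1$screen_id)
  h2 <- h2[match(key, paste(h2$drug, h2$screen_id)), ]
  expect_equal(h2$mean_diff, -h1$mean_diff, tolerance = 1e-12)
  expect_equal(h2$r_pb, -h1$r_pb, tolerance = 1e-12)
  expect_equal(h2$mw_p, h1$mw_p, tolerance = 1e-12)
  expect_equal(h2$q, h1$q, tolerance = 1e-12)
  swapped <- c(sensitivity = "resistance", resistance = "sensitivity")
  expect_identical(h2$direction, unname(swapped[h1$direction]))
})

test_that("anchor screen keeps per-screen records for duplicated drugs", {
  set.seed(23)
  cl <- sprintf("CL%03d", 1:40)
  anchor <- stats::setNames(rep(c(1L, 0L), 20), cl)
  recs <- do.call(rbind, lapply(c("screen1", "screen2"), function(s)
    data.frame(cell_line = cl, drug = "VEN", screen = s,
               log10_ic50 = -2 * anchor + rnorm(40, 0, 0.5),
               stringsAsFactors = FALSE)))
  res <- anchor_screen(recs, anchor)
  expect_identical(nrow(res), 2L)
  expect_setequal(res$screen_id, c("screen1", "screen2"))
  expect_true(all(res$hit))
  expect_error(anchor_screen(recs, stats::setNames(rep(1L, 40), cl)),
               "constant")
})

test_that("xenograft response comparison uses the two-group machinery", {
  set.seed(24)
  v <- stats::setNames(c(rnorm(6, 0.3, 0.05), rnorm(6, 0.6, 0.05)),
                       sprintf("PDX%02d", 1:12))
  anchor <- stats::setNames(rep(c(1L, 0L), each = 6), names(v))
  res <- pdx_response_test(v, anchor)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$mean_diff, 0)
  expect_identical(res$magnitude, "large")
})
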