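random_score_table <- function(n_aligners = 4, n_alpha = 5, n_pairs = 3,
                               metrics = c("s3", "kp"), miss = 0) {
  grid <- expand.grid(aligner = sprintf("A%d", seq_len(n_aligners)),
                      alpha = seq(0, 1, length.out = n_alpha),
                      pair = sprintf("P%d", seq_len(n_pairs)),
                      stringsAsFactors = FALSE)
  for (m in metrics) {
    v <- stats::runif(nrow(grid))
    if (miss > 0) v[sample.int(length(v), round(miss * length(v)))] <- NA
    grid[[m]] <- v
  }
  score_table(grid)
}

test_that("best_mean_score picks the alpha maximizing the cross-pair mean, smallest alpha on ties", {
  tbl <- score_table(data.frame(
    aligner = "A", alpha = c(0, 0, 0.5, 0.5, 1, 1),
    pair = rep(c("P1", "P2"), 3),
    s3 = c(0.2, 0.4, 0.6, 0.4, 0.7, 0.3)))
  got <- best_mean_score(tbl, "A", "s3")
  expect_equal(got$alpha, 0.5)
  expect_equal(got$mean, 0.5)
  # tie between alpha 0.5 (0.5) and a duplicate mean at alpha 1 -> smaller alpha
  tie <- score_table(data.frame(aligner = "A", alpha = c(0.2, 0.8),
                                pair = "P1", s3 = c(0.5, 0.5)))
  expect_equal(best_mean_score(tie, "A", "s3")$alpha, 0.2)

  single <- score_table(data.frame(aligner = "A", alpha = 0, pair = "P1", s3 = 0.3))
  expect_equal(best_mean_score(single, "A", "s3"), list(alpha = 0, mean = 0.3))
  expect_error(best_mean_score(single, "A", "missing_metric"))
})

test_that("best_mean_score matches exhaustive search on randomized tables", {
  set.seed(71)
  for (rep in 1:15) {
    tbl <- random_score_table(n_aligners = 5, n_alpha = 11, n_pairs = 4,
                              miss = 0.1)
    a <- sample(unique(tbl$aligner), 1L)
    got <- best_mean_score(tbl, a, "s3")
    rows <- tbl[tbl$aligner == a & !is.na(tbl$s3), ]
    means <- sapply(sort(unique(rows$alpha)), function(al)
      mean(rows$s3[rows$alpha == al]))
    expect_equal(got$mean, max(means), tolerance = 1e-12)
    expect_equal(got$alpha, sort(unique(rows$alpha))[which.max(means)])
  }
})

test_that("the trade-off score is the geometric mean of S3 and KP", {
  expect_equal(tradeoff_score(0.25, 0.49), 0.35)
  expect_equal(tradeoff_score(0.4, 0.4), 0.4)
  expect_equal(tradeoff_score(0, 0.9), 0)
  expect_true(is.na(tradeoff_score(NA, 0.5)))
  set.seed(72)
  s3 <- stats::runif(50); kp <- stats::runif(50)
  tr <- tradeoff_score(s3, kp)
  expect_true(all(tr <= pmax(s3, kp) + 1e-12 & tr >= pmin(s3, kp) - 1e-12))
})

test_that("competition ranking gives ties the minimal rank and skips after them", {
  expect_equal(competition_rank(c(1, 1, 1, 0.994, 0.952, 0.923)),
               c(1L, 1L, 1L, 4L, 5L, 6L))
  expect_equal(competition_rank(c(0.2, 0.8, 0.5)), c(3L, 1L, 2L))
  expect_equal(competition_rank(rep(0.5, 4)), rep(1L, 4))
  expect_equal(competition_rank(c(0.9, NA, 0.1)), c(1L, NA, 2L))
  set.seed(73)
  for (rep in 1:30) {
    x <- sample(stats::runif(6), 10L, replace = TRUE)
    r <- competition_rank(x)
    expect_equal(r, vapply(x, function(v) 1L + sum(x > v), integer(1L)))
  }
})

test_that("rank aggregation averages per-metric ranks and sorts the table", {
  ranks <- rbind(A = c(s3 = 1, kp = 2, nc = 3),
                 B = c(s3 = 2, kp = 1, nc = 1),
                 C = c(s3 = 3, kp = 3, nc = 2))
  rt <- aggregate_ranks(ranks)
  expect_equal(rt$avg_s3_kp, c(1.5, 1.5, 3))
  expect_equal(rt$avg_all[rt$aligner == "C"], 8 / 3)
  # tie on avg_s3_kp broken by avg_all: B (4/3) before A (2)
  expect_equal(rt$aligner, c("B", "A", "C"))
  expect_equal(aggregate_ranks(ranks, sort_by = "avg_all")$aligner,
               c("B", "A", "C"))
})

test_that("rank_aligners handles perfect ties and missing metrics", {
  best <- rbind(A = c(s3 = 0.5, kp = 0.5), B = c(s3 = 0.5, kp = 0.5))
  rt <- rank_aligners(best)
  expect_true(all(rt$avg_all == 1) && all(rt$avg_s3_kp == 1))

  holes <- rbind(A = c(s3 = 0.9, kp = NA), B = c(s3 = 0.5, kp = 0.7))
  expect_warning(rt2 <- rank_aligners(holes), "missing")
  expect_true(is.na(rt2[rt2$aligner == "A", "kp"]))
  expect_equal(rt2[rt2$aligner == "A", "s3"], 1L)
})

test_that("score correlations match the closed-form Pearson formula", {
  set.seed(74)
  for (rep in 1:10) {
    tbl <- random_score_table(n_aligners = 4, n_alpha = 5, n_pairs = 1,
                              metrics = c("s3", "kp", "ec"))
    cc <- score_correlation(tbl)
    expect_equal(diag(cc), c(s3 = 1, kp = 1, ec = 1))
    expect_equal(cc, t(cc))
    x <- tbl$s3; y <- tbl$kp
    hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cc["s3", "kp"], hand, tolerance = 1e-12)
  }
  # exact anti-correlation
  tbl <- score_table(data.frame(aligner = "A", alpha = seq(0, 1, 0.25),
                                pair = "P", s3 = seq(0.1, 0.5, 0.1),
                                kp = seq(0.5, 0.1, -0.1)))
  expect_equal(score_correlation(tbl)["s3", "kp"], -1)
  # zero variance is flagged
  flat <- score_table(data.frame(aligner = "A", alpha = seq(0, 1, 0.25),
                                 pair = "P", s3 = 0.5,
                                 kp = seq(0.1, 0.5, 0.1)))
  expect_warning(cc2 <- score_correlation(flat), "zero-variance")
  expect_true(is.na(cc2["s3", "kp"]))
})

test_that("score_table validation rejects out-of-range values and duplicate keys", {
  expect_error(score_table(data.frame(aligner = "A", alpha = 0, pair = "P",
                                      s3 = 1.2)), "\\[0, 1\\]")
  expect_error(score_table(data.frame(aligner = c("A", "A"), alpha = 0,
                                      pair = "P", s3 = 0.5)), "identify")
})
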