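# Brute-force tau-b over all pairs, with tie normalization.
taub_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

test_that("rank-sum: exact enumeration on small groups, approximation on large", {
  # most extreme ranking of 3 vs 3: two-sided p = 2 / C(6,3) = 0.1
  r <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                      test = "rank_sum")
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$test, "rank_sum_exact")
  expect_equal(r$direction, 1)

  # independent oracle: wilcox.test's exact p on tie-free draws
  for (s in 1:10) {
    x <- withr::with_seed(s, rnorm(7))
    y <- withr::with_seed(100 + s, rnorm(9) + 0.5)
    ours <- compare_groups(c(x, y), rep(c("x", "y"), c(7, 9)), "rank_sum")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }

  # exact and approximate routes agree closely at the cutover size
  diffs <- vapply(1:25, function(s) {
    x <- withr::with_seed(200 + s, rnorm(10))
    y <- withr::with_seed(300 + s, rnorm(10) + 0.8)
    exact <- compare_groups(c(x, y), rep(c("x", "y"), each = 10),
                            "rank_sum")$p_value
    approx <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    abs(exact - approx)
  }, numeric(1))
  expect_lt(max(diffs), 0.02)
})

test_that("signed-rank pairs by patient and handles degenerate pairs", {
  sc <- c(1, 2, 3, 1.5, 2.5, 4)
  lab <- rep(c("pre", "day90"), each = 3)
  pid <- rep(c("p1", "p2", "p3"), 2)
  r <- compare_groups(sc, factor(lab, levels = c("pre", "day90")),
                      "signed_rank", patient_id = pid)
  expect_equal(r$direction, 1)   # day90 larger
  expect_lt(r$p_value, 1)

  expect_warning(
    r0 <- compare_groups(c(1, 2, 1, 2), factor(rep(c("a", "b"), each = 2)),
                         "signed_rank", patient_id = c("p1", "p2", "p1", "p2")),
    "zero")
  expect_equal(r0$p_value, 1)

  expect_error(
    compare_groups(sc, lab, "signed_rank",
                   patient_id = c("p1", "p2", "p3", "p1", "p2", "p9")),
    "p3")
})

test_that("one-way ANOVA degenerates gracefully on identical groups", {
  r <- compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3), "anova")
  expect_lt(r$statistic, 1e-12)
  expect_gt(r$p_value, 0.99)
})

test_that("Kendall trend matches perfect orders and the brute-force oracle", {
  cats <- factor(c("absent", "mild", "moderate", "severe"),
                 levels = c("absent", "mild", "moderate", "severe"),
                 ordered = TRUE)
  expect_equal(ordinal_trend(c(1, 2, 3, 4), cats)$statistic, 1)
  expect_equal(ordinal_trend(c(4, 3, 2, 1), cats)$statistic, -1)

  # tied 6-point example against O(n^2) pair counting
  x <- c(1.0, 2.0, 2.0, 3.0, 3.5, 0.5)
  y <- c(1, 1, 2, 2, 3, 1)
  lev <- c("absent", "mild", "moderate")
  r <- ordinal_trend(x, factor(lev[y], levels = lev, ordered = TRUE))
  expect_equal(r$statistic, taub_bruteforce(x, y), tolerance = 1e-9)
})

test_that("Pearson correlation matches hand covariance arithmetic", {
  expect_equal(correlate(1:5, 2 * (1:5) + 1)$statistic, 1)
  expect_equal(correlate(1:5, -(1:5))$statistic, -1)
  x <- c(1, 2, 4, 5, 8)
  y <- c(2, 1, 5, 4, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y)$statistic, r_hand, tolerance = 1e-12)
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("quartile stratification takes strictly the upper tail", {
  g <- quartile_stratify(1:8)          # 75th percentile (type 7) = 6.25
  expect_equal(as.character(g), c(rep("low", 6), "high", "high"))
  expect_warning(g2 <- quartile_stratify(rep(5, 6)), "low")
  expect_true(all(g2 == "low"))
  g3 <- quartile_stratify(c(1, 1, 1, 1, 10))
  expect_equal(sum(g3 == "high"), 1L)
  expect_error(quartile_stratify(1:3), ">= 4")
})

test_that("log-rank matches the hand-worked 6-subject table", {
  paths <- generate_toy_fixtures()
  surv <- read.delim(paths[["survival"]])
  sr <- km_logrank(surv$time, surv$event, surv$group)

  # explicit O-E/V table: event times 1(A),2(B),3(A),4(B),6(B); 5 censored A
  # t=1: risk 3A/3B, E_A = 3/6,   V = (3/6)(3/6)(5/5) = 0.25
  # t=2: risk 2A/3B, E_A = 2/5,   V = (2/5)(3/5)(4/4) = 0.24
  # t=3: risk 2A/2B, E_A = 2/4,   V = 0.25
  # t=4: risk 1A/2B, E_A = 1/3,   V = (1/3)(2/3) = 2/9
  # t=6: risk 0A/1B, E_A = 0,     V = 0
  O_A <- 2
  E_A <- 0.5 + 0.4 + 0.5 + 1 / 3
  V <- 0.25 + 0.24 + 0.25 + 2 / 9
  expect_equal(sr$statistic, (O_A - E_A)^2 / V, tolerance = 1e-9)
  expect_equal(sr$p_value, pchisq((O_A - E_A)^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # invariant to swapping the group labels
  sr2 <- km_logrank(surv$time, surv$event, ifelse(surv$group == "A", "B", "A"))
  expect_equal(sr2$statistic, sr$statistic, tolerance = 1e-12)
})

test_that("KM curves are proper and equal the empirical survival w/o censoring", {
  t_ <- c(1, 2, 2, 3, 5, 5, 7, 9)
  sr <- km_logrank(c(t_, t_ + 0.5), rep(1, 16), rep(c("A", "B"), each = 8))
  a <- sr$curves[sr$curves$group == "A", ]
  expect_true(all(diff(a$surv) <= 1e-12))
  expect_true(all(diff(a$n_risk) <= 0))
  ecdf_surv <- 1 - ecdf(t_)(a$time)
  expect_equal(a$surv, ecdf_surv, tolerance = 1e-12)

  # identical groups: statistic 0, p 1
  sr0 <- km_logrank(c(t_, t_), rep(1, 16), rep(c("A", "B"), each = 8))
  expect_lt(sr0$statistic, 1e-12)
  expect_equal(sr0$p_value, 1, tolerance = 1e-9)

  # extreme separation is significant even at n = 20
  sr1 <- km_logrank(c(1:10, 101:110), rep(1, 20), rep(c("A", "B"), each = 10))
  expect_lt(sr1$p_value, 0.01)

  expect_warning(km_logrank(c(t_, t_), c(rep(1, 8), rep(0, 8)),
                            rep(c("A", "B"), each = 8)), "zero events")
})

test_that("association suite recovers every planted direction on defaults", {
  d <- default_cohort()
  suite <- suppressWarnings(suppressMessages(
    run_association_suite(d$scores, d$cohort$annotations)))
  rep_ <- suite$report
  sig4 <- c("Bcell", "CTL", "Th1", "Th2")

  er <- rep_[rep_$analysis == "er_status_ranksum" & rep_$signature %in% sig4, ]
  expect_equal(nrow(er), 4L)
  expect_true(all(er$direction > 0))          # ER- group scores higher
  expect_true(all(er$p_value < 0.05))

  co <- rep_[rep_$analysis == "er_activity_pearson" & rep_$signature == "total", ]
  expect_true(co$direction < 0 && co$p_value < 0.05)

  ca <- rep_[rep_$analysis == "caai_ranksum" & rep_$stratum == "all" &
               rep_$signature == "total", ]
  expect_true(ca$direction < 0 && ca$p_value < 0.05)

  tr <- rep_[rep_$analysis == "paired_treatment_signed_rank" &
               rep_$signature %in% sig4, ]
  expect_true(all(tr$direction > 0))
  expect_true(all(tr$p_value < 0.05))

  kd <- rep_[rep_$analysis == "infiltration_trend_kendall" &
               rep_$signature %in% sig4, ]
  expect_true(all(kd$statistic > 0) && all(kd$p_value < 0.05))

  sub <- rep_[rep_$analysis == "subtype_luminal_vs_nonluminal" &
                rep_$signature == "total", ]
  expect_true(sub$direction > 0 && sub$p_value < 0.05)
})

test_that("suite skips analyses whose annotation columns are missing", {
  d <- default_cohort()
  ann <- as.data.frame(d$cohort$annotations)
  ann$caai_status <- NULL
  ann$subtype <- NULL
  expect_message(
    suite <- suppressWarnings(
      run_association_suite(d$scores, cohort_annotation(ann))),
    "skipped")
  expect_false("caai_ranksum" %in% suite$report$analysis)
  expect_true("er_status_ranksum" %in% suite$report$analysis)
})
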