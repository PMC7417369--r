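# Frequencies, F-measure benchmarking, group tests, multiple testing, loess.

test_that("population frequencies count against nested denominators", {
  labels <- c(rep("P", 2), rep("Q", 8), rep("out", 5))
  sid <- rep("s1", 15)
  fr <- population_frequencies(labels, sid, denominator = c("P", "Q"))
  expect_equal(fr$frequency[fr$population == "P"], 0.2)
  expect_equal(fr$frequency[fr$population == "Q"], 0.8)
  # exhaustive partition sums to one
  fr_all <- population_frequencies(labels, sid)
  expect_equal(sum(fr_all$frequency), 1, tolerance = 1e-12)

  # identity with planted truth
  spec <- build_default_thymus_spec(events_per_sample = 1500,
                                    n_samples = c(mnc = 2, cd34 = 2))
  s <- simulate_sample(spec, "bdc", 2)
  fr_truth <- population_frequencies(s$truth$event_labels,
                                     rep("x", length(s$truth$event_labels)))
  got <- setNames(fr_truth$frequency, fr_truth$population)
  expect_equal(got[names(s$truth$sample_frequencies)],
               s$truth$sample_frequencies, ignore_attr = TRUE)

  expect_warning(population_frequencies(labels, sid, denominator = "absent"),
                 "empty denominator")
})

test_that("F measures agree with a brute-force confusion oracle and caret", {
  withr::with_seed(33, {
    sid <- rep(c("s1", "s2"), each = 300)
    truth <- sample(c("A", "B", "C"), 600, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    cand <- truth
    flip <- sample(600, 90)
    cand[flip] <- sample(c("A", "B", "C"), 90, replace = TRUE)
  })
  fm <- f_measure_report(cand, truth, sid)
  for (i in seq_len(nrow(fm))) {
    ix <- sid == fm$sample[i]
    p <- fm$population[i]
    tp <- sum(ix & cand == p & truth == p)
    fp <- sum(ix & cand == p & truth != p)
    fn <- sum(ix & cand != p & truth == p)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    expect_identical(fm$precision[i], prec)
    expect_identical(fm$recall[i], rec)
    expect_identical(fm$F[i], if (prec + rec == 0) 0 else
      2 * prec * rec / (prec + rec))
  }
  # independent oracle: caret's precision/recall confusion mode
  if (requireNamespace("caret", quietly = TRUE)) {
    for (s in c("s1", "s2")) {
      ix <- sid == s
      cm <- caret::confusionMatrix(factor(cand[ix], c("A", "B", "C")),
                                   factor(truth[ix], c("A", "B", "C")),
                                   mode = "prec_recall")
      for (p in c("A", "B", "C")) {
        row <- fm[fm$sample == s & fm$population == p, ]
        expect_equal(row$F,
                     unname(cm$byClass[paste("Class:", p), "F1"]),
                     tolerance = 1e-12)
      }
    }
  }

  expect_equal(f_measure_report(truth, truth, sid)$F, rep(1, 6))
  # precision 0.5, recall 1 -> F = 2/3
  fm2 <- f_measure_report(c("A", "A"), c("A", "B"), c("x", "x"))
  expect_equal(fm2$F[fm2$population == "A"], 2 / 3)
  # predicted never -> F = 0
  fm3 <- f_measure_report(c("B", "B"), c("A", "B"), c("x", "x"))
  expect_equal(fm3$F[fm3$population == "A"], 0)
})

test_that("group tests recover a planted step and respect batch confounding", {
  withr::with_seed(41, {
    n <- 26
    ages <- round(2^seq(0, log2(5110), length.out = n))
    batch <- paste0("day", (seq_len(n) - 1) %% 5 + 1)
    grp <- ages > 548
    base <- 0.03
    delta <- 0.02
    freq_y <- base + delta * grp + rnorm(n, 0, 0.004)
    freq <- data.frame(sample = paste0("s", 1:n), population = "B cells",
                       frequency = freq_y)
    gt <- group_difference_test(freq, setNames(grp, freq$sample),
                                setNames(batch, freq$sample))
    se <- 0.004 * sqrt(1 / sum(grp) + 1 / sum(!grp))
    expect_lt(abs(gt$estimate - delta), 2.5 * se)
    expect_lt(gt$p_value, 0.01)

    # batch fully explaining the difference: confounded -> error
    batch2 <- ifelse(grp, "dayA", "dayB")
    expect_error(
      group_difference_test(freq, setNames(grp, freq$sample),
                            setNames(batch2, freq$sample)),
      "confounded")

    # a batch-driven artefact is absorbed once batch enters the design
    batch3 <- rep(c("dayA", "dayB"), length.out = n)
    art <- 0.03 * (batch3 == "dayA")
    freq2 <- freq
    freq2$frequency <- 0.03 + art + rnorm(n, 0, 0.002)
    grp3 <- batch3 == "dayA"  # group aligned with batch -> rank deficient
    expect_error(
      group_difference_test(freq2, setNames(grp3, freq$sample),
                            setNames(batch3, freq$sample)),
      "confounded")
  })
})

test_that("paired t and BH adjustment match the closed-form examples", {
  ptest <- paired_population_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(ptest$t, 3.4641, tolerance = 1e-4)
  expect_equal(ptest$df, 2)
  expect_equal(ptest$p_value, 0.0742, tolerance = 1e-3)
  # closed form: 2 * P(T_2 > sqrt(12))
  expect_equal(ptest$p_value, 2 * pt(sqrt(12), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  flip <- paired_population_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(flip$t, -ptest$t)
  expect_equal(flip$p_value, ptest$p_value)

  expect_error(paired_population_test(c(1, 2, 3), c(1, 2, 3)), "zero-variance")

  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.2), 0.2)
  withr::with_seed(9, {
    p <- runif(50)
    q <- adjust_pvalues(p)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
    expect_equal(adjust_pvalues(p, "bonferroni"), pmin(p * 50, 1))
  })
  expect_error(adjust_pvalues(c(0.5, 1.2)), "outside")
})

test_that("loess trends are exact on polynomials and order-invariant", {
  x <- seq(1, 12, length.out = 30)
  y_lin <- 3 * x - 2
  expect_equal(loess_trend(x, y_lin, span = 1, degree = 1), y_lin,
               tolerance = 1e-6)
  expect_equal(loess_trend(x, y_lin, span = 1, degree = 2), y_lin,
               tolerance = 1e-6)
  expect_equal(loess_trend(x, rep(5, 30)), rep(5, 30), tolerance = 1e-9)

  withr::with_seed(3, {
    y <- sin(x) + rnorm(30, 0, 0.1)
    perm <- sample(30)
    f1 <- loess_trend(x, y, span = 0.8)
    f2 <- loess_trend(x[perm], y[perm], span = 0.8)
    expect_equal(f1[perm], f2, tolerance = 1e-9)
  })
  expect_error(loess_trend(x, y_lin, span = 2), "span")
  expect_error(loess_trend(1:3, 1:3, degree = 2), "n >=")
})
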