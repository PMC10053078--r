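test_that("cohort summary percentages use evaluable denominators at one decimal", {
  clin <- make_clinical(278, 65, c(docetaxel = 176, enzalutamide = 112,
                                   abiraterone = 50))
  cs <- cohort_summary(clin)
  tr <- cs$treatments
  expect_equal(tr$n_evaluable, rep(213L, 3))
  expect_equal(tr$pct[tr$treatment == "docetaxel"], 82.6)
  expect_equal(tr$pct[tr$treatment == "enzalutamide"], 52.6)
  expect_equal(tr$pct[tr$treatment == "abiraterone"], 23.5)
  # percentages reproduce their counts exactly
  expect_equal(round(100 * tr$n / tr$n_evaluable, 1), tr$pct)
  # a column with no evaluable record reports a missing percentage
  clin$radium223 <- NA_integer_
  cs2 <- cohort_summary(clin)
  expect_true(is.na(cs2$treatments$pct[
    cs2$treatments$treatment == "radium223"]))
  # hand tally on a small synthetic table
  small <- make_clinical(10, 2, c(docetaxel = 3))
  expect_equal(cohort_summary(small)$treatments$pct, round(100 * 3 / 8, 1))
  expect_equal(cohort_summary(small)$age$n_evaluable, 10L)
})

test_that("single-treatment subset groups patients and applies the >=10 rule", {
  counts <- c(docetaxel = 48, enzalutamide = 18, radium223 = 3,
              abiraterone = 2, carboplatin = 1, estramustine = 1)
  rows <- do.call(rbind, lapply(names(counts), function(tr) {
    n <- counts[[tr]]
    df <- data.frame(matrix(0L, n, length(counts),
                            dimnames = list(NULL, names(counts))))
    df[[tr]] <- 1L
    df
  }))
  clin <- data.frame(patient_id = sprintf("P%03d", seq_len(sum(counts))),
                     age_at_biopsy = 65, n_treatment_lines = 1L, rows,
                     check.names = FALSE, stringsAsFactors = FALSE)
  # plus patients with multiple lines who must not enter the subset
  multi <- make_clinical(30, 0, c(docetaxel = 30))
  multi$enzalutamide <- 1L
  sub <- single_treatment_subset(rbind_fill(clin, multi), min_group = 10)
  expect_equal(sub$n_single, 73L)
  expect_equal(sum(sub$groups$n), 73L)
  expect_equal(sub$groups$n[sub$groups$treatment == "docetaxel"], 48L)
  expect_setequal(sub$groups$treatment[sub$groups$retained],
                  c("docetaxel", "enzalutamide"))
  expect_equal(nrow(sub$patients), 66L)
})

test_that("Mann-Whitney wrapper matches exhaustive rank enumeration", {
  set.seed(31)
  for (sizes in list(c(3, 3), c(6, 6), c(4, 6))) {
    for (rep in 1:10) {
      x <- round(rnorm(sizes[1]), 3); y <- round(rnorm(sizes[2], 0.5), 3)
      got <- any_variant_vs_ar_expression(
        data.frame(sample = sprintf("S%02d", seq_len(sum(sizes))),
                   ar_expression = c(x, y)),
        setNames(rep(c(TRUE, FALSE), sizes), sprintf("S%02d",
                                                     seq_len(sum(sizes)))))
      expect_equal(got$p, mw_enum_oracle(x, y), tolerance = 1e-10)
    }
  }
  # complete separation at (3,3): the exact two-sided minimum 2/20
  x <- c(10, 11, 12); y <- c(1, 2, 3)
  expect_equal(mw_enum_oracle(x, y), 0.1)
})

test_that("identical distributions give p ~ 1 and empty groups degenerate cleanly", {
  ar <- data.frame(sample = sprintf("S%02d", 1:20),
                   ar_expression = rep(c(5, 7), 10))
  pos <- setNames(rep(c(TRUE, FALSE), each = 10), ar$sample)
  res <- any_variant_vs_ar_expression(ar, pos)
  expect_gt(res$p, 0.9)
  res0 <- any_variant_vs_ar_expression(ar, setNames(rep(TRUE, 20), ar$sample))
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p))
})

test_that("null rejection rate of the rank test is ~5% at alpha 0.05", {
  set.seed(32)
  rej <- mean(replicate(400, {
    ar <- data.frame(sample = sprintf("S%02d", 1:60),
                     ar_expression = rnorm(60))
    pos <- setNames(rep(c(TRUE, FALSE), each = 30), ar$sample)
    any_variant_vs_ar_expression(ar, pos)$p < 0.05
  }))
  expect_gt(rej, 0.02); expect_lt(rej, 0.08)
})

test_that("BH adjustment matches the hand step-up and its invariants hold", {
  # m = 1: q equals p
  expect_equal(p.adjust(0.04, "BH"), 0.04)
  # worked example
  expect_equal(p.adjust(c(0.01, 0.02, 0.9), "BH"), c(0.03, 0.03, 0.9))
  set.seed(33)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1))
    q <- p.adjust(p, "BH")
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("per-count group tests skip singletons and BH-adjust the family", {
  set.seed(34)
  n_pos <- setNames(c(rep(0L, 10), rep(1L, 10), rep(2L, 8), 3L),
                    sprintf("S%02d", 1:29))
  ar <- data.frame(sample = names(n_pos),
                   ar_expression = rnorm(29) + 0.4 * n_pos)
  res <- per_count_group_tests(ar, n_pos)
  expect_equal(res$skipped_groups, 3L)
  expect_equal(nrow(res$tests), choose(3, 2))
  expect_equal(res$tests$q, p.adjust(res$tests$p, "BH"))
})

test_that("univariate screen recovers exact fits and flags inestimable cases", {
  n <- 40
  ids <- sprintf("S%02d", 1:n)
  age <- seq(46, 85, length.out = n)
  clin <- data.frame(patient_id = ids, age_at_biopsy = age,
                     n_treatment_lines = 2L, docetaxel = 1L)
  vals <- matrix(0.3 * age - 5, n, 1, dimnames = list(ids, "AR45"))
  re <- structure(list(values = vals,
                       status = matrix("ok", n, 1, dimnames = dimnames(vals)),
                       sj_variant = vals, sj_reference = rep(100, n),
                       positive = vals >= 1, threshold_pct = 1),
                  class = "arv_relexpr")
  scr <- univariate_screen(clin, re, c("age_at_biopsy", "docetaxel"))
  age_row <- scr[scr$covariate == "age_at_biopsy", ]
  expect_equal(age_row$slope, 0.3, tolerance = 1e-10)
  expect_lt(age_row$p, 1e-12)
  expect_true(age_row$significant)
  # constant covariate is inestimable, never silently significant
  doc_row <- scr[scr$covariate == "docetaxel", ]
  expect_equal(doc_row$note, "inestimable")
  expect_false(doc_row$significant)
})

test_that("regression slopes are unbiased on synthetic data", {
  set.seed(36)
  n <- 40; beta <- 0.25; reps <- 300
  slopes <- replicate(reps, {
    x <- rnorm(n)
    y <- 1 + beta * x + rnorm(n, 0, 0.8)
    ids <- sprintf("S%02d", 1:n)
    clin <- data.frame(patient_id = ids, age_at_biopsy = x,
                       n_treatment_lines = 1L)
    vals <- matrix(y, n, 1, dimnames = list(ids, "AR45"))
    re <- structure(list(values = vals,
                         status = matrix("ok", n, 1,
                                         dimnames = dimnames(vals)),
                         sj_variant = vals, sj_reference = rep(100, n),
                         positive = vals >= 1, threshold_pct = 1),
                    class = "arv_relexpr")
    univariate_screen(clin, re, "age_at_biopsy")$slope
  })
  mc_se <- stats::sd(slopes) / sqrt(reps)
  expect_lt(abs(mean(slopes) - beta), 2 * mc_se + 1e-9)
})

test_that("multivariate model keeps the true covariate and coincides with univariate when alone", {
  set.seed(37)
  n <- 120
  retained_true <- retained_null <- logical(100)
  for (r in 1:100) {
    ids <- sprintf("S%03d", 1:n)
    x1 <- rnorm(n); x0 <- rnorm(n)
    y <- 2 + 0.5 * x1 + rnorm(n)
    clin <- data.frame(patient_id = ids, age_at_biopsy = x1,
                       n_treatment_lines = 1L, nullcov = x0)
    vals <- matrix(y, n, 1, dimnames = list(ids, "AR45"))
    re <- structure(list(values = vals,
                         status = matrix("ok", n, 1,
                                         dimnames = dimnames(vals)),
                         sj_variant = vals, sj_reference = rep(100, n),
                         positive = vals >= 1, threshold_pct = 1),
                    class = "arv_relexpr")
    mv <- multivariate_model(clin, re, c("age_at_biopsy", "nullcov"))
    retained_true[r] <- mv$retained[mv$feature == "age_at_biopsy"]
    retained_null[r] <- mv$retained[mv$feature == "nullcov"]
  }
  expect_gte(mean(retained_true), 0.9)
  expect_lt(mean(retained_null), 0.15)

  # single selected feature: inference identical to the univariate screen
  ids <- sprintf("S%03d", 1:n)
  x <- rnorm(n); y <- 1 + 0.3 * x + rnorm(n)
  clin <- data.frame(patient_id = ids, age_at_biopsy = x,
                     n_treatment_lines = 1L)
  vals <- matrix(y, n, 1, dimnames = list(ids, "AR45"))
  re <- structure(list(values = vals,
                       status = matrix("ok", n, 1, dimnames = dimnames(vals)),
                       sj_variant = vals, sj_reference = rep(100, n),
                       positive = vals >= 1, threshold_pct = 1),
                  class = "arv_relexpr")
  uni <- univariate_screen(clin, re, "age_at_biopsy")
  mv <- multivariate_model(clin, re, "age_at_biopsy")
  expect_equal(mv$estimate, uni$slope, tolerance = 1e-12)
  expect_equal(mv$p, uni$p, tolerance = 1e-12)
})

test_that("oncoprint ordering is the deterministic memo-sort", {
  pos <- rbind(S1 = c(TRUE, TRUE, FALSE),
               S2 = c(TRUE, FALSE, FALSE),
               S3 = c(FALSE, TRUE, TRUE),
               S4 = c(FALSE, FALSE, FALSE))
  colnames(pos) <- c("V2", "V1", "V3")
  # prevalence: V2 = 2, V1 = 2, V3 = 1 -> tie broken by name: V1, V2, V3
  ord <- oncoprint_order(pos)
  expect_equal(ord$variants, c("V1", "V2", "V3"))
  # binary keys in variant order V1,V2,V3: S1=110, S2=010, S3=101, S4=000
  expect_equal(ord$samples, c("S1", "S3", "S2", "S4"))
  # all-negative cohort: identifier order under the tie-break
  none <- pos & FALSE
  expect_equal(oncoprint_order(none)$samples, rownames(pos))
  # permuting input rows leaves the output invariant
  perm <- pos[c(3, 1, 4, 2), ]
  expect_equal(oncoprint_order(perm)$samples, ord$samples)
  expect_equal(oncoprint_order(perm)$variants, ord$variants)
})
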