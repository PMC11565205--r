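test_that("ANOVA sums of squares match brute-force deviation sums", {
  set.seed(31)
  for (dims in list(c(2, 2, 2), c(3, 2, 3), c(5, 2, 4))) {
    df <- expand.grid(genotype_id = sprintf("g%d", seq_len(dims[1])),
                      treatment = c("WW", "WS")[seq_len(dims[2])],
                      replicate = seq_len(dims[3]),
                      stringsAsFactors = FALSE)
    df$y <- rnorm(nrow(df), sd = 2) +
      as.integer(factor(df$genotype_id)) * 0.5
    at <- two_way_anova(df, "y")
    bf <- brute_force_ss(df$y, df$genotype_id, df$treatment)
    expect_equal(at$SS, unname(bf), tolerance = 1e-10)
    expect_equal(sum(at$SS), sum((df$y - mean(df$y))^2), tolerance = 1e-10)
    # cross-check against the stock linear-model ANOVA
    av <- stats::anova(stats::aov(y ~ genotype_id * treatment, df))
    expect_equal(at$SS, unname(av$`Sum Sq`), tolerance = 1e-10)
    expect_equal(at$p[1:3], unname(av$`Pr(>F)`[1:3]), tolerance = 1e-10)
  }
})

test_that("a pure genotype effect moves only the genotype SS", {
  df <- expand.grid(genotype_id = sprintf("g%d", 1:4),
                    treatment = c("WW", "WS"), replicate = 1:3,
                    stringsAsFactors = FALSE)
  df$y <- rep(1, nrow(df))
  base <- two_way_anova(df, "y")
  expect_equal(base$SS, rep(0, 4))
  expect_true(all(is.na(base$F)))  # no residual variance: F undefined
  df$y2 <- df$y + as.integer(factor(df$genotype_id))
  shifted <- two_way_anova(df, "y2")
  expect_gt(shifted$SS[1], 0)
  expect_equal(shifted$SS[2:4], rep(0, 3), tolerance = 1e-12)
})

test_that("ANOVA p-values are invariant to adding a constant", {
  set.seed(8)
  df <- expand.grid(genotype_id = sprintf("g%d", 1:5),
                    treatment = c("WW", "WS"), replicate = 1:3,
                    stringsAsFactors = FALSE)
  df$y <- rnorm(nrow(df))
  df$y2 <- df$y + 1000
  expect_equal(two_way_anova(df, "y")$p, two_way_anova(df, "y2")$p,
               tolerance = 1e-8)
})

test_that("unbalanced designs drop to unweighted means with a warning", {
  set.seed(4)
  df <- expand.grid(genotype_id = sprintf("g%d", 1:4),
                    treatment = c("WW", "WS"), replicate = 1:3,
                    stringsAsFactors = FALSE)
  df$y <- rnorm(nrow(df))
  df <- df[-1, ]  # remove one replicate
  expect_warning(at <- two_way_anova(df, "y"), "unbalanced")
  expect_false(attr(at, "balanced"))
  expect_equal(at$df[4], nrow(df) - 8)
  df_missing <- df[df$genotype_id != "g1" | df$treatment != "WW", ]
  expect_error(two_way_anova(df_missing, "y"), "empty cell")
})

test_that("variance components follow both conventions", {
  at <- structure(
    data.frame(source = c("genotype_id", "treatment",
                          "genotype_id:treatment", "residual"),
               df = c(88, 1, 88, 356),
               SS = c(127.2, 14436.1, 61.6, 61.49) * c(88, 1, 88, 356),
               MS = c(127.2, 14436.1, 61.6, 61.49),
               F = NA_real_, p = NA_real_),
    n_a = 89, n_b = 2, n_reps = 3, balanced = TRUE,
    class = c("anova_table", "data.frame"))
  vc <- variance_components(at, n_treatments = 2, n_replicates_std = 5)
  expect_equal(vc$sigma2_g, 127.2)
  expect_equal(vc$sigma2_gxt, 61.6)
  expect_equal(vc$sigma2_e, 61.49)
  # Eq-style phenotypic variance with the standardized divisor of 5
  expect_equal(vc$sigma2_p, 127.2 + 61.6 / 2 + 61.49 / 5, tolerance = 1e-12)
  expect_equal(round(vc$sigma2_p, 1), 170.3)
  # ems convention with truncation
  at$MS <- c(2, 5, 4, 6)  # MS_G < MS_GT < MS_E: both truncate
  vc2 <- variance_components(at, convention = "ems", n_replicates = 3)
  expect_equal(vc2$sigma2_g, 0)
  expect_equal(vc2$sigma2_gxt, 0)
  expect_true(vc2$truncated)
  at$MS <- rep(0, 4)
  vc3 <- variance_components(at)
  expect_equal(vc3$sigma2_p, 0)
})

test_that("heritability and CV formulas reproduce published-style values", {
  expect_equal(round(heritability(127.2, 160.03), 2), 0.79)
  expect_equal(round(heritability(963, 1281.63), 2), 0.75)
  expect_equal(heritability(0, 5), 0)
  cv <- gcv_pcv(127.2, 160.03, 23.2)
  expect_equal(round(cv$GCV_pct, 2), 48.61)
  expect_equal(round(cv$PCV_pct, 2), 54.53)
  cv2 <- gcv_pcv(963, 1281.63, 148.35)
  expect_equal(round(cv2$GCV_pct, 2), 20.92)
  expect_equal(round(cv2$PCV_pct, 2), 24.13)
  cv3 <- gcv_pcv(0, 4, 10)
  expect_equal(cv3$GCV_pct, 0)
  expect_equal(cv3$PCV_pct, 100 * 2 / 10)
  expect_error(gcv_pcv(1, 2, 0), "substitute mean")
})

test_that("fold change is max/min of genotype means within treatment", {
  means <- data.frame(genotype_id = c("a", "b", "c"), treatment = "WW",
                      A_n = c(17.6, 25, 39.3))
  expect_equal(round(fold_change(means, "A_n", "WW"), 2), 2.23)
  means$A_n <- c(2, 4, 8)
  expect_equal(fold_change(means, "A_n", "WW"), 4)
  means$A_n <- rep(3, 3)
  expect_equal(fold_change(means, "A_n", "WW"), 1)
  means$A_n <- c(-1, 2, 3)
  expect_error(fold_change(means, "A_n", "WW"), "undefined")
})

test_that("ems heritability does not increase along a noise ladder", {
  h2_at_noise <- function(sig_e) {
    mean(vapply(1:30, function(s) {
      sim <- simulate_trial(sim_config(seed = s, n_genotypes = 30,
                                       sigma_e = sig_e))
      rec <- with_log_gs(sim$records)
      at <- two_way_anova(rec, "log_gs")
      vc <- variance_components(at, convention = "ems",
                                n_replicates_std = 3)
      heritability(vc$sigma2_g, vc$sigma2_p)
    }, numeric(1)))
  }
  ladder <- vapply(c(0.05, 0.2, 0.6), h2_at_noise, numeric(1))
  expect_true(all(diff(ladder) < 0))
})

test_that("trait summary table assembles all pieces per trait", {
  sim <- small_trial(seed = 2)
  d <- derive_physiology(sim$records)
  m <- aggregate_means(d)
  tab <- trait_summary_table(d, m, c("A_n", "g_s", "iwue"))
  expect_equal(tab$trait, c("A_n", "g_s", "iwue"))
  expect_true(all(tab$H_b2 >= 0 & tab$H_b2 <= 1))
  expect_true(all(tab$PCV_pct >= tab$GCV_pct))
  expect_equal(tab$mean[1], mean(d$A_n))
})
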