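test_that("studentized-range CDF agrees with the stock implementation", {
  for (k in c(2, 4, 6)) {
    for (df in c(5, 20, 120)) {
      for (q in c(1, 2.5, 4)) {
        expect_equal(ptukey_sr(q, k, df), stats::ptukey(q, k, df),
                     tolerance = 1e-6,
                     label = sprintf("q=%g k=%d df=%g", q, k, df))
      }
    }
  }
})

test_that("two-group critical value collapses to the sqrt(2) t limit", {
  # with k = 2 the Tukey test is a two-sample t-test, so the critical
  # value is sqrt(2) times the t (normal, at df = Inf) quantile
  expect_equal(round(qtukey_sr(0.95, 2, Inf), 3),
               round(sqrt(2) * stats::qnorm(0.975), 3))
  expect_equal(qtukey_sr(0.95, 2, 30), sqrt(2) * stats::qt(0.975, 30),
               tolerance = 1e-4)
})

test_that("tukey_hsd letters: equal groups share, outliers stand alone", {
  two <- tukey_hsd(c(a = 10, b = 10), ns = 5, ms_error = 4, df_error = 16)
  expect_equal(two$groups$letters, c("a", "a"))
  four <- tukey_hsd(c(g1 = 10, g2 = 10.4, g3 = 9.8, g4 = 45),
                    ns = 6, ms_error = 1, df_error = 20)
  out_letter <- four$groups$letters[four$groups$group == "g4"]
  others <- four$groups$letters[four$groups$group != "g4"]
  expect_false(any(grepl(out_letter, others)))
  expect_true(all(others == others[1]))
  expect_error(tukey_hsd(c(a = 1, b = 2), 3, 1, df_error = 0.5), "df_error")
})

test_that("letter partition is invariant to group input order", {
  means <- c(w = 1, x = 1.2, y = 5, z = 9)
  t1 <- tukey_hsd(means, ns = 4, ms_error = 0.5, df_error = 12)
  t2 <- tukey_hsd(rev(means), ns = 4, ms_error = 0.5, df_error = 12)
  g1 <- setNames(t1$groups$letters, t1$groups$group)
  g2 <- setNames(t2$groups$letters, t2$groups$group)
  shares <- function(g, i, j) {
    any(strsplit(g[[i]], "")[[1]] %in% strsplit(g[[j]], "")[[1]])
  }
  for (i in names(means)) for (j in names(means)) {
    expect_equal(shares(g1, i, j), shares(g2, i, j),
                 label = paste(i, j))
  }
})

test_that("unequal group sizes use the Tukey-Kramer adjustment", {
  means <- c(a = 0, b = 2)
  th <- tukey_hsd(means, ns = c(4, 12), ms_error = 3, df_error = 14)
  q_expected <- 2 / sqrt(3 / 2 * (1 / 4 + 1 / 12))
  expect_equal(th$pairs$q, q_expected, tolerance = 1e-12)
})

test_that("pearson matches the direct covariance formula and cor.test", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.4)
  y <- c(0.7, 2.9, 2.5, 6.1, 3.8)
  res <- pearson(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  fit <- stats::lm(y ~ x)
  expect_equal(res$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(res$intercept, unname(coef(fit)[1]), tolerance = 1e-12)
})

test_that("pearson handles exact, orthogonal and degenerate inputs", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, 2 * x + 1)$r_squared, 1)
  # orthogonalized y: correlation zero to machine precision
  set.seed(2)
  y <- rnorm(10)
  y_perp <- resid(stats::lm(y ~ x))
  expect_lt(abs(pearson(x, y_perp)$r), 1e-12)
  expect_warning(res <- pearson(x, rep(3, 10)), "zero variance")
  expect_true(is.na(res$r))
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("correlation matrix covers all trait pairs pairwise-complete", {
  sim <- small_trial()
  m <- aggregate_means(derive_physiology(sim$records))
  cm <- correlation_matrix(m, c("A_n", "g_s", "iwue"))
  expect_equal(nrow(cm), 3)
  expect_true(all(abs(cm$r) <= 1))
  expect_equal(cm$r_squared, cm$r^2)
})

test_that("haplotype ANOVA detects a real haplotype effect on g_s", {
  hits <- vapply(1:25, function(s) {
    sim <- simulate_trial(sim_config(seed = 300 + s,
                                     haplotype_effect = 0.15))
    rec <- with_log_gs(sim$records)
    at <- haplotype_anova(rec, "log_gs", "SbPIP1.1", sim$assignments)
    at$p[at$source == "population"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("haplotype ANOVA flags structural problems by name", {
  sim <- small_trial()
  rec <- with_log_gs(sim$records)
  asg <- sim$assignments
  asg$group <- "RP"  # NRP absent
  expect_error(haplotype_anova(rec, "log_gs", "SbPIP1.1", asg), "NRP")
  expect_error(haplotype_anova(rec, "log_gs", "SbTIP9.9",
                               sim$assignments), "no assignments")
  dup <- rbind(sim$assignments,
               data.frame(genotype_id = sim$assignments$genotype_id[1],
                          aquaporin_id = "SbPIP1.1",
                          group = "NRP"))
  expect_error(haplotype_anova(rec, "log_gs", "SbPIP1.1", dup),
               "more than one group")
})

test_that("treatment term is null-calibrated when WS equals WW", {
  pvals <- vapply(1:20, function(s) {
    sim <- simulate_trial(sim_config(
      seed = 600 + s, n_genotypes = 20, ws_gs_factor = 1,
      psi_predawn_WS = -0.1, ws_kplant_factor = 1))
    rec <- with_log_gs(sim$records)
    at <- haplotype_anova(rec, "log_gs", "SbPIP1.1", sim$assignments)
    at$p[at$source == "treatment"]
  }, numeric(1))
  # under the treatment null, small p should not be systematic
  expect_gt(mean(pvals > 0.05), 0.7)
})
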