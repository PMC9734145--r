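# Shapiro-Wilk-gated paired comparisons, repeated-measures ANOVA with
# generalized eta squared, Tukey-adjusted post-hoc contrasts.

test_that("identical samples give a degenerate null result", {
  a <- c(1, 2, 3, 4, 5, 6)
  res <- paired_comparison(a, a)
  expect_equal(res$p_value, 1)
  expect_equal(res$effect_size, 0)
})

test_that("normal differences take the t branch and recover Cohen's d", {
  set.seed(2024)
  ds <- replicate(200, {
    d <- rnorm(20, 0.55, 1)
    res <- paired_comparison(d + 5, rep(5, 20) + rnorm(20) * 0)
    c(t_branch = res$method == "paired_t", d = res$effect_size,
      dir = sign(res$statistic))
  })
  # the gate keeps the parametric branch for most normal samples
  expect_gt(mean(ds["t_branch", ]), 0.9)
  expect_equal(mean(ds["d", ds["t_branch", ] == 1]), 0.55,
               tolerance = 0.1)
})

test_that("skewed differences trip the gate into the Wilcoxon branch", {
  set.seed(77)
  a <- rlnorm(31, 0, 1)
  b <- rep(0, 31)
  res <- paired_comparison(a, b)
  expect_equal(res$method, "wilcoxon")
  expect_gte(res$effect_size, 0)
  expect_lte(res$effect_size, 1)
  # effect direction agrees with the t branch on the same data
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(sign(res$z), sign(unname(tt$statistic)))
})

test_that("wilcoxon p-value matches the stats wilcox.test reference", {
  set.seed(12)
  a <- rlnorm(25); b <- rnorm(25, 1)
  res <- paired_comparison(a, b)
  if (res$method == "wilcoxon") {
    ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                        correct = TRUE))
    expect_equal(res$p_value, ref$p.value)
    # |Z|/sqrt(n) consistent with the p-value route
    expect_equal(abs(res$z), qnorm(res$p_value / 2, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("interaction F equals the squared paired t on the dd-contrast", {
  set.seed(314)
  for (k in 1:50) {
    n <- sample(4:40, 1L)
    Y <- matrix(rnorm(4 * n, sd = runif(1, 0.5, 30)), n, 4)
    fit <- rm_anova_2x2(Y)
    dd <- (Y[, 1] - Y[, 2]) - (Y[, 3] - Y[, 4])
    tt <- t.test(dd)
    expect_equal(fit$effects$F[3L], unname(tt$statistic)^2,
                 tolerance = 1e-8)
    expect_true(all(fit$effects$ges >= 0 & fit$effects$ges <= 1))
  }
})

test_that("F and ges match the aov() error-strata oracle", {
  # a small hand-decomposable table
  Y <- matrix(c(10, 12, 11, 13,
                20, 19, 21, 22,
                15, 14, 16, 18,
                30, 28, 27, 33), nrow = 4, byrow = TRUE)
  fit <- rm_anova_2x2(Y)
  oracle <- aov_oracle_2x2(Y)
  expect_equal(fit$effects$F, oracle$F, tolerance = 1e-10)
  expect_equal(fit$effects$ges, oracle$ges, tolerance = 1e-10)
  # and on random data
  set.seed(99)
  Y2 <- matrix(rnorm(4 * 12, 50, 10), 12, 4)
  fit2 <- rm_anova_2x2(Y2)
  oracle2 <- aov_oracle_2x2(Y2)
  expect_equal(fit2$effects$F, oracle2$F, tolerance = 1e-10)
  expect_equal(fit2$effects$ges, oracle2$ges, tolerance = 1e-10)
})

test_that("identical cells across conditions give all-zero F", {
  Y <- matrix(rep(c(4, 9, 2, 7), each = 4), 4, 4)   # no effects at all
  Y <- matrix(rep(rnorm(4, 10), 4), 4, 4)           # subject differences only
  fit <- rm_anova_2x2(Y)
  expect_equal(fit$effects$F, c(0, 0, 0))
  expect_equal(fit$effects$ges, c(0, 0, 0))
})

test_that("posthoc contrasts: estimates, dominance and highlights", {
  set.seed(8)
  Y <- matrix(rnorm(4 * 15, 50, 5), 15, 4)
  fit <- rm_anova_2x2(Y, factor_names = c("Condition", "Articulation"),
                      level_names = list(c("teaching", "performing"),
                                         c("legato", "staccato")))
  ph <- posthoc_emm_tukey(fit)
  expect_equal(nrow(ph), 6L)
  expect_true(all(ph$p_tukey >= ph$p_unadjusted))
  expect_equal(attr(ph, "family_size"), 4L)
  expect_equal(sum(ph$highlight), 2L)
  # estimates are differences of cell means
  cm <- fit$cell_means
  expect_equal(ph$estimate[1L], unname(cm[1L] - cm[2L]))
  # equal cell means: adjusted p near 1
  Yn <- Y - matrix(colMeans(Y), 15, 4, byrow = TRUE)
  phn <- posthoc_emm_tukey(rm_anova_2x2(Yn))
  expect_true(all(phn$p_tukey > 0.999))
})

test_that("posthoc estimates match the emmeans reference", {
  set.seed(123)
  n <- 10L
  Y <- matrix(rnorm(4 * n, 50, 5), n, 4)
  fit <- rm_anova_2x2(Y)
  ph <- posthoc_emm_tukey(fit)
  long <- data.frame(
    value = as.vector(Y), subj = factor(rep(seq_len(n), 4L)),
    A = factor(rep(c("A1", "A1", "A2", "A2"), each = n)),
    B = factor(rep(c("B1", "B2", "B1", "B2"), each = n)))
  # inline the data so downstream re-evaluation of the call can see it
  m <- eval(bquote(stats::aov(value ~ A * B + Error(subj / (A * B)),
                              data = .(long))))
  emm <- suppressMessages(emmeans::emmeans(m, ~ A * B))
  ref <- as.data.frame(pairs(emm, adjust = "tukey"))
  # emmeans orders cells A1.B1, A2.B1, A1.B2, A2.B2; map by name
  my <- setNames(ph$estimate, gsub(" ", "", ph$contrast))
  for (i in seq_len(nrow(ref))) {
    key <- gsub(" ", "", gsub("([AB][12]) ([AB][12])", "\\1.\\2",
                              ref$contrast[i]))
    if (key %in% names(my)) {
      expect_equal(unname(my[key]), ref$estimate[i], tolerance = 1e-8)
    }
  }
})

test_that("the technique battery contains the reported analyses", {
  cfg <- default_config("exp1")
  cfg$n_participants <- 6L
  cfg$seed <- 3L
  rep <- run_pipeline(config = cfg)
  art <- rep$stats$articulation
  expect_s3_class(art$ioi_test, "test_result")
  expect_s3_class(art$kot_anova, "anova_result")
  expect_s3_class(art$kv_anova, "anova_result")
  expect_null(art$transition_anova)
  dyn <- rep$stats$dynamics
  expect_s3_class(dyn$ioi_test, "test_result")
  expect_s3_class(dyn$kv_anova, "anova_result")
  expect_s3_class(dyn$transition_anova, "anova_result")
  expect_s3_class(dyn$transition_posthoc, "tbl_df")
})
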