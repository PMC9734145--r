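#' Shapiro-Wilk-gated paired comparison
#'
#' Compares two paired samples (e.g. participant mean IOIs under teaching
#' vs. performing). A Shapiro-Wilk test is first run on the paired
#' differences; if its p-value falls below `alpha_gate` the comparison uses
#' a two-tailed Wilcoxon signed-rank test with effect size
#' `r = |Z| / sqrt(n)` (Z from the normal approximation with continuity
#' correction for n >= 10, otherwise back-derived from the exact p-value);
#' otherwise a two-tailed paired t-test with Cohen's
#' `d = mean(diff) / sd(diff)`. Zero-variance differences make the t
#' statistic undefined and are reported as a degenerate result with
#' `p = 1`, `d = 0`.
#'
#' @param a,b paired numeric vectors (same participants, same order).
#' @param alpha_gate normality gate (default 0.05).
#' @param labels names of the two conditions, used in the descriptives.
#' @return A `test_result` list: `method` (`"paired_t"` or `"wilcoxon"`),
#'   `statistic`, `df` (t only), `p_value`, `effect_size` (`d` or `r`),
#'   `shapiro_p`, `descriptives` (M/SD/Mdn/IQR per condition), `n`,
#'   `two_tailed = TRUE`.
#' @export
paired_comparison <- function(a, b, alpha_gate = 0.05,
                              labels = c("a", "b")) {
  if (length(a) != length(b)) stop("samples must be paired (equal length)",
                                   call. = FALSE)
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- a - b
  desc <- tibble::tibble(
    condition = labels,
    M = c(mean(a), mean(b)), SD = c(stats::sd(a), stats::sd(b)),
    Mdn = c(stats::median(a), stats::median(b)),
    IQR = c(stats::IQR(a), stats::IQR(b)))
  if (stats::sd(d) == 0) {
    sw_p <- NA_real_
    return(structure(list(method = "paired_t", statistic = NA_real_,
                          df = n - 1L, p_value = 1, effect_size = 0,
                          effect_size_type = "cohens_d", shapiro_p = sw_p,
                          degenerate = TRUE, descriptives = desc, n = n,
                          two_tailed = TRUE), class = "test_result"))
  }
  sw_p <- stats::shapiro.test(d)$p.value
  if (sw_p < alpha_gate) {
    use_exact <- n < 10L && !any(d == 0) && !any(duplicated(abs(d[d != 0])))
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = use_exact,
                                              correct = TRUE))
    z <- if (use_exact) {
      stats::qnorm(wt$p.value / 2, lower.tail = FALSE)
    } else {
      signed_rank_z(d)
    }
    structure(list(method = "wilcoxon", statistic = unname(wt$statistic),
                   z = z, df = NULL, p_value = wt$p.value,
                   effect_size = min(abs(z) / sqrt(n), 1),
                   effect_size_type = "r", shapiro_p = sw_p,
                   degenerate = FALSE, descriptives = desc, n = n,
                   two_tailed = TRUE), class = "test_result")
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    structure(list(method = "paired_t", statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   effect_size = mean(d) / stats::sd(d),
                   effect_size_type = "cohens_d", shapiro_p = sw_p,
                   degenerate = FALSE, descriptives = desc, n = n,
                   two_tailed = TRUE), class = "test_result")
  }
}

# Z for the Wilcoxon signed-rank statistic: normal approximation with tie
# correction and continuity correction, matching wilcox.test internals.
signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  cc <- sign(V - mu) * 0.5
  (V - mu - cc) / sqrt(sigma2)
}

#' @export
print.test_result <- function(x, ...) {
  if (x$method == "paired_t") {
    cat(sprintf("Paired t-test: t(%d) = %.3f, p = %.4g, Cohen's d = %.3f\n",
                x$df, x$statistic, x$p_value, x$effect_size))
  } else {
    cat(sprintf("Wilcoxon signed-rank: V = %g, Z = %.3f, p = %.4g, r = %.3f\n",
                x$statistic, x$z, x$p_value, x$effect_size))
  }
  cat(sprintf("  (Shapiro-Wilk on differences: p = %.4g; n = %d)\n",
              x$shapiro_p, x$n))
  print(x$descriptives)
  invisible(x)
}

#' 2x2 fully within-subjects ANOVA with generalized eta squared
#'
#' Repeated-measures analysis of variance for a 2 (factor A, e.g.
#' Condition: teaching vs. performing) x 2 (factor B, e.g. Subcomponent)
#' design with both factors within subjects and one observation (a
#' participant-cell mean) per cell. The sum-of-squares decomposition is
#' computed directly; each effect is tested against its own
#' subject-by-effect error term with df (1, n-1). With 2-level factors no
#' sphericity correction is needed. Generalized eta squared is
#' `SS_effect / (SS_effect + SS_subjects + SS_As + SS_Bs + SS_ABs)` — the
#' denominator pools all subject-related variance, making the measure
#' comparable across designs.
#'
#' @param cells numeric matrix or data frame with one row per participant
#'   and 4 columns ordered `A1B1, A1B2, A2B1, A2B2`; rows with missing
#'   values are dropped listwise.
#' @param factor_names names of the two factors.
#' @param level_names list of two character vectors with the level names.
#' @return An `anova_result` list: `effects` tibble (effect, F, df_num,
#'   df_den, p, ges), `cell_means`, `n`, `ss` (all sums of squares).
#' @export
rm_anova_2x2 <- function(cells, factor_names = c("A", "B"),
                         level_names = list(c("A1", "A2"), c("B1", "B2"))) {
  Y <- as.matrix(cells)
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 complete participants", call. = FALSE)
  stopifnot(ncol(Y) == 4L)
  gm <- mean(Y)
  subj <- rowMeans(Y)
  mA <- c(mean(Y[, 1:2]), mean(Y[, 3:4]))          # A levels
  mB <- c(mean(Y[, c(1, 3)]), mean(Y[, c(2, 4)]))  # B levels
  cellm <- colMeans(Y)
  ss_subj <- 4 * sum((subj - gm)^2)
  ss_A <- 2 * n * sum((mA - gm)^2)
  ss_B <- 2 * n * sum((mB - gm)^2)
  a_of <- c(1, 1, 2, 2); b_of <- c(1, 2, 1, 2)
  ss_AB <- n * sum((cellm - mA[a_of] - mB[b_of] + gm)^2)
  subjA <- cbind(rowMeans(Y[, 1:2, drop = FALSE]),
                 rowMeans(Y[, 3:4, drop = FALSE]))
  subjB <- cbind(rowMeans(Y[, c(1, 3), drop = FALSE]),
                 rowMeans(Y[, c(2, 4), drop = FALSE]))
  ss_As <- 2 * sum((subjA - outer(subj, c(0, 0), `+`) -
                      matrix(mA, n, 2, byrow = TRUE) + gm)^2)
  ss_Bs <- 2 * sum((subjB - outer(subj, c(0, 0), `+`) -
                      matrix(mB, n, 2, byrow = TRUE) + gm)^2)
  ss_total <- sum((Y - gm)^2)
  ss_ABs <- ss_total - ss_subj - ss_A - ss_B - ss_AB - ss_As - ss_Bs
  ss_ABs <- max(ss_ABs, 0)
  err <- c(ss_As, ss_Bs, ss_ABs)
  eff <- c(ss_A, ss_B, ss_AB)
  # a null effect is F = 0 even when its error SS is also 0
  Fv <- ifelse(eff == 0, 0, (eff / 1) / (err / (n - 1)))
  p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
  denom_subject <- ss_subj + ss_As + ss_Bs + ss_ABs
  ges <- ifelse(eff == 0, 0, eff / (eff + denom_subject))
  effects <- tibble::tibble(
    effect = c(factor_names[1L], factor_names[2L],
               paste(factor_names, collapse = ":")),
    F = Fv, df_num = 1L, df_den = n - 1L, p = p, ges = ges)
  cell_names <- paste0(rep(level_names[[1L]], each = 2L), ".",
                       rep(level_names[[2L]], 2L))
  structure(list(effects = effects,
                 cell_means = stats::setNames(cellm, cell_names),
                 cells = Y, n = n,
                 factor_names = factor_names, level_names = level_names,
                 ss = c(subjects = ss_subj, A = ss_A, B = ss_B, AB = ss_AB,
                        As = ss_As, Bs = ss_Bs, ABs = ss_ABs,
                        total = ss_total)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("2x2 repeated-measures ANOVA (n = %d)\n", x$n))
  e <- x$effects
  for (k in seq_len(nrow(e))) {
    cat(sprintf("  %-12s F(%d,%d) = %8.3f, p = %.4g, ges = %.3f\n",
                e$effect[k], e$df_num[k], e$df_den[k], e$F[k], e$p[k],
                e$ges[k]))
  }
  invisible(x)
}

#' Tukey-adjusted post-hoc contrasts on the four cell means
#'
#' All six pairwise contrasts among the four cell (estimated marginal)
#' means of a fitted 2x2 within-subjects ANOVA. Each contrast uses the
#' paired-difference standard error `sd(diff)/sqrt(n)` with `n - 1` degrees
#' of freedom (the multivariate within-subjects error structure), and
#' p-values are adjusted over the family of 4 means by the studentized
#' range (Tukey) method: `p_adj = P(q(4, df) > sqrt(2) |t|)`. The two
#' condition-within-subcomponent contrasts (A1 vs A2 at each level of B)
#' are marked `highlight = TRUE`.
#'
#' @param fit an `anova_result` from [rm_anova_2x2()].
#' @return Tibble with one row per contrast: `contrast`, `estimate`, `se`,
#'   `t`, `df`, `p_unadjusted`, `p_tukey`, `highlight`, and an attribute
#'   `family_size = 4`.
#' @export
posthoc_emm_tukey <- function(fit) {
  stopifnot(inherits(fit, "anova_result"))
  Y <- fit$cells
  n <- fit$n
  cn <- names(fit$cell_means)
  pairs <- utils::combn(4L, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    d <- Y[, i] - Y[, j]
    est <- mean(d)
    se <- stats::sd(d) / sqrt(n)
    if (se == 0) {
      tval <- if (est == 0) 0 else Inf
      p_un <- if (est == 0) 1 else 0
      p_tk <- p_un
      warning("degenerate contrast (zero error variance): ", cn[i], " - ",
              cn[j])
    } else {
      tval <- est / se
      p_un <- 2 * stats::pt(-abs(tval), df = n - 1)
      p_tk <- stats::ptukey(sqrt(2) * abs(tval), nmeans = 4L, df = n - 1,
                            lower.tail = FALSE)
    }
    data.frame(contrast = paste(cn[i], "-", cn[j]), estimate = est,
               se = se, t = tval, df = n - 1L, p_unadjusted = p_un,
               p_tukey = max(p_tk, p_un))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  # A1.Bk - A2.Bk: condition effect within each subcomponent
  lv <- fit$level_names
  hl <- paste(paste0(lv[[1L]][1L], ".", lv[[2L]]), "-",
              paste0(lv[[1L]][2L], ".", lv[[2L]]))
  out$highlight <- out$contrast %in% hl
  attr(out, "family_size") <- 4L
  out
}
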