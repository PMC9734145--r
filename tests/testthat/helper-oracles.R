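# Independent oracles and small fixture builders used across tests.

# Brute-force edit distance by memoised recursion in pure R, independent of
# the package's dynamic-programming aligner.
brute_edit_distance <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > length(a)) return(length(b) - j + 1L)
    if (j > length(b)) return(length(a) - i + 1L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- min(rec(i + 1L, j + 1L) + (a[i] != b[j]),
             rec(i + 1L, j) + 1L,
             rec(i, j + 1L) + 1L)
    memo[[key]] <- v
    v
  }
  rec(1L, 1L)
}

# A miniature score with arbitrary pitch content, built on the fixture
# score's row structure.
score_from_pitches <- function(pitches) {
  s <- make_fixture_score("exp1", "articulation")[seq_along(pitches), ]
  s$pitch <- as.integer(pitches)
  s
}

# A performance object from a pitch vector: isochronous at the given IOI,
# durations set by a constant key-overlap.
perf_from_pitches <- function(pitches, ioi = 187.5, kot = -50,
                              velocity = 80, tempo = 80, ...) {
  n <- length(pitches)
  onset <- (seq_len(n) - 1L) * ioi
  offset <- onset + ioi + kot
  performance(tibble::tibble(pitch = pitches, onset_ms = onset,
                             offset_ms = offset,
                             velocity = rep(velocity, n)),
              cued_tempo_qbpm = tempo, ...)
}

# An error-free performance of a fixture score.
clean_perf_of <- function(score, ioi = 187.5, kot = -50, velocity = 80) {
  perf_from_pitches(score$pitch, ioi = ioi, kot = kot, velocity = velocity)
}

# 2x2 within-subjects ANOVA through base aov() Error() strata: the
# independent oracle for the in-repo sum-of-squares decomposition.
aov_oracle_2x2 <- function(Y) {
  n <- nrow(Y)
  long <- data.frame(
    value = as.vector(Y),
    subj = factor(rep(seq_len(n), 4L)),
    A = factor(rep(c("a1", "a1", "a2", "a2"), each = n)),
    B = factor(rep(c("b1", "b2", "b1", "b2"), each = n)))
  fit <- stats::aov(value ~ A * B + Error(subj / (A * B)), data = long)
  s <- summary(fit)
  get_row <- function(stratum, term) {
    tab <- s[[stratum]][[1L]]
    i <- grep(term, trimws(rownames(tab)), fixed = TRUE)
    tab[i, , drop = FALSE]
  }
  ss_subj <- s[["Error: subj"]][[1L]]["Residuals", "Sum Sq"]
  a <- get_row("Error: subj:A", "A")
  b <- get_row("Error: subj:B", "B")
  ab <- get_row("Error: subj:A:B", "A:B")
  err <- c(s[["Error: subj:A"]][[1L]]["Residuals", "Sum Sq"],
           s[["Error: subj:B"]][[1L]]["Residuals", "Sum Sq"],
           s[["Error: subj:A:B"]][[1L]]["Residuals", "Sum Sq"])
  eff <- c(a[1L, "Sum Sq"], b[1L, "Sum Sq"], ab[1L, "Sum Sq"])
  list(F = c(a[1L, "F value"], b[1L, "F value"], ab[1L, "F value"]),
       ges = eff / (eff + ss_subj + sum(err)))
}
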