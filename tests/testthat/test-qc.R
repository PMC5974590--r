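make_pq <- function(id, accs, outlier = rep(FALSE, length(accs)),
                    valid = !is.na(accs), prec = 0.15) {
  tr <- data.frame(
    target_id = paste0("t", seq_along(accs)), media = "m", onset_ms = 0,
    valid = valid, n_valid_samples = ifelse(valid, 50L, 0L),
    fix_start_ms = 0, fix_duration_ms = 500,
    accuracy_deg = accs, sd_x_deg = ifelse(valid, prec, NA),
    sd_y_deg = ifelse(valid, prec, NA), rms_x_deg = ifelse(valid, prec, NA),
    rms_y_deg = ifelse(valid, prec, NA), n_bridged_pairs = 0L,
    outlier = outlier, stringsAsFactors = FALSE
  )
  summarize_participant(tr, id, 60)
}

test_that("the 1.5-SD rule flags only large upper-tail outliers, order-free", {
  expect_equal(flag_outlier_trials(rep(1, 5)), rep(FALSE, 5))

  vals <- c(1.0, 1.1, 0.9, 1.0, 6.0)
  # brute-force mean/SD oracle
  thr <- mean(vals) + 1.5 * sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1))
  expect_identical(flag_outlier_trials(vals), vals > thr)
  expect_identical(which(flag_outlier_trials(vals)), 5L)

  # permutation invariance of the flagged set
  set.seed(2)
  perm <- sample(5)
  expect_identical(flag_outlier_trials(vals[perm]), (vals > thr)[perm])

  # upper-tail only: an equally extreme low value is never flagged
  low <- c(1.0, 1.1, 0.9, 1.0, 0.001)
  expect_false(any(flag_outlier_trials(low)))

  # NA (invalid trials) pass through unflagged
  expect_identical(flag_outlier_trials(c(vals, NA)), c(vals > thr, FALSE))
  expect_warning(f1 <- flag_outlier_trials(1), "fewer than 2")
  expect_false(any(f1))
})

test_that("inclusion decisions: exclude, review, include with reasons", {
  none <- make_pq("p0", rep(NA_real_, 5), valid = rep(FALSE, 5))
  d0 <- inclusion_decision(none)
  expect_equal(d0$decision, "exclude")
  expect_match(d0$reason, "no valid fixations")

  good <- make_pq("p1", rep(0.4, 5))
  expect_equal(inclusion_decision(good)$decision, "include")

  # one huge-error trial among four good ones warrants review, not exclusion
  flagged <- make_pq("p2", c(0.5, 0.6, 12, 0.5, 0.4))
  d2 <- inclusion_decision(flagged)
  expect_equal(d2$decision, "review")

  # never include with zero valid trials, whatever the thresholds
  expect_equal(inclusion_decision(none, max_mean_accuracy_deg = 100)$decision,
               "exclude")
})

test_that("group analysis pools trials for outlier flagging and is self-consistent", {
  ps <- list(make_pq("a", c(1.0, 1.1, 0.9, 1.0, 1.0)),
             make_pq("b", c(0.9, 1.0, 6.0, 1.1, 1.0)),
             make_pq("c", rep(NA_real_, 5), valid = rep(FALSE, 5)))
  gs <- analyze_group(ps, "demo")
  expect_equal(gs$n_recruited, 3)
  expect_equal(gs$n_excluded, 1)
  expect_equal(gs$n_outlier_trials, 1)
  flagged <- gs$trial_table[gs$trial_table$outlier, ]
  expect_equal(flagged$participant, "b")
  expect_equal(flagged$accuracy_deg, 6.0)
  # overall mean equals brute-force recomputation from surviving trials
  expect_equal(gs$overall$accuracy_mean,
               mean(c(mean(c(1.0, 1.1, 0.9, 1.0, 1.0)),
                      mean(c(0.9, 1.0, 1.1, 1.0)))), tolerance = 1e-9)
  surv <- gs$trial_table[gs$trial_table$valid & !gs$trial_table$outlier, ]
  per_part <- tapply(surv$accuracy_deg, surv$participant, mean)
  expect_equal(gs$overall$accuracy_mean, mean(per_part), tolerance = 1e-9)
})

test_that("identical runs compare as no-difference; unmatched are counted", {
  r1 <- list(make_pq("a", rep(1, 5)), make_pq("b", rep(1.2, 5)),
             make_pq("only1", rep(1, 5)))
  r2 <- list(make_pq("a", rep(1, 5)), make_pq("b", rep(1.2, 5)),
             make_pq("only2", rep(1, 5)))
  cmp <- compare_runs(r1, r2)
  expect_equal(cmp$n_pairs, 2)
  expect_equal(cmp$n_unmatched_run1, 1)
  expect_equal(cmp$n_unmatched_run2, 1)
  expect_true(all(cmp$tests$p_value == 1))
  expect_true(all(cmp$tests$note == "all differences zero"))
  expect_true(cmp$low_power)
  # a participant with no valid data in run 2 drops out of the pairing
  r2b <- list(make_pq("a", rep(1, 5)),
              make_pq("b", rep(NA_real_, 5), valid = rep(FALSE, 5)))
  expect_equal(compare_runs(r1, r2b)$n_pairs, 1)
})

test_that("paired signed-rank statistic and p match exhaustive enumeration", {
  acc1 <- c(1.31, 0.92, 1.70, 1.05, 1.44, 0.88)
  acc2 <- c(1.10, 1.05, 1.32, 0.95, 1.20, 1.15)
  r1 <- lapply(seq_along(acc1), function(i) make_pq(paste0("p", i), rep(acc1[i], 5)))
  r2 <- lapply(seq_along(acc2), function(i) make_pq(paste0("p", i), rep(acc2[i], 5)))
  cmp <- compare_runs(r1, r2, exact = TRUE)
  got <- cmp$tests[cmp$tests$measure == "mean_accuracy_deg", ]
  o <- oracle_signed_rank(acc1, acc2)
  expect_equal(got$statistic, o$V)
  expect_equal(got$p_value, o$p, tolerance = 1e-12)
})

test_that("group comparison wires Shapiro, Kruskal-Wallis, and Mann-Whitney", {
  g <- function(label, accs) lapply(seq_along(accs), function(i)
    make_pq(paste0(label, i), rep(accs[i], 5)))
  sep <- list(lo = g("l", c(1, 2, 3)), hi = g("h", c(4, 5, 6)))
  cmp <- compare_groups(sep, alpha_corrected = 0.008,
                        measures = "mean_accuracy_deg")
  pw <- cmp$measures$mean_accuracy_deg$pairwise
  expect_equal(pw$U, oracle_u(c(1, 2, 3), c(4, 5, 6)))  # = 0 by enumeration
  expect_false(pw$significant)  # n = 3 vs 3 cannot reach p < 0.008

  same <- list(a = g("a", c(1, 2, 3)), b = g("b", c(1, 2, 3)))
  cmp2 <- compare_groups(same, measures = "mean_accuracy_deg")
  pw2 <- cmp2$measures$mean_accuracy_deg$pairwise
  expect_equal(pw2$U, 3 * 3 / 2)  # null-symmetric value n1*n2/2
  expect_false(pw2$significant)
  kw <- cmp2$measures$mean_accuracy_deg$kruskal
  expect_gt(kw$p_value, 0.9)

  # groups of fewer than 2 usable members are omitted with a warning
  tiny <- list(a = g("a", c(1, 2, 3)), b = g("b", c(4, 5, 6)), c = g("c", 1))
  expect_warning(cmp3 <- compare_groups(tiny, measures = "mean_accuracy_deg"),
                 "fewer than 2")
  expect_equal(cmp3$groups, c("a", "b"))

  # Shapiro-Wilk screen matches stats::shapiro.test on a non-degenerate group
  set.seed(9)
  vals <- rnorm(8, 1, 0.3)
  norm <- list(a = g("a", vals), b = g("b", vals + 1))
  sw <- compare_groups(norm, measures = "mean_accuracy_deg")
  sh <- sw$measures$mean_accuracy_deg$shapiro
  expect_equal(sh$p_value[sh$group == "a"], shapiro.test(vals)$p.value,
               tolerance = 1e-9)
})

test_that("reports are deterministic, annotate the vendor band, handle empties", {
  empty <- render_report(list())
  expect_true(any(grepl("No participants", empty)))
  expect_true(any(grepl("0.4-0.9", empty)))
  expect_true(any(grepl("vendor-claimed", empty)))

  ps <- list(make_pq("a", c(1, 1.1, 0.9, 1, 1)), make_pq("b", c(2, 6, 1, 1, 1)))
  gs <- analyze_group(ps, "demo")
  r1 <- render_report(list(gs))
  r2 <- render_report(list(gs))
  expect_identical(r1, r2)
  expect_true(any(grepl("Group: demo", r1)))
})
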