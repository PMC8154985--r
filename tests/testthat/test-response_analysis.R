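test_that("loom_angle gives the closed-form visual angle", {
  expect_equal(loom_angle(0, 30), 0)
  expect_equal(loom_angle(5, 30), 2 * atan(2.5 / 30) * 180 / pi)
  expect_equal(loom_angle(5, 30), 9.5, tolerance = 0.005)
  # 50 mm dot at 30 mm: ~79.6 deg, within 0.3% of the quoted 79.4
  expect_equal(loom_angle(50, 30), 79.4, tolerance = 0.003)
  expect_error(loom_angle(5, 0), "positive")
  expect_error(loom_angle(-1, 30), "non-negative")
  # mean expansion rate of the 2 s, 5 mm loom: ~4.7 deg/s
  expect_equal(loom_expansion_rate(5, 30, 2), 4.7, tolerance = 0.02)
  # trajectory is monotone and hits the final angle
  th <- loom_angle_at(seq(0, 2, 0.1), 5, 30, 2)
  expect_true(all(diff(th) > 0))
  expect_equal(th[21], loom_angle(5, 30))
})

test_that("stimulus protocols validate ordering and overlap", {
  p <- stimulus_protocol(c(30, 10, 20), stim_duration = 5)
  expect_equal(p$presentations$onset, c(10, 20, 30))
  expect_error(stimulus_protocol(c(0, 3), stim_duration = 5), "overlap")
  lp <- looming_protocol()
  expect_equal(nrow(lp$presentations), 10)
  expect_equal(unique(diff(lp$presentations$onset)), 150)
})

test_that("build_regressors produces normalized, kernel-shaped regressors", {
  empty <- build_regressors(stimulus_protocol(numeric(0), numeric(0)),
                            duration = 50, rate = 1)
  expect_equal(ncol(empty$design), 1)            # intercept only
  expect_true(all(empty$design[, "intercept"] == 1))

  # a single one-sample epoch reproduces the kernel shifted to the onset
  p1 <- stimulus_protocol(10, stim_duration = 1)
  b1 <- build_regressors(p1, duration = 100, rate = 1, tau = 3.5)
  r <- b1$design[, 1]
  expect_equal(sum(b1$kernel), 1)                # unit-sum kernel
  expect_equal(which(r > 1e-12)[1], 11)          # starts at the onset sample
  expect_equal(r[11:40], b1$kernel[1:30], tolerance = 1e-9)

  # kernel normalization conserves the waveform area
  lp <- looming_protocol()
  bl <- build_regressors(lp, duration = 1800, rate = 1, tau = 3.5)
  expect_equal(sum(bl$design[, 1]), sum(bl$binary[, 1]), tolerance = 1e-6)

  # 10 presentations, 150 s apart: transients decay to < 1% before next onset
  on_idx <- lp$presentations$onset + 1
  pre_onset <- bl$design[on_idx[-1] - 1, 1]
  expect_true(all(pre_onset < 0.01 * max(bl$design[, 1])))

  # per-presentation mode: disjoint epochs give orthogonal binary waveforms
  bp <- build_regressors(lp, duration = 1800, rate = 1,
                         mode = "per_presentation")
  expect_equal(ncol(bp$design), 11)
  gram <- t(bp$binary) %*% bp$binary
  expect_true(all(gram[upper.tri(gram)] == 0))

  expect_error(build_regressors(lp, duration = 100, rate = 1),
               "outside the sampled interval")
})

test_that("fit_traces solves OLS exactly and matches the oracle", {
  lp <- looming_protocol()
  basis <- build_regressors(lp, duration = 1800, rate = 1)
  reg <- basis$design[, 1]

  # exact fit: trace = 2 * regressor + 1
  tm <- trace_matrix(matrix(2 * reg + 1, nrow = 1), rate = 1)
  st <- fit_traces(tm, basis)
  expect_equal(st$beta, 2, tolerance = 1e-9)
  expect_equal(st$intercept, 1, tolerance = 1e-9)
  expect_lte(st$mse, 1e-12)
  expect_equal(st$score, Inf)                    # noiseless sentinel

  # noisy fit equals the normal-equations oracle to 1e-9
  set.seed(11)
  y <- reg + stats::rnorm(1800, 0, 0.1)
  stn <- fit_traces(trace_matrix(matrix(y, nrow = 1), rate = 1), basis)
  oc <- oracle_ols(basis$design, y)
  expect_equal(stn$beta, unname(oc[1]), tolerance = 1e-9)
  expect_equal(stn$intercept, unname(oc[2]), tolerance = 1e-9)
  expect_equal(stn$beta, 1, tolerance = 0.1)

  # oracle equivalence with multiple regressors
  bp <- build_regressors(lp, duration = 1800, rate = 1,
                         mode = "per_presentation")
  set.seed(12)
  y2 <- bp$design %*% c(stats::runif(10), 5) + stats::rnorm(1800, 0, 0.2)
  st2 <- fit_traces(trace_matrix(matrix(y2, nrow = 1), rate = 1), bp)
  oc2 <- oracle_ols(bp$design, as.numeric(y2))
  expect_equal(as.numeric(attr(st2, "coefficients")), unname(oc2), tolerance = 1e-9)

  expect_error(fit_traces(trace_matrix(matrix(1, 1, 10), rate = 1), basis),
               "different time lengths")
  bad <- basis
  bad$design <- cbind(basis$design, basis$design[, 1])
  expect_error(fit_traces(tm, bad), "rank-deficient")
})

test_that("pure-noise traces score below planted responders", {
  lp <- looming_protocol()
  basis <- build_regressors(lp, duration = 1800, rate = 1)
  set.seed(21)
  reg <- basis$design[, 1]
  n_noise <- 50
  traces <- rbind(matrix(reg * 120, 5, 1800, byrow = TRUE) +
                    matrix(stats::rnorm(1800 * 5, 0, 1), 5, 1800),
                  matrix(stats::rnorm(1800 * n_noise), n_noise, 1800))
  st <- fit_traces(trace_matrix(traces, rate = 1), basis)
  expect_true(min(st$score[1:5]) > max(st$score[6:55]))
})

test_that("select_responsive takes the top quantile with a stable tie rule", {
  mk <- function(score) {
    s <- data.frame(trace = seq_along(score), beta = score, intercept = 0,
                    mse = 1, score = score)
    class(s) <- c("score_table", class(s))
    s
  }
  set.seed(3)
  sel <- select_responsive(mk(stats::rnorm(1000)), 0.05)
  expect_equal(sum(sel$responsive), 50)
  expect_equal(attr(sel, "n_selected"), 50)
  # the selected are exactly the 50 largest
  expect_equal(sort(which(sel$responsive)),
               sort(order(-sel$score)[1:50]))
  # quoted bookkeeping: top 5% of 47,992 scores is 2,400
  sel_big <- select_responsive(mk(stats::rnorm(47992)), 0.05)
  expect_equal(sum(sel_big$responsive), 2400)
  # all-equal scores: first ceil(f N) by index
  sel_tie <- select_responsive(mk(rep(1, 100)), 0.05)
  expect_equal(which(sel_tie$responsive), 1:5)
})

test_that("zscore_events finds threshold-crossing peaks", {
  expect_equal(nrow(zscore_events(trace_matrix(matrix(3, 1, 100), rate = 1),
                                  1:50)), 0)     # constant trace: no events
  set.seed(7)
  base <- stats::rnorm(200)
  tr <- base
  tr[120:126] <- tr[120:126] + 10 * c(2, 4, 7, 10, 7, 4, 2) / 10 * stats::sd(base[1:50]) * 10
  tm <- trace_matrix(matrix(tr, 1), rate = 1)
  ev5 <- zscore_events(tm, 1:50, threshold = 5)
  expect_equal(nrow(ev5), 1)                     # one planted transient
  expect_equal(ev5$sample, 123)                  # at its peak
  # threshold monotonicity: events at 6 are a subset of events at 5
  set.seed(8)
  tr2 <- stats::rnorm(500)
  tr2[c(100, 300, 400)] <- c(5.5, 6.5, 12)
  tm2 <- trace_matrix(matrix(tr2, 1), rate = 1)
  e5 <- zscore_events(tm2, 1:80, threshold = 5)$sample
  e6 <- zscore_events(tm2, 1:80, threshold = 6)$sample
  expect_true(all(e6 %in% e5))
  expect_gte(length(e5), length(e6))
  # flat baseline on a varying trace is an error
  tmv <- trace_matrix(matrix(c(rep(1, 50), 5, rep(1, 49)), 1), rate = 1)
  expect_error(zscore_events(tmv, 1:50), "zero baseline SD")
  expect_error(zscore_events(tm2, 490:510), "outside")
})
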