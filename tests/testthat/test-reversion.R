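test_that("reversion detection needs both displacement and duration", {
  mono <- make_fixture("line", list(v = 400, duration = 10))
  expect_length(detect_reversions(mono), 0)

  # forward run then a 300 nm backtrack lasting 1.5 s
  t <- seq(0, 6.5, by = 0.01)
  x <- ifelse(t <= 5, 400 * t, 2000 - 200 * (t - 5))
  ev <- detect_reversions(data.frame(t = t, x = x))
  expect_length(ev, 1)
  expect_equal(ev[[1]]$direction, 1)
  expect_equal(ev[[1]]$t_rev, 5, tolerance = 0.1)

  # same backtrack but too fast (0.5 s): rejected by the duration filter
  t2 <- seq(0, 5.6, by = 0.01)
  x2 <- ifelse(t2 <= 5, 400 * t2, 2000 - 600 * (t2 - 5))
  expect_length(detect_reversions(data.frame(t = t2, x = x2)), 0)

  # 200 nm backtrack: rejected by the displacement filter
  t3 <- seq(0, 7, by = 0.01)
  x3 <- ifelse(t3 <= 5, 400 * t3, 2000 - 100 * (t3 - 5))
  expect_length(detect_reversions(data.frame(t = t3, x = x3)), 0)
})

test_that("raising the detection thresholds never finds more events", {
  trajs <- small_rs(10, seed = 23)
  count <- function(mb, md)
    sum(vapply(trajs,
               function(tr) length(detect_reversions(tr, min_back = mb,
                                                     min_dur = md)), 0))
  base <- count(250, 1)
  expect_lte(count(400, 1), base)
  expect_lte(count(250, 2), base)
  expect_lte(count(600, 3), count(400, 2))
})

test_that("saturating-exponential fits recover noiseless curves exactly", {
  for (A in c(604, -350, 120)) {
    for (tr in c(0.1, 0.75)) {
      for (off in c(-50, 0, 53)) {
        t <- seq(0, 4 * tr, by = 0.01)
        x <- A * (1 - exp(-t / tr)) + off
        fit <- fit_saturating_exponential(t, x)
        expect_equal(fit$A, A, tolerance = 1e-6)
        expect_equal(fit$t_r, tr, tolerance = 1e-6)
        expect_equal(fit$offset, off, tolerance = 1e-5)
      }
    }
  }
})

test_that("the full pipeline recovers rise times from wave-shaped fixtures", {
  for (case in list(list(tr = 0.75, sd = 0), list(tr = 0.75, sd = 10),
                    list(tr = 0.4, sd = 10), list(tr = 0.1, sd = 10))) {
    fx <- make_fixture("exp_reversion",
                       list(t_r = case$tr, A = 604, offset = 53,
                            noise_sd = case$sd), seed = 3)
    evs <- detect_reversions(fx)
    expect_length(evs, 1)
    ev <- fit_rise_time(evs[[1]], fx)
    expect_true(ev$fitted)
    expect_equal(ev$t_r_ms, case$tr * 1000, tolerance = 0.1)
  }
})

test_that("noisy rise-time recovery stays within ten percent", {
  errs <- vapply(1:25, function(r) {
    fx <- make_fixture("exp_reversion",
                       list(t_r = 0.3, A = 500, noise_sd = 10), seed = r)
    evs <- detect_reversions(fx)
    if (length(evs) == 0) return(NA_real_)
    ev <- fit_rise_time(evs[[1]], fx)
    if (!isTRUE(ev$fitted)) return(NA_real_)
    abs(ev$t_r_ms - 300) / 300
  }, 0)
  expect_gt(mean(!is.na(errs)), 0.8)
  expect_lt(stats::median(errs, na.rm = TRUE), 0.1)
})

test_that("a purely linear approach yields no measurable rise time", {
  t <- seq(0, 6.5, by = 0.01)
  x <- ifelse(t <= 5, 400 * t, 2000 - 200 * (t - 5))
  ev <- detect_reversions(data.frame(t = t, x = x))[[1]]
  fit <- fit_rise_time(ev, data.frame(t = t, x = x))
  expect_false(fit$fitted)
})

test_that("the exponential-decay scale of a known sample is recovered", {
  set.seed(7)
  draws <- stats::rexp(500, rate = 1 / 200)
  st <- rise_time_statistics(draws)
  expect_equal(st$flag, "ok")
  expect_equal(st$t_r_ms, 200, tolerance = 0.15)
  expect_true(st$se_ms > 0)
  expect_equal(rise_time_statistics(draws[1:5])$flag, "too_few_events")
})

test_that("wave-shaped reversions follow a forward-motor detachment", {
  ens <- acc_ensemble("rs")
  rv <- ens$reversions
  # the symmetric ensemble reverses out of runs in both directions
  expect_gt(sum(rv$direction == 1), 5)
  expect_gt(sum(rv$direction == -1), 5)
  fwd <- rv[rv$fitted & rv$direction == 1, ]
  skip_if(nrow(fwd) < 20)
  # re-simulate the trajectories of the first events and look for a
  # forward-team detachment shortly before the reversal
  triggered <- vapply(seq_len(min(nrow(fwd), 40)), function(r) {
    tr <- simulate(canonical_config("rs"), seed = 2024,
                   stream = fwd$traj[r] - 1L)
    i_rev <- which.min(abs(tr$t - fwd$t_rev[r]))
    win <- max(1, i_rev - 50):min(length(tr$t), i_rev + 10)
    any(diff(tr$nf[win]) < 0)
  }, NA)
  expect_gt(mean(triggered), 0.5)
})
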