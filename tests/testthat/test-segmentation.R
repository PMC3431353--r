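test_that("processive-period selection handles canonical path shapes", {
  line <- make_fixture("line", list(v = 500, duration = 10))
  iv <- select_processive_periods(line)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 1)
  expect_equal(iv$end, nrow(line))
  expect_equal(iv$direction, 1L)

  tri <- make_fixture("triangle", list(v = 400, half_period = 2, duration = 4))
  iv2 <- select_processive_periods(tri)
  expect_equal(nrow(iv2), 2)
  expect_equal(iv2$direction, c(1L, -1L))
  expect_false(any(iv2$end[1] >= iv2$start[2]))   # disjoint

  short <- make_fixture("line", list(v = 500, duration = 0.2))
  expect_equal(nrow(select_processive_periods(short)), 0)
})

test_that("segment extraction applies the speed and linearity filters", {
  line <- make_fixture("line", list(v = 400, duration = 8))
  ss <- extract_segments(line)
  expect_gt(nrow(ss$segments), 0)
  expect_equal(unique(round(ss$segments$v, 6)), 400)
  expect_true(all(abs(ss$segments$r) > 0.999999))

  slow <- make_fixture("line", list(v = 50, duration = 8))
  expect_equal(nrow(extract_segments(slow)$segments), 0)

  # heavy localization noise destroys the within-window linearity
  noisy <- make_fixture("line", list(v = 400, duration = 8, noise_sd = 200),
                        seed = 4)
  iv <- data.frame(start = 1, end = nrow(noisy), direction = 1,
                   displacement = 400 * 8)
  expect_equal(nrow(extract_segments(noisy, iv)$segments), 0)

  # backward motion passes the filters symmetrically
  back <- make_fixture("line", list(v = -400, duration = 8))
  ivb <- data.frame(start = 1, end = nrow(back), direction = -1,
                    displacement = -3200)
  ssb <- extract_segments(back, ivb)
  expect_gt(nrow(ssb$segments), 0)
  expect_true(all(ssb$segments$direction == -1L))
})

test_that("raising the linearity threshold never admits more segments", {
  traj <- small_rs()[[1]]
  counts <- vapply(c(0.9, 0.95, 0.98, 0.99, 0.995),
                   function(th) nrow(extract_segments(traj,
                                                      min_corr = th)$segments),
                   0)
  expect_true(all(diff(counts) <= 0))
})

test_that("state-resolved histogram weights partition the totals bin-wise", {
  segs <- tugsim:::combine_segment_sets(lapply(small_rs(), extract_segments))
  skip_if(nrow(segs$segments) < 5)
  h <- velocity_histogram(segs, mode = "count")
  expect_equal(unname(rowSums(h$pulling)), h$weights, tolerance = 1e-9)
  expect_equal(unname(rowSums(h$attachment)), h$weights, tolerance = 1e-9)
  hm <- velocity_histogram(segs, mode = "max1")
  expect_equal(max(hm$weights), 1)
  expect_equal(unname(rowSums(hm$pulling)), hm$weights, tolerance = 1e-9)
})

test_that("occupancy weighting distributes a segment across its states", {
  # hand-built segment set: one segment fully in pulling state (2,0),
  # one split half-and-half between (2,1) and (2,0)
  segs <- structure(list(
    segments = data.frame(start = c(1, 41), v = c(400, 400), r = c(1, 1),
                          direction = c(1L, 1L)),
    states = data.frame(
      seg = c(1L, 2L, 2L),
      qf = c(2L, 2L, 2L), qb = c(0L, 1L, 0L),
      nf = c(2L, 2L, 2L), nb = c(0L, 1L, 0L),
      frac = c(1, 0.5, 0.5)),
    seg_len = 40, sample_dt = 0.01), class = "segment_set")
  h <- velocity_histogram(segs, mode = "count")
  bin <- which(h$weights > 0)
  expect_length(bin, 1)
  expect_equal(h$weights[bin], 2)
  expect_equal(h$pulling[bin, "(2,0)"], 1.5)
  expect_equal(h$pulling[bin, "(2,1)"], 0.5)
})

test_that("backward fraction is the share of negative-slope segments", {
  segs <- structure(list(
    segments = data.frame(start = 1:4, v = c(300, -300, 500, 200),
                          r = rep(1, 4), direction = c(1L, -1L, 1L, 1L)),
    states = NULL, seg_len = 40, sample_dt = 0.01), class = "segment_set")
  expect_equal(backward_fraction(segs), 0.25)
  empty <- structure(list(segments = segs$segments[0, ], states = NULL),
                     class = "segment_set")
  expect_error(backward_fraction(empty), "no accepted segments")
})

test_that("mu equals the area quotient of the pooled spatial histograms", {
  trajs <- small_rs(12, seed = 17)
  res <- motor_spatial_distribution(trajs, c(100, 600))
  skip_if(res$n_samples == 0)
  mids <- res$d_breaks[-1] - diff(res$d_breaks) / 2
  area_f <- sum(res$forward[mids > 110])
  area_b <- sum(res$backward[mids < -110])
  expect_equal(area_f / area_b, res$mu, tolerance = 1e-9)
  expect_equal(res$mu, res$n_pulling_forward / res$n_pulling_backward)
})

test_that("the symmetric reference system is statistically direction-blind", {
  segs <- acc_ensemble("rs")$segments$segments
  expect_equal(mean(segs$v < 0), 0.5, tolerance = 0.12)
  expect_equal(mean(abs(segs$v[segs$v > 0])), mean(abs(segs$v[segs$v < 0])),
               tolerance = 0.1)
})

test_that("mu is flagged when no backward motor pulls or no segment matches", {
  cfg <- referential_set(N_b = 0, seed = 6)
  cfg$forward$count <- 2L
  trajs <- simulate_ensemble(cfg, 4, base_seed = 6)
  res <- motor_spatial_distribution(trajs, c(100, 900))
  skip_if(res$n_samples == 0)
  expect_true(is.infinite(res$mu))
  expect_true(res$no_backward_pulling)
  res2 <- motor_spatial_distribution(trajs, c(5000, 6000))
  expect_true(is.na(res2$mu))
  expect_true(res2$no_segments)
})
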