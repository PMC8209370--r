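# Hand-checkable score fixtures: build a feature_set and reference directly.
make_fs <- function(mf, lat, bf_mean, bf_sd, ids_step = paste0("s", seq_along(mf)),
                    ids_sin = paste0("b", seq_along(bf_mean))) {
  structure(list(
    steps = data.frame(protocol_id = ids_step, amplitude_pA = 10,
                       mean_frequency_Hz = mf, latency_s = lat,
                       stringsAsFactors = FALSE),
    sinusoids = data.frame(protocol_id = ids_sin, amplitude_pA = 6,
                           frequency_Hz = 8, burst_mean_Hz = bf_mean,
                           burst_sd_Hz = bf_sd, stringsAsFactors = FALSE),
    cycles = list(), valid = TRUE), class = "feature_set")
}

make_ref <- function(mf, lat, bf, ids_step = paste0("s", seq_along(mf)),
                     ids_sin = paste0("b", seq_along(bf))) {
  reference_features(data.frame(
    protocol_id = c(ids_step, ids_step, ids_sin),
    feature = c(rep("mean_frequency", length(mf)),
                rep("first_spike_latency", length(lat)),
                rep("burst_frequency", length(bf))),
    value = c(mf, lat, bf),
    units = c(rep("Hz", length(mf)), rep("s", length(lat)),
              rep("Hz", length(bf))), stringsAsFactors = FALSE))
}

test_that("score components reproduce hand-computed sums", {
  # errors of 2, 3, 1 Hz over three steps at weight 1
  sim <- make_fs(mf = c(42, 53, 61), lat = c(0.05, 0.03, 0.02),
                 bf_mean = 50, bf_sd = 0)
  ref <- make_ref(mf = c(40, 50, 60), lat = c(0.05, 0.03, 0.02), bf = 50)
  expect_equal(mean_frequency_score(sim, ref), 6)
  expect_equal(latency_score(sim, ref), 0)
  expect_equal(burst_score(sim, ref), 0)

  # a 1 ms latency lag scores exactly 1 under the default weights,
  # the same as a 1 Hz mean-frequency error
  sim1 <- make_fs(mf = 41, lat = 0.051, bf_mean = 50, bf_sd = 0)
  ref1 <- make_ref(mf = 40, lat = 0.050, bf = 50)
  expect_equal(latency_score(sim1, ref1), 1.0)
  expect_equal(mean_frequency_score(sim1, ref1), 1.0)

  # a full 1 s lag scales linearly to 1000
  sim2 <- make_fs(mf = 40, lat = 1.05, bf_mean = 50, bf_sd = 0)
  expect_equal(latency_score(sim2, ref1), 1000)
})

test_that("burst score multiplies the error by the stability penalty (sd + 1)", {
  # constant 50 Hz across ten cycles against a 40 Hz target
  sim <- make_fs(mf = 40, lat = 0.05, bf_mean = 50, bf_sd = 0)
  ref <- make_ref(mf = 40, lat = 0.05, bf = 40)
  expect_equal(burst_score(sim, ref), 10)

  # alternating 40/60 (mean 50, population sd 10) against a 50 Hz target:
  # the sd factor multiplies a zero difference
  cyc <- rep(c(40, 60), 5)
  sim2 <- make_fs(mf = 40, lat = 0.05, bf_mean = mean(cyc),
                  bf_sd = sqrt(mean((cyc - mean(cyc))^2)))
  expect_equal(sim2$sinusoids$burst_sd_Hz, 10)
  ref2 <- make_ref(mf = 40, lat = 0.05, bf = 50)
  expect_equal(burst_score(sim2, ref2), 0)

  # nonzero error with the same spread: |55-50| * (10+1)
  sim3 <- make_fs(mf = 40, lat = 0.05, bf_mean = 55, bf_sd = 10)
  expect_equal(burst_score(sim3, ref2), 55)
})

test_that("totals are exact sums and respect weight linearity", {
  sim <- make_fs(mf = c(42, 53, 61), lat = c(0.051, 0.03, 0.02),
                 bf_mean = 50, bf_sd = 0)
  ref <- make_ref(mf = c(40, 50, 60), lat = c(0.05, 0.03, 0.02), bf = 40)
  sb <- total_score(sim, ref)
  expect_identical(sb$total, sb$score_mean_frequency + sb$score_latency +
                     sb$score_burst_frequency)
  expect_equal(sb$total, 6 + 1 + 10)

  w2 <- feature_weights(mean_frequency = 2)
  sb2 <- total_score(sim, ref, w2)
  expect_equal(sb2$score_mean_frequency, 2 * sb$score_mean_frequency)
  expect_equal(sb2$score_latency, sb$score_latency)
  expect_equal(sb2$score_burst_frequency, sb$score_burst_frequency)
})

test_that("a candidate scores exactly zero against its own synthetic reference", {
  p <- example_parameters(2)
  suite <- mini_suite()
  ref <- generate_reference(p, suite)
  sb <- total_score(extract_features(p, suite), ref)
  expect_identical(sb$total, 0)
  expect_false(sb$penalty_applied)
})

test_that("invalid candidates get the finite penalty, mismatches error", {
  sim <- make_fs(mf = 40, lat = 0.05, bf_mean = 50, bf_sd = 0)
  sim$valid <- FALSE
  ref <- make_ref(mf = 40, lat = 0.05, bf = 50)
  sb <- total_score(sim, ref)
  expect_true(sb$penalty_applied)
  expect_equal(sb$total, DIVERGENCE_PENALTY)

  ref_other <- make_ref(mf = 40, lat = 0.05, bf = 50, ids_step = "other")
  sim$valid <- TRUE
  expect_error(total_score(sim, ref_other), "missing")
})

test_that("reference schema rejects latencies not stored in seconds", {
  expect_error(reference_features(data.frame(
    protocol_id = "s1", feature = "first_spike_latency",
    value = 52, units = "ms", stringsAsFactors = FALSE)), "seconds")
  expect_error(reference_features(data.frame(
    protocol_id = "s1", feature = "mean_frequency",
    value = 40, units = "s", stringsAsFactors = FALSE)), "units")
})
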