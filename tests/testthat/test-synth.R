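# contiguous regions of the rectified envelope above a threshold
count_bursts <- function(x, rate, threshold = 0.25) {
  w <- as.integer(0.05 * rate)
  env <- stats::filter(abs(x), rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  above <- env > threshold * max(env)
  sum(diff(c(FALSE, above)) == 1)
}

test_that("a noise-free normal recording contains its S1 and S2 bursts", {
  spec <- synth_spec(heart_rate_bpm = 60, noise_sigma = 0, duration_s = 6,
                     seed = 1)
  rec <- generate_recording(spec)
  expect_equal(length(rec$samples), 12000)
  expect_equal(rec$rate, 2000)
  expect_equal(rec$label, "normal")
  # 6 cycles at 60 bpm: 6 S1 + 6 S2 bursts on the envelope
  expect_equal(count_bursts(rec$samples, 2000), 12)
  # suppressing S2 entirely leaves only the 6 S1 bursts
  spec_m <- synth_spec(heart_rate_bpm = 60, noise_sigma = 0,
                       anomaly_kind = "missing_s2", anomaly_strength = 1,
                       duration_s = 6, seed = 1)
  expect_equal(count_bursts(generate_recording(spec_m)$samples, 2000), 6)
  # an ectopic burst adds one extra burst per cycle
  spec_e <- synth_spec(heart_rate_bpm = 60, noise_sigma = 0,
                       anomaly_kind = "ectopic_burst", duration_s = 6,
                       seed = 1)
  expect_equal(count_bursts(generate_recording(spec_e)$samples, 2000), 18)
})

test_that("generation is seed-deterministic with zero-strength identity", {
  spec <- synth_spec(seed = 123)
  expect_identical(generate_recording(spec)$samples,
                   generate_recording(spec)$samples)
  # zero-strength anomalies reduce to the anomaly-free waveform
  for (k in c("murmur", "ectopic_burst", "missing_s2")) {
    s0 <- synth_spec(anomaly_kind = k, anomaly_strength = 0, seed = 123)
    expect_equal(generate_recording(s0)$samples,
                 generate_recording(spec)$samples, tolerance = 1e-12)
    expect_equal(generate_recording(s0)$label, "abnormal")
  }
})

test_that("anomalies only touch their time support under matched seeds", {
  base <- generate_recording(synth_spec(heart_rate_bpm = 60, seed = 9))$samples
  murm <- generate_recording(synth_spec(heart_rate_bpm = 60, seed = 9,
                                        anomaly_kind = "murmur"))$samples
  d <- abs(murm - base) > 1e-12
  # changed samples fall inside systolic windows [t0+0.05, t0+0.35] per cycle
  t <- (which(d) - 1) / 2000
  phase <- t %% 1  # 60 bpm: 1-s cycles
  expect_true(all(phase >= 0.05 - 1e-9 & phase <= 0.35 + 1e-9))
  expect_gt(sum(d), 0)
  # missing_s2 only alters samples in the S2 burst supports
  miss <- generate_recording(synth_spec(heart_rate_bpm = 60, seed = 9,
                                        anomaly_kind = "missing_s2"))$samples
  d2 <- which(abs(miss - base) > 1e-12)
  phase2 <- ((d2 - 1) / 2000) %% 1
  expect_true(all(phase2 >= 0.35 - 1e-9 & phase2 <= 0.55 + 1e-9))
})

test_that("dataset generation balances domains and is reproducible", {
  out <- generate_dataset(9, 3, seed = 31)
  expect_length(out$dataset, 12)
  labs <- dataset_labels(out$dataset)
  expect_equal(sum(labs == "normal"), 9)
  expect_equal(sum(labs == "abnormal"), 3)
  doms <- table(vapply(out$dataset, `[[`, character(1), "domain_id"))
  expect_equal(unname(as.vector(doms)), c(6, 6))
  expect_equal(out$manifest$recording_id,
               unname(vapply(out$dataset, `[[`, character(1), "recording_id")))
  # abnormals cycle through the three anomaly kinds
  expect_setequal(out$manifest$anomaly_kind[labs == "abnormal"],
                  c("murmur", "ectopic_burst", "missing_s2"))
  out2 <- generate_dataset(9, 3, seed = 31)
  expect_identical(lapply(out$dataset, `[[`, "samples"),
                   lapply(out2$dataset, `[[`, "samples"))
  expect_error(generate_dataset(0, 0), "at least one")
})

test_that("wider domain spread increases between-domain feature distance", {
  # per-band standardization deliberately cancels static coloration, so the
  # domain gap is driven by noise level (burst-to-floor contrast), jointly
  # widened with tilt here
  mean_sf_dist <- function(gap) {
    doms <- list(list(name = "d1", noise_sigma = 0.05,
                      spectral_tilt = -gap, heart_rate_bpm = 75),
                 list(name = "d2", noise_sigma = 0.05 * (1 + 6 * gap),
                      spectral_tilt = gap, heart_rate_bpm = 75))
    dd <- generate_dataset(12, 0, domains = doms, seed = 77)
    sf <- preprocess_dataset(dd$dataset)
    doms_of <- vapply(dd$dataset, `[[`, character(1), "domain_id")
    m1 <- colMeans(do.call(rbind, sf[doms_of == "d1"]))
    m2 <- colMeans(do.call(rbind, sf[doms_of == "d2"]))
    sqrt(sum((m1 - m2)^2))
  }
  expect_gt(mean_sf_dist(0.8), mean_sf_dist(0.05))
})
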