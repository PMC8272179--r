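simple_fall_template <- function(noise_sd = 0.03) {
  # 12 s plan: 4.5 rest | 0.5 descent | 0.3 impact | 6.7 rest
  activity_template("fall_simple", "fall",
                    list(phase_rest(4.5),
                         phase_descent(0.5, c(0.1, 0.4)),
                         phase_impact(0.3, c(2, 8)),
                         phase_rest(6.7)),
                    noise_sd = noise_sd)
}

test_that("sample count is sampling rate times template duration", {
  cfg <- generator_config(seed = 1)
  rec <- generate_fall_record(simple_fall_template(), cfg, seed = 2)
  expect_equal(rec$N, 1200L)  # 12 s at 100 Hz
})

test_that("a noise-free rest-only record reads exactly 1 g", {
  tpl <- activity_template("rest_only", "adl", list(phase_rest(5)),
                           noise_sd = 0)
  cfg <- generator_config(seed = 1)
  rec <- generate_adl_record(tpl, cfg, seed = 9)
  expect_equal(compute_avm(rec)$values, rep(1, 500))
})

test_that("fall records reproduce the three-phase morphology", {
  cfg <- generator_config(seed = 1)
  rec <- generate_fall_record(simple_fall_template(), cfg, seed = 7)
  v <- compute_avm(rec)$values
  pk <- attr(rec, "primary_index")
  # independent re-generation: same seed, same maximum
  rec2 <- generate_fall_record(simple_fall_template(), cfg, seed = 7)
  expect_identical(max(v), max(compute_avm(rec2)$values))
  expect_gte(max(v), 1.6)
  expect_lte(max(v), 8 + 4 * 0.03)  # amplitude draw plus noise allowance
  # at least 4 s on both sides of the primary peak
  expect_gte(pk / rec$fs_hz, 4)
  expect_gte((rec$N - pk) / rec$fs_hz, 4)
  # pre-impact descent dips below 1 g just before the peak
  expect_lt(mean(v[(pk - 40):(pk - 25)]), 1)
  # rest phase sits at 1 g within noise
  expect_equal(mean(v[(pk + 200):rec$N]), 1, tolerance = 0.02)
})

test_that("a too-short fall template is rejected", {
  tpl <- activity_template("short", "fall",
                           list(phase_rest(1), phase_impact(0.3, c(2, 4)),
                                phase_rest(6)))
  expect_error(generate_fall_record(tpl, generator_config(seed = 1), 3),
               "4 s")
})

test_that("walking defeats the quiet period except at the record boundary", {
  tpl <- default_templates(difficulty = 0)$adl_walk
  cfg <- generator_config(seed = 1)
  det <- detector_config(threshold = 1.5)
  for (seed in 1:5) {
    rec <- generate_adl_record(tpl, cfg, seed)
    av <- compute_avm(rec)
    expect_gt(max(av$values), 1.5)       # steps do cross the threshold
    ev <- detect_events(av, det)
    # every surviving event hugs the end of the record (truncated quiet
    # window); none has the 4 s tail margin, so none is retained
    expect_lte(nrow(ev), 1L)
    if (nrow(ev)) {
      expect_gt(ev$t0_time_s, record_duration(rec) - 2.5)
    }
    out <- build_event_centered(list(rec), det)
    expect_length(out$ecrs, 0L)
  }
})

test_that("an impact-like ADL yields exactly one potential event", {
  tpl <- activity_template("sit", "adl",
                           list(phase_rest(5), phase_impact(0.3, 2),
                                phase_rest(5)))
  rec <- generate_adl_record(tpl, generator_config(seed = 1), seed = 4)
  ev <- detect_events(compute_avm(rec), detector_config(threshold = 1.5))
  expect_equal(nrow(ev), 1L)
})

test_that("low-peak ADL never cross a 1.33 g threshold", {
  tpl <- default_templates(difficulty = 0)$adl_slow
  cfg <- generator_config(seed = 1)
  for (seed in 1:5) {
    rec <- generate_adl_record(tpl, cfg, seed)
    ev <- detect_events(compute_avm(rec), detector_config(threshold = 1.33))
    expect_equal(nrow(ev), 0L)
  }
})

test_that("datasets are reproducible and correctly sized", {
  cfg <- generator_config(n_fall_records = 10, n_adl_records = 10, seed = 33)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(lapply(ds1$records, `[[`, "ax"),
                   lapply(ds2$records, `[[`, "ax"))
  expect_equal(nrow(ds1$manifest), 20L)
  expect_equal(as.integer(table(ds1$manifest$class)[c("fall", "adl")]),
               c(10L, 10L))
  # written manifests are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds1, d1); write_dataset(ds2, d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  back <- read_dataset(d1)
  expect_equal(back$records[["R0001"]]$ax, ds1$records[["R0001"]]$ax,
               tolerance = 1e-12)
})

test_that("error injection hits exactly the configured share of records", {
  cfg <- generator_config(n_fall_records = 10, n_adl_records = 0,
                          error_spike_frac = 0.2, seed = 12)
  ds <- generate_dataset(cfg)
  peaks <- vapply(ds$records, function(r) max(compute_avm(r)$values),
                  numeric(1))
  expect_equal(sum(peaks > 30), 2L)
  expect_equal(sum(ds$manifest$error_type == "avm_over_30g"), 2L)

  cfg2 <- generator_config(n_fall_records = 10, n_adl_records = 5,
                           error_lowpeak_frac = 0.3, seed = 13)
  ds2 <- generate_dataset(cfg2)
  man2 <- ds2$manifest
  expect_equal(sum(man2$error_type == "fall_peak_under_1p1g"), 3L)
  weak <- ds2$records[man2$error_type == "fall_peak_under_1p1g"]
  expect_true(all(vapply(weak, function(r) max(compute_avm(r)$values),
                         numeric(1)) < 1.1))
})

test_that("generator config round-trips through YAML", {
  cfg <- generator_config(n_fall_records = 7, n_adl_records = 3,
                          difficulty = 0.5, error_spike_frac = 0.1,
                          seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$n_fall_records, 7L)
  expect_equal(back$difficulty, 0.5)
  expect_equal(back$seed, 99L)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(back)
  expect_identical(ds1$manifest, ds2$manifest)
})

test_that("short-tail falls are generated, detected, but not retained", {
  cfg <- generator_config(n_fall_records = 10, n_adl_records = 0,
                          short_tail_frac = 0.3, seed = 41)
  ds <- generate_dataset(cfg)
  expect_equal(sum(ds$manifest$short_tail), 3L)
  th <- calibrate_threshold(ds, cfg = detector_config())
  out <- build_event_centered(qc_kept_records(ds),
                              detector_config(threshold = th))
  ret <- out$retention
  expect_gt(ret$n_fall[ret$margin_s == 0],
            ret$n_fall[ret$margin_s == 4])
})
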