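test_that("sweep and site constructors enforce their invariants", {
  expect_error(new_sweep(numeric(0), 20000), "at least 2 samples")
  expect_error(new_sweep(1, 20000), "at least 2 samples")
  expect_error(new_sweep(c(1, NA), 20000), "finite")
  expect_error(new_sweep(1:10, 10000), "20-50 kHz")
  expect_silent(new_sweep(1:10, 10000, strict = FALSE))
  expect_error(recording_site("dendrite", -5), "non-negative")
  expect_error(recording_site("dendrite", 350), "300")
  expect_error(recording_site("soma", 20), "distance_um = 0")
  expect_error(stim_protocol(c(0, 0.1, 0.05), "TBS"), "strictly increasing")
})

test_that("the TBS protocol expands to 4 x 10 x 10 = 400 pulses", {
  p <- tbs_protocol()
  expect_length(p$pulse_times, 400)
  expect_true(all(diff(p$pulse_times) > 0))
  # episode starts every 10 s, bursts every 200 ms, stimuli every 10 ms
  expect_equal(p$pulse_times[101] - p$pulse_times[1], 10)
  expect_equal(p$pulse_times[11] - p$pulse_times[1], 0.2)
  expect_equal(p$pulse_times[2] - p$pulse_times[1], 0.01)
})

test_that("the pairing protocol encodes 300 repetitions at 1 Hz and the interval", {
  pp <- pairing_protocol(interval_ms = 10)
  expect_length(pp$pulse_times, 300)
  expect_equal(unique(round(diff(pp$pulse_times), 9)), 1)
  expect_identical(pp$label, "pairing_pre_post")
  expect_equal(pp$params$ap_times - pp$pulse_times, rep(0.010, 300))
  expect_identical(pairing_protocol(interval_ms = -10)$label,
                   "pairing_post_pre")
})

test_that("sessions validate channel structure", {
  s1 <- flat_sweep(); s2 <- flat_sweep()
  s2$channel <- 2L
  proto <- stim_protocol(0.05, "test")
  expect_error(recording_session(list(s1, s2), proto,
                                 list(recording_site("soma"))),
               "one recording_site per channel")
  s3 <- flat_sweep(fs = 25000); s3$channel <- 1L
  expect_error(recording_session(list(s1, s3), proto,
                                 list(recording_site("soma"))),
               "share one sampling rate")
})

test_that("write/read round-trips sessions exactly across seeds", {
  for (seed in c(1L, 7L)) {
    ses <- make_tbs_session(tbs_gen_config(seed = seed, baseline_min = 1,
                                           post_min = 1, n_episodes = 2L,
                                           n_bursts = 3L))
    d <- withr::local_tempdir()
    write_session(ses, d)
    back <- read_session(d)
    expect_identical(lapply(back$sweeps, `[[`, "samples"),
                     lapply(ses$sweeps, `[[`, "samples"))
    expect_identical(vapply(back$sweeps, `[[`, 1.0, "t0"),
                     vapply(ses$sweeps, `[[`, 1.0, "t0"))
    expect_identical(vapply(back$sweeps, `[[`, "", "epoch"),
                     vapply(ses$sweeps, `[[`, "", "epoch"))
    expect_identical(back$protocol$pulse_times, ses$protocol$pulse_times)
    expect_identical(back$sites[[1]]$kind, "soma")
  }
})

test_that("a second write of a read session is byte identical", {
  ses <- make_tbs_session(tbs_gen_config(seed = 3, baseline_min = 1,
                                         post_min = 0, n_episodes = 1L,
                                         n_bursts = 2L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(ses, d1)
  write_session(read_session(d1), d2)
  for (f in c("chan1.tsv", "session.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("sweep count bookkeeping matches the generator config", {
  cfg <- tbs_gen_config(seed = 1, baseline_min = 2, post_min = 1,
                        n_episodes = 4L)
  ses <- make_tbs_session(cfg)
  eps <- vapply(ses$sweeps, `[[`, "", "epoch")
  expect_equal(sum(eps == "baseline"), 2 * 60 * cfg$test_hz)
  expect_equal(sum(eps == "induction"), 4)
  expect_equal(sum(eps == "post"), 1 * 60 * cfg$test_hz)
})

test_that("a two-channel session writes two trace tables plus one sidecar", {
  s1 <- flat_sweep(); s2 <- flat_sweep(); s2$channel <- 2L
  ses <- recording_session(list(s1, s2), stim_protocol(0.05, "test"),
                           list(recording_site("soma"),
                                recording_site("dendrite", 120)))
  d <- withr::local_tempdir()
  write_session(ses, d)
  expect_setequal(list.files(d),
                  c("chan1.tsv", "chan2.tsv", "session.json"))
})

test_that("malformed on-disk sessions are rejected", {
  expect_error(read_session(withr::local_tempdir()), "session.json")
  ses <- recording_session(list(flat_sweep(n = 10)),
                           stim_protocol(1e-4, "test"),
                           list(recording_site("soma")))
  # decreasing time column
  d <- withr::local_tempdir()
  write_session(ses, d)
  tab <- read.delim(file.path(d, "chan1.tsv"))
  tab$time_s <- rev(tab$time_s)
  write.table(tab, file.path(d, "chan1.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(read_session(d), "increasing")
  # non-uniform sampling
  d2 <- withr::local_tempdir()
  write_session(ses, d2)
  tab <- read.delim(file.path(d2, "chan1.tsv"))
  tab$time_s[5] <- tab$time_s[5] + 2e-5
  write.table(tab, file.path(d2, "chan1.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_session(d2), "uniform|increasing")
  # unknown signal kind in the sidecar
  d3 <- withr::local_tempdir()
  write_session(ses, d3)
  sc <- readLines(file.path(d3, "session.json"))
  writeLines(gsub("\"voltage\"", "\"conductance\"", sc),
             file.path(d3, "session.json"))
  expect_error(read_session(d3), "signal_kind")
})

test_that("operations fail fast on the wrong signal kind", {
  cur <- new_sweep(rep(0, 100), 20000, "current")
  expect_error(sweep_derivative(cur), "voltage")
  expect_error(p_over_minus4(flat_sweep(), list(flat_sweep())), "current")
})
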