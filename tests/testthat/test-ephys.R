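test_that("zero subtraction removes the baseline exactly", {
  flat <- current_trace(rep(5, 10000), 50000, 0.15)
  z <- zero_subtract(flat)
  expect_equal(z$samples, rep(0, 10000))

  zero <- current_trace(rep(0, 10000), 50000, 0.15)
  expect_equal(zero_subtract(zero)$samples, rep(0, 10000))

  # additive fixture: offset b + step signal s(t) returns exactly s(t)
  tr <- gen_traces(baseline_offset = -12.5)
  sig <- tr$total$samples + 12.5
  expect_equal(zero_subtract(tr$total)$samples, sig)

  late <- current_trace(rep(1, 100), 1000, 0.05)
  expect_error(zero_subtract(late, baseline_window = 0.14), "exceeds")
})

test_that("window mean density matches constants and the analytic integral", {
  const <- current_trace(rep(-480, 10000), 50000, 0.15, capacitance = 10)
  expect_equal(window_mean_density(const), -48)
  zero <- current_trace(rep(0, 10000), 50000, 0.15, capacitance = 10)
  expect_equal(window_mean_density(zero), 0)

  # slow-inactivating component against its closed-form window average;
  # discretization error at 50 kHz stays within 0.1%
  comp <- list(amp = -600, tau_act = 5e-5, tau_inact = 20e-3)
  tr <- gen_traces(components = list(comp), slow = 1L, capacitance = 15)
  got <- window_mean_density(tr$total)
  want <- analytic_window_mean(comp$amp, comp$tau_act, comp$tau_inact,
                               0.4e-3, 1.0e-3) / 15
  expect_lt(abs(got - want) / abs(want), 1e-3)

  nocap <- current_trace(rep(1, 100), 1000, 0.05)
  expect_error(window_mean_density(nocap), "capacitance")
})

test_that("peak density and time find the in-window signed extremum", {
  # triangular inward pulse peaking 1.2 ms after the step
  sr <- 50000; onset <- 0.15
  tt <- (0:9999) / sr - onset
  tri <- ifelse(tt >= 0 & tt < 2.4e-3,
                -1000 * (1 - abs(tt - 1.2e-3) / 1.2e-3), 0)
  tr <- current_trace(tri, sr, onset, capacitance = 10)
  pk <- peak_density_and_time(tr)
  expect_equal(pk$time_ms, 1.2)
  expect_equal(pk$density, -100)

  # monotonic decay peaks at the first in-window sample
  dec <- current_trace(ifelse(tt >= 0, -1000 * exp(-tt / 1e-3), 0), sr, onset,
                       capacitance = 10)
  expect_equal(peak_density_and_time(dec)$time_ms, 0.4)

  # outward polarity flips the extremum
  up <- current_trace(-tri, sr, onset, capacitance = 10)
  expect_equal(peak_density_and_time(up, polarity = "outward")$density, 100)

  narrow <- current_trace(rep(0, 100), 1000, 0.05, capacitance = 10)
  expect_error(peak_density_and_time(narrow, window = c(0.06, 0.07)),
               "no samples")
})

test_that("fast components peak earlier than slow ones", {
  tr <- gen_traces()   # fast tau_inact 1 ms + slow tau_inact 20 ms
  fast <- subtract_traces(zero_subtract(tr$total), zero_subtract(tr$slow))
  t_fast <- peak_density_and_time(fast)$time_ms
  t_slow <- peak_density_and_time(zero_subtract(tr$slow))$time_ms
  expect_lt(t_fast, t_slow)
})

test_that("trace subtraction conserves current exactly", {
  tr <- gen_traces()
  total <- zero_subtract(tr$total)
  slow <- zero_subtract(tr$slow)
  fast <- subtract_traces(total, slow)
  expect_identical(fast$samples + slow$samples, total$samples)

  expect_equal(subtract_traces(total, total)$samples,
               rep(0, length(total$samples)))
  zero <- current_trace(rep(0, length(total$samples)), total$sample_rate,
                        total$step_onset)
  expect_identical(subtract_traces(total, zero)$samples, total$samples)

  shorter <- current_trace(total$samples[1:100], total$sample_rate, 0.001)
  expect_error(subtract_traces(total, shorter), "identical length")
})

test_that("percent metrics reproduce printed per-cell values", {
  expect_equal(as.numeric(remaining_ap_percent(47, 120)), 39.2)
  expect_equal(as.numeric(remaining_ap_percent(120, 120)), 100.0)
  expect_equal(as.numeric(remaining_ap_percent(0, 120)), 0.0)
  expect_equal(as.numeric(remaining_ap_percent(3, 48)), 6.3)  # half away from zero
  und <- remaining_ap_percent(5, 0)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))

  expect_equal(rheobase_change_percent(640, 500), 28.0)
  expect_equal(rheobase_change_percent(600, 300), 100.0)
  expect_equal(rheobase_change_percent(500, 500), 0.0)
  expect_equal(rheobase_change_percent(480, 500), -4.0)
  expect_error(rheobase_change_percent(500, 0), "positive")
})

test_that("cell summaries reproduce every printed Average and SEM row", {
  cells <- read_ephys_cells(knotopt_file("drg_ephys_cells.csv"))

  rheo <- summarize_cells(cells, "rheobase_change")
  want_rheo <- data.frame(dose = c("baseline", "0.01", "0.1", "1"),
                          mean = c(0.0, 4.9, 13.5, 49.1),
                          sem = c(0.0, 3.1, 5.1, 10.3))
  got <- rheo[match(want_rheo$dose, rheo$dose), ]
  expect_equal(got$mean, want_rheo$mean)
  expect_equal(got$sem, want_rheo$sem)
  expect_true(all(got$n == 10L))

  ap <- summarize_cells(cells, "remaining_ap")
  want_ap <- rbind(
    data.frame(dose = "baseline", frequency_Hz = c(0.1, 1, 3, 10),
               mean = c(100, 100, 100, 100), sem = c(0, 0, 0, 0)),
    data.frame(dose = "0.01", frequency_Hz = c(0.1, 1, 3, 10),
               mean = c(100.0, 99.9, 82.9, 58.3), sem = c(0.0, 0.1, 9.3, 10.7)),
    data.frame(dose = "0.1", frequency_Hz = c(0.1, 1, 3, 10),
               mean = c(100.0, 84.8, 63.7, 46.3), sem = c(0.0, 9.4, 12.5, 11.0)),
    data.frame(dose = "1", frequency_Hz = c(0.1, 1, 3, 10),
               mean = c(50.0, 34.9, 24.3, 17.8), sem = c(16.7, 15.0, 10.9, 10.2)))
  key <- paste(ap$dose, ap$frequency_Hz)
  wkey <- paste(want_ap$dose, want_ap$frequency_Hz)
  m <- match(wkey, key)
  expect_false(anyNA(m))
  expect_equal(ap$mean[m], want_ap$mean)
  expect_equal(ap$sem[m], want_ap$sem)
})

test_that("summary edge cases: identical values, singleton groups, exclusions", {
  cells <- data.frame(
    cell = rep(c("c1", "c2"), each = 2),
    dose = rep(c("baseline", "1"), 2),
    rheobase_pA = c(100, 150, 100, 150),
    `aps_0.1Hz` = c(10, 5, 10, 5), `aps_1Hz` = c(120, 60, 120, 60),
    `aps_3Hz` = c(120, 60, 120, 60), `aps_10Hz` = c(120, 60, 120, 60),
    check.names = FALSE)
  s <- summarize_cells(cells, "rheobase_change")
  expect_equal(s$mean[s$dose == "1"], 50.0)
  expect_equal(s$sem[s$dose == "1"], 0.0)

  one <- cells[cells$cell == "c1", ]
  s1 <- summarize_cells(one, "rheobase_change")
  expect_equal(s1$mean[s1$dose == "1"], 50.0)
  expect_true(is.na(s1$sem[s1$dose == "1"]))

  # zero-baseline cells drop out of that frequency's average
  cells$`aps_10Hz`[cells$cell == "c2"] <- 0
  ap <- summarize_cells(cells, "remaining_ap")
  expect_equal(ap$n[ap$dose == "1" & ap$frequency_Hz == 10], 1L)
})

test_that("two-group comparisons report an unpaired t-test", {
  set.seed(8)
  g1 <- gen_ephys_table(n_cells = 6, seed = 14)
  g1$group <- ifelse(as.integer(sub("cell_", "", g1$cell)) <= 3,
                     "vehicle", "drug")
  s <- summarize_cells(g1, "rheobase_change", group_col = "group")
  row <- s[s$dose == "1", ]
  expect_true(is.finite(row$p))
  expect_true(row$p >= 0 && row$p <= 1)
  expect_true(is.finite(row$t))
})

test_that("ephys table validation catches impossible counts", {
  tf <- withr::local_tempfile(fileext = ".csv")
  cells <- gen_ephys_table(n_cells = 3, seed = 4, path = tf)
  back <- read_ephys_cells(tf)
  expect_equal(back$rheobase_pA, cells$rheobase_pA)
  bad <- cells
  bad$`aps_0.1Hz`[1] <- 11
  utils::write.csv(bad, tf, row.names = FALSE)
  expect_error(read_ephys_cells(tf), "exceeds stimulus count")
})
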