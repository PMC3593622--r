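exact_target <- function(sub, net = "RVMT") {
  target_ic(sub$truth$true_maps[net, ],
            time_course = sub$truth$true_courses[, net], label = net)
}

# localizer-estimated target: on noiseless data the window decompositions
# share their fixed points with the localizer's, so agreement is near-exact
fl_target <- function(sub, net = "RVMT") {
  cached(paste0("fltgt_", sub$series$subject_id, "_", net), {
    fl <- run_localizer(sub$series, 60,
                        ica_config(5, tolerance = 1e-12, seed = 8))
    select_target(fl, exact_target(sub, net))
  })
}

test_that("streaming partitions the series after the localizer", {
  sub <- fix_subject()
  vols <- stream_volumes(sub$series, 60)
  expect_length(vols, 160L)
  expect_identical(vols[[1]]$index, 60L)
  expect_identical(vols[[160]]$index, 219L)
  expect_length(stream_volumes(sub$series, 219), 1L)
  # FL block + stream reconstructs the full series
  streamed <- do.call(rbind, lapply(vols, `[[`, "values"))
  expect_identical(rbind(sub$series$data[1:60, ], streamed), sub$series$data)
  expect_error(stream_volumes(sub$series, 400), "range")
})

test_that("back-projection is exact on constructed volumes and runs no ICA", {
  sub <- fix_subject(noise_sd = 0)
  x <- sub$truth$true_maps["RVMT", ]
  tgt <- exact_target(sub)
  expect_no_ica({
    r <- bp_update(4 * x, tgt)
  })
  expect_equal(r$amplitude, 4, tolerance = 1e-10)
  # two orthogonal targets jointly
  set.seed(2)
  v <- length(x)
  x1 <- standardize_test(rnorm(v))
  x2 <- standardize_test(rnorm(v))
  x2 <- standardize_test(x2 - sum(x1 * x2) / sum(x1^2) * x1)
  r2 <- bp_update(2 * x1 + 3 * x2,
                  list(target_ic(x1, label = "a"), target_ic(x2, label = "b")))
  expect_equal(r2$amplitudes[[1]], c(2, 3), tolerance = 1e-10)
})

test_that("joint back-projection on a noiseless stream equals the true mixing", {
  sub <- fix_subject(noise_sd = 0)
  targets <- lapply(rownames(sub$truth$true_maps), function(n) exact_target(sub, n))
  amps <- t(vapply(61:220, function(i)
    pseudo_project(sub$series$data[i, ], sub$truth$true_maps), numeric(5)))
  expect_equal(amps, unname(sub$truth$true_courses[61:220, ]), tolerance = 1e-8)
})

test_that("temporally constrained updates track a stationary noiseless window", {
  sub <- fix_subject(noise_sd = 0)
  tgt <- fl_target(sub)
  cfg <- monitor_config("rtc", 15, ica_config(5, tolerance = 1e-10, seed = 3))
  w <- extract_window(sub$series, end = 100, length = 15)
  r <- rtc_update(w, tgt, cfg, tr_index = 100)
  expect_gte(cor(r$dynamic_map[[1]], tgt$spatial_map), 0.99)
  expect_error(rtc_update(w[1:10, ], tgt, cfg), "not full")
})

test_that("spatially constrained updates reproduce the localizer on its own block", {
  sub <- fix_subject(noise_sd = 0)
  tgt <- fl_target(sub)
  cfg <- monitor_config("rsc", 15, ica_config(5, tolerance = 1e-10, seed = 3))
  w <- extract_window(sub$series, end = 100, length = 15)
  vol <- get_volume(sub$series, 100)
  r <- rsc_update(w, vol, tgt, cfg, tr_index = 100)
  expect_gte(cor(r$dynamic_map[[1]], tgt$spatial_map), 0.99)
  bp <- bp_update(vol, tgt)
  expect_equal(r$amplitude, bp$amplitude, tolerance = 0.05)
  # a zero volume has zero amplitude regardless of the map
  r0 <- rsc_update(w, rep(0, ncol(w)), tgt, cfg)
  expect_identical(r0$amplitude, 0)
})

test_that("spatio-temporal amplitudes collapse to back-projection when spaces agree", {
  sub <- fix_subject(noise_sd = 0)
  tgt <- fl_target(sub)
  cfg <- monitor_config("rstc", 15, ica_config(5, tolerance = 1e-12, seed = 3))
  w <- extract_window(sub$series, end = 100, length = 15)
  vol <- get_volume(sub$series, 100)
  r <- rstc_update(w, vol, tgt, cfg, tr_index = 100)
  expect_false(is.na(r$fl_amplitude))
  expect_equal(r$amplitude, r$fl_amplitude, tolerance = 1e-6)
})

test_that("a session yields one result per monitored TR with BP warm-up", {
  sub <- fix_subject()
  tgt <- exact_target(sub)
  ses <- run_session(sub$series,
                     monitor_config("rtc", ica = ica_config(5, seed = 1)),
                     tgt, start = 60)
  expect_identical(nrow(ses), 160L)
  expect_identical(ses$tr_index, 60:219)
  expect_identical(which(!ses$warmup)[1], 15L) # first full window at TR 74
  expect_identical(ses$tr_index[!ses$warmup][1], 74L)
  expect_true(all(vapply(ses$dynamic_map, length, integer(1)) ==
                    ncol(sub$series$data)))
  bp <- run_session(sub$series,
                    monitor_config("bp", ica = ica_config(5, seed = 1)),
                    tgt, start = 60)
  expect_identical(nrow(bp), 160L)
  expect_false(any(bp$skipped))
  expect_false(any(bp$warmup))
})

test_that("a zero time budget skips every window update but still reports amplitudes", {
  sub <- fix_subject()
  tgt <- exact_target(sub)
  ses <- run_session(sub$series,
                     monitor_config("rtc", ica = ica_config(5, seed = 1),
                                    time_budget = 0),
                     tgt, start = 60)
  post <- ses[!ses$warmup, ]
  expect_true(all(post$skipped))
  expect_true(all(is.finite(post$amplitude)))
  # the carried map is the FL map throughout
  expect_no_ica({
    for (m in post$dynamic_map) expect_identical(m, tgt$spatial_map)
  })
  # skipped amplitudes equal back-projection onto the carried map
  i <- which(!ses$warmup)[1]
  expect_equal(ses$amplitude[i],
               pseudo_project(sub$series$data[ses$tr_index[i] + 1, ],
                              tgt$spatial_map),
               tolerance = 1e-12)
})

test_that("sessions are bitwise reproducible given the seed", {
  sub <- fix_subject()
  tgt <- exact_target(sub)
  cfg <- monitor_config("rstc", ica = ica_config(5, seed = 77))
  s1 <- run_session(sub$series, cfg, tgt, start = 60)
  s2 <- run_session(sub$series, cfg, tgt, start = 60)
  expect_identical(s1$amplitude, s2$amplitude)
  expect_identical(s1$dynamic_map, s2$dynamic_map)
})

test_that("per-step amplitudes replay from the logged maps", {
  sub <- fix_subject()
  tgt <- exact_target(sub)
  ses <- run_session(sub$series,
                     monitor_config("rsc", ica = ica_config(5, seed = 5)),
                     tgt, start = 60)
  for (i in c(20, 80, 140)) {
    y <- sub$series$data[ses$tr_index[i] + 1, ]
    expect_equal(ses$amplitude[i], pseudo_project(y, ses$dynamic_map[[i]]),
                 tolerance = 1e-10)
  }
})

test_that("invalid method names are rejected", {
  expect_error(monitor_config("glm"), "one of|arg")
  expect_error(monitor_config("rtc", window_length = 3, ica = ica_config(5)),
               "model order")
})

test_that("session glance and CSV export expose the run summary", {
  sub <- fix_subject()
  tgt <- exact_target(sub)
  ses <- run_session(sub$series,
                     monitor_config("bp", ica = ica_config(5, seed = 1)),
                     tgt, start = 60)
  g <- glance(ses)
  expect_identical(g$method, "bp")
  expect_identical(g$n_trs, 160L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_session_csv(ses, p, template_map = tgt$spatial_map)
  df <- read.csv(p)
  expect_identical(nrow(df), 160L)
  expect_true(all(c("tr_index", "amplitude", "skipped",
                    "spatial_corr_to_template") %in% names(df)))
})
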