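test_that("discrete tuning reproduces restrict-then-rate per condition", {
  g <- event_group(list(`1` = seq(0.25, 4.75, 0.5)),
                   time_support = epoch_set(0, 10))
  tt <- tuning_discrete(g, list(ON = epoch_set(0, 5), OFF = epoch_set(5, 10)))
  expect_equal(tt["ON", "1"], 2)
  expect_equal(tt["OFF", "1"], 0)

  # condition equal to the full support matches the metadata rate
  tt2 <- tuning_discrete(g, list(all = epoch_set(0, 10)))
  expect_equal(unname(tt2["all", "1"]), group_metadata(g)$rate)

  expect_error(tuning_discrete(g, list(z = epoch_set(20, 21))),
               "zero duration")

  # random events/epochs against the restrict-then-rate oracle
  set.seed(9)
  for (rep in 1:10) {
    gg <- event_group(list(`1` = random_events(100), `2` = random_events(50)),
                      time_support = epoch_set(0, 100))
    ep <- random_lattice_epochs(4, 100)
    if (total_duration(ep) == 0) next
    tt3 <- tuning_discrete(gg, list(a = ep))
    for (id in 1:2) {
      expect_equal(unname(tt3["a", as.character(id)]),
                   event_rate(restrict(gg[[id]], ep)))
    }
  }
})

test_that("1D tuning divides spike counts by sample-count occupancy", {
  # feature dwells in one bin: 100 samples at dt 0.1 -> 10 s occupancy;
  # 20 spikes there -> 2 Hz, all other bins undefined
  feat <- ts_signal((0:99) * 0.1, rep(0.55, 100),
                    time_support = epoch_set(0, 9.9))
  g <- event_group(list(`1` = seq(0.1, 9.8, length.out = 20)),
                   time_support = epoch_set(0, 9.9))
  tc <- tuning_1d(g, feat, nb_bins = 10, range = c(0, 1))
  expect_equal(tc$occupancy[6], 10)
  expect_equal(unname(tc$rates[6, 1]), 2)
  expect_true(all(is.na(tc$rates[-6, 1])))

  # uniform feature + homogeneous Poisson unit: flat curve near true rate
  set.seed(10)
  tfeat <- ts_signal((0:5999) * 0.05, runif(6000, 0, 1),
                     time_support = epoch_set(0, 300))
  spk <- ts_events(sort(runif(300 * 8, 0, 300)),
                   time_support = epoch_set(0, 300))
  gp <- event_group(list(`1` = spk), time_support = epoch_set(0, 300))
  tcf <- tuning_1d(gp, tfeat, nb_bins = 5, range = c(0, 1))
  se <- sqrt(8 / tcf$occupancy)
  expect_true(all(abs(tcf$rates[, 1] - 8) < 3 * se))

  # doubling the bin count preserves total occupancy
  tc2 <- tuning_1d(gp, tfeat, nb_bins = 10, range = c(0, 1))
  expect_equal(sum(tc2$occupancy), sum(tcf$occupancy))
})

test_that("2D tuning uses product binning and marginalizes to 1D", {
  # all samples in one cell: 20 spikes over 10 s -> 2 Hz there
  tm <- (0:99) * 0.1
  feat <- ts_frame(tm, cbind(x = rep(0.25, 100), y = rep(0.75, 100)),
                   time_support = epoch_set(0, 9.9))
  g <- event_group(list(`1` = seq(0.1, 9.8, length.out = 20)),
                   time_support = epoch_set(0, 9.9))
  tc <- tuning_2d(g, feat, nb_bins = 2, ranges = list(c(0, 1), c(0, 1)))
  expect_equal(tc$rates[1, 2, 1], 2)
  expect_equal(sum(!is.na(tc$rates[, , 1])), 1)
  expect_equal(sum(tc$occupancy), 10)

  # marginal over y equals the 1D curve on the x channel
  set.seed(12)
  tm2 <- (0:1999) * 0.05
  xy <- cbind(x = runif(2000), y = runif(2000))
  feat2 <- ts_frame(tm2, xy, time_support = epoch_set(0, 99.95))
  g2 <- event_group(list(`1` = random_events(400, 0, 99.95)),
                    time_support = epoch_set(0, 99.95))
  t2 <- tuning_2d(g2, feat2, nb_bins = 4, ranges = list(c(0, 1), c(0, 1)))
  t1 <- tuning_1d(g2, ts_signal(tm2, xy[, 1],
                                time_support = epoch_set(0, 99.95)),
                  nb_bins = 4, range = c(0, 1))
  occ_x <- rowSums(t2$occupancy)
  marg <- rowSums(t2$rates[, , 1] * t2$occupancy, na.rm = TRUE) / occ_x
  expect_equal(marg, t1$rates[, 1], tolerance = 1e-10)
})

test_that("continuous-trace tuning averages values per feature bin", {
  tm <- (0:999) * 0.1
  feat <- ts_signal(tm, rep(seq(0.05, 0.95, 0.1), 100),
                    time_support = epoch_set(0, 99.9))

  # constant trace: every visited bin is exactly 1.0
  v1 <- ts_signal(tm, rep(1, 1000), time_support = epoch_set(0, 99.9))
  tc1 <- tuning_continuous(v1, feat, nb_bins = 10, range = c(0, 1))
  expect_true(all(tc1$rates[, 1] == 1))

  # trace equal to the feature, identity binning: bin means near centers
  v2 <- ts_signal(tm, feat$values, time_support = epoch_set(0, 99.9))
  tc2 <- tuning_continuous(v2, feat, nb_bins = 10, range = c(0, 1))
  expect_true(all(abs(tc2$rates[, 1] - tc2$bin_centers) <= 0.05))

  expect_error(
    tuning_continuous(ts_signal(200:210, rep(1, 11),
                                time_support = epoch_set(200, 210)),
                      feat, 10),
    "overlap")
})
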