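test_that("restrict keeps closed-boundary members and propagates support", {
  x <- ts_events(c(1, 3, 6, 11), time_support = epoch_set(0, 12))
  ep <- epoch_set(c(0, 10), c(5, 12))
  r <- restrict(x, ep)
  expect_equal(sample_times(r), c(1, 3, 11))
  expect_equal(as.data.frame(time_support(r)),
               data.frame(start = c(0, 10), end = c(5, 12)))

  # boundary sample is kept (closed intervals)
  x2 <- ts_events(5, time_support = epoch_set(0, 10))
  expect_equal(length(restrict(x2, epoch_set(0, 5))), 1L)

  # idempotence and identity on own support
  r2 <- restrict(r, ep)
  expect_identical(r2, r)
  expect_identical(restrict(x, time_support(x)), x)
})

test_that("restrict conserves samples and matches a membership scan", {
  set.seed(11)
  for (rep in 1:25) {
    x <- random_events(sample.int(500, 1))
    ep <- random_lattice_epochs(5, 100)
    r <- restrict(x, ep)
    keep <- probe_mask_times(ep, sample_times(x))
    expect_identical(sample_times(r), sample_times(x)[keep])
    expect_equal(length(r) + sum(!keep), length(x))
  }
})

test_that("value_from picks nearest source values, ties to earlier sample", {
  src <- ts_signal(0:2, c(10, 20, 30))
  expect_equal(value_from(ts_events(c(0.4, 1.6)), src)$values, c(10, 30))
  expect_equal(value_from(ts_events(0.5), src)$values, 10)
  expect_error(value_from(ts_events(5, time_support = epoch_set(4, 6)), src),
               "common time support")
})

test_that("value_from matches a brute-force nearest-neighbor scan", {
  set.seed(22)
  st <- sort(runif(50, 0, 100))
  src <- ts_signal(st, rnorm(50), time_support = epoch_set(0, 100))
  tt <- sort(runif(100, 0, 100))
  tgt <- ts_events(tt, time_support = epoch_set(0, 100))
  got <- value_from(tgt, src)
  expect_equal(got$values, src$values[brute_nearest(tt, st)])

  # ts_frame source yields a frame on target times
  fr <- ts_frame(st, cbind(a = rnorm(50), b = rnorm(50)),
                 time_support = epoch_set(0, 100))
  gotf <- value_from(tgt, fr)
  expect_equal(unname(gotf$values), unname(fr$values[brute_nearest(tt, st), ]))
})

test_that("count bins from interval starts, keeps full bins only", {
  x <- ts_events(c(0.5, 1.5, 1.6, 3.2), time_support = epoch_set(0, 4))
  cnt <- count(x, 1)
  expect_equal(sample_times(cnt), c(0.5, 1.5, 2.5, 3.5))
  expect_equal(sample_values(cnt), c(1, 2, 0, 1))
  expect_identical(as.data.frame(time_support(cnt)),
                   data.frame(start = 0, end = 4))

  # empty series: all-zero counts
  e <- ts_events(numeric(0), time_support = epoch_set(0, 3))
  expect_equal(sample_values(count(e, 1)), c(0, 0, 0))

  # conservation when epochs align with bin multiples
  set.seed(33)
  x3 <- random_events(200)
  expect_equal(sum(sample_values(count(x3, 0.5, epoch_set(0, 100)))), 200)
  expect_error(count(x3, 0), "> 0")
})

test_that("count matches a brute-force histogram over multi-interval epochs", {
  set.seed(44)
  for (rep in 1:20) {
    x <- random_events(sample.int(500, 1))
    ep <- epoch_set(c(0, 40.3), c(30.7, 90.1))
    b <- sample(c(0.1, 0.25, 1, 3.3), 1)
    got <- sample_values(count(x, b, ep))
    want <- c(brute_count_interval(sample_times(x), 0, 30.7, b),
              brute_count_interval(sample_times(x), 40.3, 90.1, b))
    expect_equal(got, as.numeric(want))
    expect_lte(sum(got), length(x))
  }
})

test_that("threshold keeps strict exceedances and rebuilds run-based support", {
  x <- ts_signal(0:5, c(0, 1, 3, 3, 1, 0))
  th <- threshold(x, 2, "above")
  expect_equal(sample_times(th), c(2, 3))
  expect_equal(sample_values(th), c(3, 3))
  expect_equal(as.data.frame(time_support(th)),
               data.frame(start = 2, end = 3))

  # level below the minimum: identity on samples
  th2 <- threshold(x, -1, "above")
  expect_equal(sample_values(th2), sample_values(x))

  # above/below partition the samples with value != level
  set.seed(55)
  y <- ts_signal(sort(runif(200, 0, 50)), rnorm(200),
                 time_support = epoch_set(0, 50))
  up <- threshold(y, 0.2, "above")
  dn <- threshold(y, 0.2, "below")
  expect_equal(sort(c(sample_times(up), sample_times(dn))),
               sample_times(y)[sample_values(y) != 0.2])

  # empty result is valid: empty series with empty support
  none <- threshold(x, 10, "above")
  expect_equal(length(none), 0L)
  expect_equal(n_intervals(time_support(none)), 0L)
})

test_that("event_rate divides count by intersected support duration", {
  x <- ts_events(seq(0.25, 4.75, 0.5), time_support = epoch_set(0, 5))
  expect_equal(event_rate(x), 2)
  e <- ts_events(numeric(0), time_support = epoch_set(0, 5))
  expect_equal(event_rate(e), 0)
  expect_error(event_rate(x, epoch_set(10, 10)), "zero duration")

  # restrict-then-rate equals rate with ep, on random inputs
  set.seed(66)
  for (rep in 1:10) {
    y <- random_events(sample.int(300, 1))
    ep <- random_lattice_epochs(5, 100)
    if (total_duration(ep_intersect(time_support(y), ep)) == 0) next
    expect_equal(event_rate(restrict(y, ep)), event_rate(y, ep))
  }
})

test_that("as_units rescales for display and round-trips exactly", {
  x <- ts_signal(c(0.5, 1.5), c(1, 2))
  expect_equal(as_units(x, "ms")$time, c(500, 1500))
  expect_equal(as_units(x, "s")$time, sample_times(x))
  expect_error(as_units(x, "min"))

  set.seed(77)
  t <- sort(round(runif(500, 0, 100), 3))
  y <- ts_events(t)
  for (u in c("ms", "us")) {
    disp <- as_units(y, u)$time
    back <- ts_events(disp, time_units = u)
    expect_identical(sample_times(back), t)
  }
  ep <- epoch_set(1.5, 2.5)
  expect_equal(as_units(ep, "ms"), data.frame(start = 1500, end = 2500))
})

test_that("operations yield objects that pass the shared validators", {
  set.seed(88)
  x <- random_events(100)
  ep <- random_lattice_epochs(4, 100)
  sig <- ts_signal(sort(runif(80, 0, 100)), rnorm(80),
                   time_support = epoch_set(0, 100))
  for (obj in list(restrict(x, ep), count(x, 0.7, ep),
                   threshold(sig, 0, "above"), value_from(x, sig))) {
    expect_silent(neurotime:::validate_series(obj))
  }
})
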