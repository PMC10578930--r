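test_that("construction normalizes: sorting, overlap and abutting merges", {
  ep <- epoch_set(c(0, 5), c(10, 15))
  expect_equal(as.data.frame(ep), data.frame(start = 0, end = 15))

  ep <- epoch_set(c(3, 0), c(4, 2))
  expect_equal(as.data.frame(ep), data.frame(start = c(0, 3), end = c(2, 4)))

  ep <- epoch_set(c(0, 2), c(2, 4))
  expect_equal(as.data.frame(ep), data.frame(start = 0, end = 4))

  expect_equal(n_intervals(epoch_set(numeric(0), numeric(0))), 0L)
  expect_equal(total_duration(epoch_set(numeric(0), numeric(0))), 0)
})

test_that("construction rejects bad input, naming the offending index", {
  expect_error(epoch_set(1:3, 1:2), "same length")
  expect_error(epoch_set(c(0, 5), c(1, 4)), "interval 2")
})

test_that("merged intervals inherit the label of the earliest constituent", {
  ep <- epoch_set(c(5, 0, 20), c(12, 10, 30), labels = c("b", "a", "c"))
  expect_equal(ep$label, c("a", "c"))
  expect_equal(as.data.frame(ep)$start, c(0, 20))
})

test_that("interval algebra matches the spec examples", {
  expect_equal(as.data.frame(ep_intersect(epoch_set(0, 10), epoch_set(5, 15))),
               data.frame(start = 5, end = 10))
  expect_equal(n_intervals(ep_intersect(epoch_set(0, 5), epoch_set(6, 8))), 0L)
  i <- ep_intersect(epoch_set(c(0, 20), c(10, 30)), epoch_set(5, 25))
  expect_equal(as.data.frame(i), data.frame(start = c(5, 20), end = c(10, 25)))

  u <- ep_union(epoch_set(c(0, 10), c(5, 15)), epoch_set(3, 12))
  expect_equal(as.data.frame(u), data.frame(start = 0, end = 15))
  a <- epoch_set(c(1, 7), c(3, 9))
  expect_identical(as.data.frame(ep_union(a, epoch_set(numeric(0), numeric(0)))),
                   as.data.frame(a))

  d <- ep_setdiff(epoch_set(0, 10), epoch_set(3, 5))
  expect_equal(as.data.frame(d), data.frame(start = c(0, 5), end = c(3, 10)))
  expect_equal(n_intervals(ep_setdiff(a, a)), 0L)
  expect_identical(as.data.frame(ep_setdiff(a, epoch_set(numeric(0), numeric(0)))),
                   as.data.frame(a))
})

test_that("duration filters and gap merging behave per their definitions", {
  ep <- epoch_set(c(0, 2), c(1, 10))
  expect_equal(as.data.frame(drop_short_intervals(ep, 2)),
               data.frame(start = 2, end = 10))
  expect_identical(as.data.frame(drop_short_intervals(ep, 0)),
                   as.data.frame(ep))
  expect_equal(as.data.frame(drop_long_intervals(ep, 5)),
               data.frame(start = 0, end = 1))
  expect_error(drop_short_intervals(ep, -1), "non-negative")

  m <- merge_close_intervals(epoch_set(c(0, 1.5), c(1, 2)), 1)
  expect_equal(as.data.frame(m), data.frame(start = 0, end = 2))
  ep2 <- epoch_set(c(0, 1.5), c(1, 2))
  expect_identical(as.data.frame(merge_close_intervals(ep2, 0)),
                   as.data.frame(ep2))
  # transitive closure: chained gaps all <= max_gap collapse to one interval
  m3 <- merge_close_intervals(epoch_set(c(0, 1.5, 2.6), c(1, 2, 3)), 0.6)
  expect_equal(as.data.frame(m3), data.frame(start = 0, end = 3))
  expect_error(merge_close_intervals(ep2, -0.1), "non-negative")
})

test_that("algebra agrees with a boolean-mask oracle on a 1 ms lattice", {
  set.seed(101)
  probes <- lattice_probes(50)
  for (rep in 1:50) {
    a <- random_lattice_epochs(6, 50)
    b <- random_lattice_epochs(6, 50)
    ma <- probe_mask(a, probes)
    mb <- probe_mask(b, probes)
    expect_identical(probe_mask(ep_intersect(a, b), probes), ma & mb)
    expect_identical(probe_mask(ep_union(a, b), probes), ma | mb)
    expect_identical(probe_mask(ep_setdiff(a, b), probes), ma & !mb)
  }
})

test_that("algebraic laws hold: commutativity, associativity, De Morgan", {
  set.seed(202)
  probes <- lattice_probes(20)
  univ <- epoch_set(0, 20)
  for (rep in 1:20) {
    a <- random_lattice_epochs(5, 20)
    b <- random_lattice_epochs(5, 20)
    c <- random_lattice_epochs(5, 20)
    expect_identical(as.data.frame(ep_intersect(a, b)),
                     as.data.frame(ep_intersect(b, a)))
    expect_identical(as.data.frame(ep_union(a, b)),
                     as.data.frame(ep_union(b, a)))
    expect_identical(as.data.frame(ep_intersect(ep_intersect(a, b), c)),
                     as.data.frame(ep_intersect(a, ep_intersect(b, c))))
    expect_identical(as.data.frame(ep_union(ep_union(a, b), c)),
                     as.data.frame(ep_union(a, ep_union(b, c))))
    expect_identical(as.data.frame(ep_intersect(a, a)), as.data.frame(a))
    # set_diff(a, b) == intersect(a, complement(b)) at the probe level
    expect_identical(probe_mask(ep_setdiff(a, b), probes),
                     probe_mask(ep_intersect(a, ep_setdiff(univ, b)), probes))
    # De Morgan at the probe level
    expect_identical(
      probe_mask(ep_setdiff(univ, ep_union(a, b)), probes),
      probe_mask(ep_intersect(ep_setdiff(univ, a), ep_setdiff(univ, b)),
                 probes))
  }
})

test_that("epoch CSV round-trips and normalizes on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start,end,label", "0,10,w", "5,15,r", "20,30,s"), f)
  ep <- read_epochs_csv(f)
  expect_equal(as.data.frame(ep),
               data.frame(start = c(0, 20), end = c(15, 30),
                          label = c("w", "s")))

  f2 <- withr::local_tempfile(fileext = ".csv")
  write_epochs_csv(ep, f2)
  expect_identical(as.data.frame(read_epochs_csv(f2)), as.data.frame(ep))

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("begin,stop", "0,1"), f3)
  expect_error(read_epochs_csv(f3), "start,end\\[,label\\]")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("start,end", "0,1", "5,2"), f4)
  expect_error(read_epochs_csv(f4), "row 2")
})
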