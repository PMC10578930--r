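# a random session holding one of every object type
random_session <- function() {
  ev <- random_events(sample.int(100, 1))
  sig <- ts_signal(sort(runif(50, 0, 100)), rnorm(50),
                   time_support = epoch_set(0, 100))
  fr <- ts_frame(sort(runif(30, 0, 100)),
                 cbind(x = rnorm(30), y = rnorm(30)),
                 time_support = epoch_set(0, 100))
  g <- event_group(list(`1` = random_events(60), `3` = random_events(20)),
                   time_support = epoch_set(0, 100))
  g <- set_metadata(g, "region", c(`1` = "ADN", `3` = "CA1"))
  g <- set_metadata(g, "depth", c(`1` = runif(1), `3` = runif(1)))
  session(paste0("s", sample.int(1e6, 1)),
          objects = list(epochs = random_lattice_epochs(4, 100),
                         spikes = ev, lfp = sig, pos = fr, units = g),
          metadata = list(strain = "C57BL/6", weight = runif(1) * 30,
                          experimenter = "A.B."))
}

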