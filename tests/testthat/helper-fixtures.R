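# Hand-built trajectory objects for closed-form checks of the diversity
# summaries (no stochasticity involved).
make_fixture_trajectory <- function(times, counts, spec = simple_bdm(ncol(counts))) {
  colnames(counts) <- paste0("type", seq_len(ncol(counts)))
  structure(list(times = times, counts = counts, record = "grid",
                 arrivals = rep(NA_real_, ncol(counts)),
                 extinctions = rep(NA_real_, ncol(counts)),
                 censored = rep(FALSE, ncol(counts)),
                 t_end = max(times), n_events = 0, status = "t_max",
                 seed = 0L, rep = 1L, spec = spec),
            class = "bdm_trajectory")
}

# two-point (mean local) log-log slope of a pmf over [s_lo, s_hi]
tail_slope <- function(prob, s_lo, s_hi) {
  (log(prob[s_hi + 1]) - log(prob[s_lo + 1])) / (log(s_hi) - log(s_lo))
}
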