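# Shared small-scale truth specifications and fixture builders.

small_truth <- function(...) {
  do.call(truth_spec, utils::modifyList(
    list(ages = 40:59, periods = 2001:2015), list(...)))
}

# Lexis diagram whose case counts equal their expectations exactly (no
# sampling), so fits recover the generating parameters to numerical
# precision.  Counts are non-integer, which the Poisson IRLS accepts.
exact_lexis <- function(truth, periods = truth$periods) {
  A <- length(truth$ages); P <- length(periods)
  O <- matrix(truth$offset, A, P)
  lr <- matrix(truth_log_rate(truth, rep(truth$ages, P),
                              rep(periods, each = A)), A, P)
  lexis_diagram(O * exp(lr), O, truth$ages[1], periods[1], truth$delta)
}
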