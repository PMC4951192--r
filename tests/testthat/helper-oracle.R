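# Deliberately naive trial-by-trial likelihood replay, written directly from
# the update and softmax definitions with named-vector bookkeeping. Serves
# as the independent oracle for session_negloglik().
oracle_negloglik <- function(model, eta, kappa, beta, a, schedule, records) {
  V <- c(SURE0 = 0, SURE5 = 0, SURE10 = 0, RISKY = 0)
  tr <- schedule$trials
  nll <- 0
  for (t in seq_len(nrow(tr))) {
    if (records$aborted[t]) next
    ch <- records$chosen[t]
    if (tr$kind[t] == "CHOICE") {
      offered <- c(tr$cue_left[t], tr$cue_right[t])
      other <- offered[offered != ch]
      p <- 1 / (1 + exp(-beta * (V[[ch]] - V[[other]])))
      nll <- nll - log(max(p, 1e-12))
    }
    r <- records$reward[t]
    if (model == "UTILITY" && r == 10) r <- 10 * a
    d <- r - V[[ch]]
    lr <- if (model == "WSLS") 1 else eta
    mult <- if (model == "ASYMMETRIC") {
      if (d > 0) 1 + kappa else if (d < 0) 1 - kappa else 1
    } else 1
    V[[ch]] <- V[[ch]] + lr * d * mult
  }
  nll
}
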