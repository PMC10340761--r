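# Shared fixtures, built in code.

# two-marker configuration kept tiny for fast unit tests
tiny_config <- function(seed = 42, n_met = 31, n_nonmet = 49) {
  sim_config(
    markers = list(
      marker_sim_spec("CA9", "expression", 92.7, 17.8, 1.4531880),
      marker_sim_spec("MIR125B1", "methylation", 36.27, 66.34, 5.215393)
    ),
    n_metastatic = n_met, n_nonmetastatic = n_nonmet, seed = seed
  )
}

# brute-force pairwise-concordance AUC: P(positive scored above negative),
# ties counting one half
concordance_auc <- function(values, outcome, direction) {
  s <- if (direction == "low_positive") -values else values
  pos <- s[outcome == 1]; neg <- s[outcome == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exhaustive O(n * m) Youden sweep over observed thresholds; J compared on
# the integer scale tp*n0 - fp*n1 so exact ties are resolved exactly
brute_youden <- function(values, outcome, direction) {
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  best <- list(j_int = -Inf, fp = Inf)
  for (t in sort(unique(values))) {
    call <- if (direction == "low_positive") values <= t else values > t
    tp <- sum(call & outcome == 1); fp <- sum(call & outcome == 0)
    j_int <- tp * n0 - fp * n1
    if (j_int > best$j_int || (j_int == best$j_int && fp < best$fp))
      best <- list(j_int = j_int, fp = fp, cutoff = t,
                   sens = tp / n1, spec = (n0 - fp) / n0)
  }
  best
}
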