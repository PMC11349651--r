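# Build a minimal valid subject from the CAPS component inputs.
# `drop` is MMSE points lost between two visits 366 days apart
# (>= 3 points is rapid under the 365.25-day-year convention).
make_subject <- function(id = "S1", npiq_total = 0L, drop = 0L, fazekas = 0L,
                         scheltens = NULL, status = "unknown", age = 70,
                         mmse0 = 26L, ...) {
  npiq <- setNames(integer(12L), npiq_domains())
  left <- npiq_total
  for (d in npiq_domains()) {
    take <- min(3L, left)
    npiq[[d]] <- take
    left <- left - take
    if (left == 0L) break
  }
  subject(
    id = id, age = age, sex = "female",
    cognitive_scores = data.frame(
      date = as.Date("2022-01-01") + c(0L, 366L),
      instrument = "MMSE",
      raw = c(mmse0, max(0L, mmse0 - drop))),
    npiq = npiq_profile(severities = npiq),
    fazekas = fazekas, scheltens_mtla = scheltens,
    amyloid_status_reference = status, ...)
}

# Brute-force c-statistic: fraction of positive/negative pairs where the
# positive subject outscores the negative one, ties counting one half.
auc_pairwise_oracle <- function(scores, labels01) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
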