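# Independent oracles used across test files.

# AUC as explicit pairwise concordance: P(score_pos "beats" score_neg),
# ties counting one half. Quadratic in n; independent of the rank-based
# implementation it checks.
auc_pairwise_oracle <- function(scores, reference, lower_is_positive = TRUE) {
  s <- if (lower_is_positive) -scores else scores
  pos <- s[reference]
  neg <- s[!reference]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Empirical survival 1 - ECDF at time t (valid KM oracle without censoring).
surv_ecdf <- function(times, t) mean(times > t)

# Survival probability of a km curve at time t (step-function lookup).
km_surv_at <- function(km, stratum, t) {
  cur <- km[km$stratum == stratum & km$time <= t, ]
  cur$survival[which.max(cur$time)]
}

# A small scored cohort shared by several files.
small_cohort <- function(n = 120, seed = 101, ...) {
  score_cohort(generate_cohort(generator_params(n = n, seed = seed, ...)))
}
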