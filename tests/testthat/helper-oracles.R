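# Independent oracles used across the suite. Each is coded from first
# principles and deliberately shares no code path with the implementation.

# Exhaustive O(n^2) interval scan: longest block of TRUEs by checking
# every (i, j) interval against its cumulative sum.
brute_longest_run <- function(flags) {
  n <- length(flags)
  if (!n) return(0L)
  s <- c(0L, cumsum(as.integer(flags)))
  best <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (s[j + 1L] - s[i] == j - i + 1L && j - i + 1L > best)
        best <- j - i + 1L
    }
  }
  best
}

# Kruskal-Wallis H from the general rank-ANOVA identity
# H = (N - 1) * SSbetween / SStotal on midranks, which absorbs ties
# without an explicit correction factor. Algebraically equal to the
# 12/(N(N+1)) form with tie correction, but derived differently.
kw_h_oracle <- function(samples) {
  values <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  r <- rank(values)
  N <- length(r)
  rbar <- mean(r)
  ssb <- sum(tapply(r, g, function(x) length(x) * (mean(x) - rbar)^2))
  sst <- sum((r - rbar)^2)
  if (sst == 0) return(NA_real_)
  (N - 1) * ssb / sst
}

# small random spec for property loops
random_spec <- function(name = "rnd") {
  group_spec(name,
             ok_mean = runif(1, 0, 100), ok_sd = runif(1, 0, 30),
             thick_mean = runif(1, 5, 50), thick_sd = runif(1, 0, 10),
             n_animals = sample(2:8, 1), scales_per_animal = sample(2:12, 1),
             measurements_per_scale = sample(2:6, 1),
             animal_icc = runif(1, 0, 0.9))
}
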