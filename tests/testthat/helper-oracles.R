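# Independent oracle for exact binomial intervals: bisection on the binomial
# tail sums, no beta quantiles involved.
cp_oracle <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  bisect <- function(f) {
    lo <- 0; hi <- 1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  low <- if (k == 0) 0 else
    bisect(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) < alpha / 2)
  high <- if (k == n) 1 else
    bisect(function(p) stats::pbinom(k, n, p) >= alpha / 2)
  c(low = low, high = high)
}
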