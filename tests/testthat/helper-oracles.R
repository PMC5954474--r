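# Independent oracles used across tests.

# Direct evaluation of the product-moment formula and the exact t transform,
# written from the textbook definition (independent of pearson()).
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum((x - mean(x))^2)
  sy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sx * sy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# brute-force significant-figure rounding via formatted strings
signif_oracle <- function(x, digits) as.numeric(formatC(x, digits = digits, format = "g"))
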