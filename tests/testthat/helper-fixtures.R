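# Shared fixtures and independent oracles used across test files.

wakeLevel <- function()
  list(label = "A1", P_NMDA = 1.64, P_GABA = 3.98, P_AMPA = 1.22, g_Ks = 0.97)

deepLevel <- function()
  list(label = "A4", P_NMDA = 1.07, P_GABA = 9.41, P_AMPA = 1.22, g_Ks = 0.97)

# Brute-force plug-in entropies over explicit pattern strings (independent
# of the package's key-based implementation).
bruteJointEntropy <- function(m) {
  pats <- apply(m, 2, paste, collapse = "")
  p <- as.numeric(table(pats)) / length(pats)
  -sum(p * log2(p))
}

bruteMarginalEntropy <- function(row) {
  p1 <- mean(row == 1)
  p <- c(p1, 1 - p1)
  p <- p[p > 0]
  -sum(p * log2(p))
}

bruteIntegration <- function(m)
  sum(apply(m, 1, bruteMarginalEntropy)) - bruteJointEntropy(m)

bruteComplexity <- function(m) {
  N <- nrow(m)
  if (N < 2) return(0)
  hj <- bruteJointEntropy(m)
  cond <- vapply(seq_len(N), function(i)
    hj - bruteJointEntropy(m[-i, , drop = FALSE]), numeric(1))
  hj - sum(cond)
}

# Brute-force cross-correlogram: explicit double loop over spike pairs.
bruteCcg <- function(ref, cmp, lo = -19.5, bw = 1.3, nb = 30) {
  counts <- integer(nb)
  for (t in ref) for (s in cmp) {
    lag <- s - t
    if (lag >= lo && lag < lo + bw * nb) {
      b <- floor((lag - lo) / bw) + 1
      counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# Brute-force pairwise mean phase coherence.
bruteMpc <- function(ref, cmp) {
  acc <- 0 + 0i
  n <- 0
  for (t in cmp) {
    if (t < ref[1] || t >= ref[length(ref)]) next
    k <- max(which(ref <= t))
    ph <- (t - ref[k]) / (ref[k + 1] - ref[k])
    acc <- acc + exp(2i * pi * ph)
    n <- n + 1
  }
  if (n == 0) return(NA_real_)
  Mod(acc / n)
}
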