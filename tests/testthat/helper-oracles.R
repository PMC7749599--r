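# Independent oracles, deliberately naive: brute-force active-set NNLS and
# pairwise-counting AUC. These stay free of the code paths they check.

# Enumerate all 2^p active sets; solve the unconstrained LS on each passive
# set; keep the feasible (coef >= 0) solution with the smallest RSS.
nnls_bruteforce <- function(A, b) {
  p <- ncol(A)
  best <- list(coef = rep(0, p), rss = sum(b^2))
  for (mask in seq_len(2^p - 1)) {
    passive <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    Ap <- A[, passive, drop = FALSE]
    z <- tryCatch(qr.solve(Ap, b), error = function(e) NULL)
    if (is.null(z) || any(z < 0)) next
    r <- b - Ap %*% z
    rss <- sum(r^2)
    if (rss < best$rss - 1e-15) {
      coef <- rep(0, p)
      coef[passive] <- z
      best <- list(coef = coef, rss = rss)
    }
  }
  best
}

# AUC by counting all (neg, pos) pairs; ties count one half.
auc_pairs <- function(neg, pos) {
  wins <- outer(pos, neg, `>`)
  ties <- outer(pos, neg, `==`)
  (sum(wins) + 0.5 * sum(ties)) / (length(neg) * length(pos))
}

# n random probability 4-vectors (rows sum to 1).
random_simplex_rows <- function(n) {
  m <- matrix(rexp(n * 4L), n, 4L)
  m / rowSums(m)
}
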