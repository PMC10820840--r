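# Brute-force O(n^2) nondominance oracle built directly on dominates();
# the reference against which the sweep-based filter is checked.
oracle_nondominated <- function(M, senses) {
  n <- nrow(M)
  vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && dominates(M[j, ], M[i, ], senses)
    }, logical(1)))
  }, logical(1))
}

# TRUE when some point of `front` improves on `point` in BOTH objectives
# by more than the stated margins (senses respected) — "dominated beyond
# tolerance".
dominated_beyond_tol <- function(front, senses, point, tol) {
  sgn <- ifelse(senses == "min", -1, 1)
  P <- sweep(as.matrix(front), 2, sgn, `*`)
  q <- sgn * point
  any(P[, 1] > q[1] + tol[1] & P[, 2] > q[2] + tol[2])
}

# Coded points of the published Pareto-front selections (max DD & max MM,
# and rows 1-4 of max DD & min MM).
published_maxmax_rows <- function() {
  rbind(c(0.80, -0.10, 0.31), c(0.86, -0.01, 0.25),
        c(0.75, -0.29, 0.34), c(0.78, -0.20, 0.29))
}
published_maxmin_rows <- function() {
  rbind(c(0.35, -1.67, 1.61), c(0.36, -1.67, 1.43),
        c(0.32, -1.67, 1.67), c(0.37, -1.68, 1.47))
}
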