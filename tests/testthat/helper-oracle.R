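# Brute-force reference implementations, written independently of the
# package's compiled cores: plain R loops, full O(n^2) searches, stats::svd.
# Tie-breaking matches the documented convention: (distance, row index).

oracle_dist <- function(A, B) sqrt(sum((A - B)^2))

oracle_simplex <- function(states, target, k) {
  n <- nrow(states)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j) oracle_dist(states[i, ], states[j, ]),
                1)
    cand <- setdiff(order(d, seq_len(n)), i)
    nb <- cand[seq_len(min(k, length(cand)))]
    d1 <- max(d[nb[1]], 1e-12)
    w <- exp(-d[nb] / d1)
    pred[i] <- sum(w * target[nb]) / sum(w)
  }
  pred
}

oracle_cross_map <- function(states, cause, lib, k) {
  n <- nrow(states)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    d <- vapply(lib, function(j) oracle_dist(states[i, ], states[j, ]), 1)
    o <- order(d, lib)
    nb <- lib[o][lib[o] != i]
    dd <- d[o][lib[o] != i]
    m <- min(k, length(nb))
    nb <- nb[seq_len(m)]; dd <- dd[seq_len(m)]
    d1 <- max(dd[1], 1e-12)
    w <- exp(-dd / d1)
    pred[i] <- sum(w * cause[nb]) / sum(w)
  }
  cor(pred, cause)
}

oracle_smap <- function(X, y, theta, exclude_target = TRUE, svd_tol = 1e-10) {
  m <- nrow(X); E <- ncol(X)
  coefs <- matrix(NA_real_, m, E + 1)
  pred <- numeric(m)
  for (t in seq_len(m)) {
    lib <- if (exclude_target) setdiff(seq_len(m), t) else seq_len(m)
    d <- vapply(lib, function(j) oracle_dist(X[t, ], X[j, ]), 1)
    dbar <- mean(d)
    w <- exp(-theta * d / dbar)
    A <- cbind(w, X[lib, , drop = FALSE] * w)
    B <- w * y[lib]
    sv <- svd(A)
    keep <- sv$d > svd_tol * max(sv$d)
    cf <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% B) / sv$d[keep])
    coefs[t, ] <- cf
    pred[t] <- cf[1] + sum(cf[-1] * X[t, ])
  }
  list(coefficients = coefs, predictions = pred)
}
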