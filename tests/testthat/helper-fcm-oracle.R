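# Independently coded textbook fuzzy C-means, written deliberately in
# plain scalar-loop style as an oracle for the vectorized implementation.
# Same deterministic quantile initialization, same update equations.
fcm_oracle <- function(x, n_classes, m = 2, tol = 1e-9, max_iter = 2000) {
  N <- length(x)
  centers <- as.numeric(quantile(x, (seq_len(n_classes) - 0.5) / n_classes))
  U <- matrix(0, N, n_classes)
  objective <- numeric(0)
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(N)) {
      d <- abs(x[i] - centers)
      if (any(d == 0)) {
        U[i, ] <- as.numeric(d == 0) / sum(d == 0)
      } else {
        for (k in seq_len(n_classes)) {
          s <- 0
          for (j in seq_len(n_classes))
            s <- s + (d[k] / d[j])^(2 / (m - 1))
          U[i, k] <- 1 / s
        }
      }
    }
    obj <- 0
    for (i in seq_len(N))
      for (k in seq_len(n_classes))
        obj <- obj + U[i, k]^m * (x[i] - centers[k])^2
    objective <- c(objective, obj)
    new_centers <- numeric(n_classes)
    for (k in seq_len(n_classes)) {
      num <- den <- 0
      for (i in seq_len(N)) {
        w <- U[i, k]^m
        num <- num + w * x[i]
        den <- den + w
      }
      new_centers[k] <- num / den
    }
    delta <- max(abs(new_centers - centers))
    centers <- new_centers
    if (delta < tol) break
  }
  ord <- order(centers)
  list(centroids = centers[ord], memberships = U[, ord, drop = FALSE],
       objective = objective)
}
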