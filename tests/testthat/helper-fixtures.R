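# shared geometric fixtures, built in code

circle_mask <- function(n, r, ctr = (n + 1) / 2) {
  outer(seq_len(n) - ctr, seq_len(n) - ctr,
        function(y, x) sqrt(y^2 + x^2)) <= r
}

exact_circle_sdf <- function(n, r, ctr = (n + 1) / 2) {
  outer(seq_len(n) - ctr, seq_len(n) - ctr,
        function(y, x) sqrt(y^2 + x^2)) - r
}

ellipse_mask <- function(n, a, b, theta = 0, ctr = (n + 1) / 2) {
  outer(seq_len(n) - ctr, seq_len(n) - ctr, function(y, x) {
    yr <- y * cos(theta) + x * sin(theta)
    xr <- -y * sin(theta) + x * cos(theta)
    (yr / a)^2 + (xr / b)^2
  }) <= 1
}

# anisotropic total variation
total_variation <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))

# Ramanujan's second approximation to the ellipse perimeter
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Euclidean chain length with the Kulpa step-length correction, which
# removes the systematic overestimate of naive (1, sqrt 2) step weights
chain_length <- function(chain) {
  steps <- rbind(diff(chain), chain[1, ] - chain[nrow(chain), ])
  diag_ <- rowSums(abs(steps)) == 2
  0.948 * sum(!diag_) + 1.340 * sum(diag_)
}

# a quick single-slice phantom for unit tests (defaults elsewhere)
unit_phantom <- function(seed = 1L, ...) {
  make_phantom(phantom_spec(n_slices = 1L, seed = seed, ...))
}
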