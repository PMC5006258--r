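# Shared numerical helpers.

# Draw n probability triples (rows) from a Dirichlet distribution via
# normalized gamma variates.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# |sum(theta) - 1| tolerance for simplex membership checks
SIMPLEX_TOL <- 1e-9

check_simplex <- function(theta, what = "theta") {
  if (any(theta < -SIMPLEX_TOL) || abs(sum(theta) - 1) > SIMPLEX_TOL) {
    rar_abort(sprintf("%s must be a probability vector summing to 1 (got sum %.12f)",
                      what, sum(theta)))
  }
  invisible(theta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
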