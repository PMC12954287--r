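# Internal helpers: deterministic seed substreams and small numerics.

# Derive a reproducible 32-bit sub-seed from a run seed and a stream name.
# All randomness in the package flows through named substreams so that a
# single run seed fixes phantoms, fold assignment, initialization and
# batching independently of evaluation order.
sub_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 97259L
  as.integer((as.double(seed) * 48271 + h * 1009 + 12345) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; used for the analytic volume quadrature of deformed phantoms.
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stopf("'%s' must be positive and finite", name)
  }
  invisible(x)
}
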