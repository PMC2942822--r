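# Independent fixed-step RK4 integrator used as oracle for the
# matrix-exponential solver. Deliberately naive: it never touches the
# package's solver path.
rk4_solve <- function(A, x0, times, h = 1e-3) {
  f <- function(x) A %*% x
  out <- matrix(0, length(x0), length(times))
  x <- x0
  prev <- 0
  for (i in seq_along(times)) {
    target <- times[i]
    while (prev < target - 1e-12) {
      step <- min(h, target - prev)
      k1 <- f(x)
      k2 <- f(x + step / 2 * k1)
      k3 <- f(x + step / 2 * k2)
      k4 <- f(x + step * k3)
      x <- x + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      prev <- prev + step
    }
    out[, i] <- x
  }
  rownames(out) <- rownames(A)
  out
}

# small random non-negative rate vectors on the canonical topology
random_rates <- function(topology, seed) {
  set.seed(seed)
  stats::setNames(stats::runif(nrow(topology$edges), 0, 3),
                  topology$edges$param)
}
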