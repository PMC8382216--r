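# Internal numeric helpers shared across modules.

# Evaluate an expression with a local RNG seed, restoring global RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Trapezoidal integral of y over x (x ascending).
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Area-parameterized Gaussian profile: integral over the real line equals area.
gaussianProfile <- function(x, center, sigma, area) {
  area / (sigma * sqrt(2 * pi)) * exp(-((x - center)^2) / (2 * sigma^2))
}

# Logical index of x falling in any of a list of closed intervals.
inWindows <- function(x, windows) {
  hit <- rep(FALSE, length(x))
  for (w in windows) hit <- hit | (x >= w[1] & x <= w[2])
  hit
}

# Complement of a set of intervals within [lo, hi]; intervals need not be sorted.
intervalComplement <- function(windows, lo, hi) {
  if (length(windows) == 0L) return(list(c(lo, hi)))
  m <- do.call(rbind, windows)
  m <- m[order(m[, 1]), , drop = FALSE]
  # merge overlaps
  merged <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1L]) {
    last <- merged[[length(merged)]]
    if (m[i, 1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
    else merged[[length(merged) + 1L]] <- m[i, ]
  }
  out <- list()
  cur <- lo
  for (w in merged) {
    if (w[1] > cur) out[[length(out) + 1L]] <- c(cur, min(w[1], hi))
    cur <- max(cur, w[2])
    if (cur >= hi) break
  }
  if (cur < hi) out[[length(out) + 1L]] <- c(cur, hi)
  out
}

# Finite-difference Jacobian of vector-valued f at p.
fdJacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(NA_real_, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(1, abs(p[j]))
    pj <- p
    pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

# Parameter covariance from residuals and Jacobian; pseudo-inverse fallback
# when J^T J is numerically singular (e.g. a fitted band collapsed to zero area).
covFromJacobian <- function(J, resid, nPar) {
  n <- length(resid)
  dof <- max(n - nPar, 1L)
  s2 <- sum(resid^2) / dof
  JtJ <- crossprod(J)
  inv <- tryCatch(solve(JtJ), error = function(e) MASS::ginv(JtJ))
  s2 * inv
}
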