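# GF(2^8) arithmetic (reduction polynomial 0x11d, generator 2), table-driven.
# Used by the Reed-Solomon outer code; erasure-only decoding works by
# Lagrange interpolation, so only +, *, / are needed.

gf_tables <- local({
  exp_t <- integer(512)
  log_t <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp_t[i + 1L] <- x
    log_t[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwAnd(bitwXor(x, 0x11dL), 0xffL)
  }
  exp_t[256:510] <- exp_t[1:255]
  list(exp = exp_t, log = log_t)
})

gf_mul <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.integer(a), n)
  b <- rep_len(as.integer(b), n)
  out <- integer(n)
  nz <- a != 0L & b != 0L
  out[nz] <- gf_tables$exp[gf_tables$log[a[nz] + 1L] +
                           gf_tables$log[b[nz] + 1L] + 1L]
  out
}

gf_div <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.integer(a), n)
  b <- rep_len(as.integer(b), n)
  if (any(b == 0L)) stop("division by zero in GF(256)", call. = FALSE)
  out <- integer(n)
  nz <- a != 0L
  out[nz] <- gf_tables$exp[(gf_tables$log[a[nz] + 1L] -
                            gf_tables$log[b[nz] + 1L] + 255L) %% 255L + 1L]
  out
}

gf_add <- function(a, b) bitwXor(as.integer(a), as.integer(b))

# Evaluate, at points `xs`, the degree < k polynomial interpolating
# (points[i], values[, i]); `values` is a matrix with one row per byte
# position (columns = known points). Returns a matrix rows x length(xs).
gf_lagrange_eval <- function(points, values, xs) {
  k <- length(points)
  out <- matrix(0L, nrow = nrow(values), ncol = length(xs))
  for (j in seq_along(xs)) {
    x <- xs[j]
    acc <- integer(nrow(values))
    for (i in seq_len(k)) {
      num <- 1L
      den <- 1L
      for (l in seq_len(k)) {
        if (l == i) next
        num <- gf_mul(num, gf_add(x, points[l]))
        den <- gf_mul(den, gf_add(points[i], points[l]))
      }
      li <- gf_div(num, den)
      acc <- gf_add(acc, gf_mul(values[, i], li))
    }
    out[, j] <- acc
  }
  out
}
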