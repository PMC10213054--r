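# Independent oracles, written from first principles and kept free of the
# package's implementation paths.

# Literal shift-register simulation of a feed-forward convolutional
# encoder: register holds the current bit followed by the previous m bits;
# each output stream is the XOR of the register bits selected by its tap
# polynomial (MSB = current bit).
oracle_conv_encode <- function(message, m, taps, terminate = TRUE) {
  reg <- integer(m)  # previous bits, most recent first
  out <- integer(0)
  input <- c(message, if (terminate) integer(m))
  for (b in input) {
    window <- c(b, reg)
    for (tp in taps) {
      sel <- as.integer(intToBits(tp))[(m + 1):1]
      out <- c(out, sum(window * sel) %% 2L)
    }
    reg <- c(b, reg)[seq_len(m)]
  }
  out
}

# Bitwise long-division CRC over a bit vector (MSB-first register).
oracle_crc <- function(bits, poly = 0x07, init = 0xFF, width = 8L,
                       final_xor = 0x00) {
  reg <- as.integer(intToBits(init))[width:1]
  pv <- as.integer(intToBits(poly))[width:1]
  for (b in bits) {
    fb <- xor(b == 1L, reg[1] == 1L)
    reg <- c(reg[-1], 0L)
    if (fb) reg <- xor(reg == 1L, pv == 1L) * 1L
  }
  fx <- as.integer(intToBits(final_xor))[width:1]
  sum(xor(reg == 1L, fx == 1L) * 2^((width:1) - 1))
}

# Total CTC log probability of emitting `bases` from a posterior: standard
# forward recursion over the blank-extended label sequence.
oracle_ctc_forward <- function(post, bases) {
  lp <- log(pmax(post, 1e-12))
  if (!nzchar(bases)) {
    return(sum(lp[, 1]))
  }
  lab <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T")) + 1L
  ext <- rep(1L, 2L * length(lab) + 1L)
  ext[seq(2L, 2L * length(lab), 2L)] <- lab
  n <- length(ext)
  lse2 <- function(a, b) {
    m <- pmax(a, b)
    ifelse(is.infinite(m), m, m + log1p(exp(pmin(a, b) - m)))
  }
  al <- rep(-Inf, n)
  al[1] <- lp[1, 1]
  if (n > 1) al[2] <- lp[1, ext[2]]
  for (t in seq_len(nrow(post))[-1]) {
    prev <- al
    for (s in seq_len(n)) {
      v <- prev[s]
      if (s > 1) v <- lse2(v, prev[s - 1])
      if (s > 2 && ext[s] != 1L && ext[s] != ext[s - 2]) v <- lse2(v, prev[s - 2])
      al[s] <- v + lp[t, ext[s]]
    }
  }
  lse2(al[n], al[n - 1])
}

# Batched CTC forward over many base sequences (rows of `labmat`, integers
# 1..4, equal length), linear domain with per-row rescaling. Returns the
# log probability per sequence.
oracle_ctc_forward_batch <- function(post, labmat) {
  ncw <- nrow(labmat)
  len <- ncol(labmat)
  n <- 2L * len + 1L
  ext <- matrix(1L, ncw, n)
  ext[, seq(2L, 2L * len, 2L)] <- labmat + 1L
  # allow skipping the previous blank when labels differ
  allow <- matrix(FALSE, ncw, n)
  if (len > 1) {
    for (s in seq(4L, 2L * len, 2L)) allow[, s] <- ext[, s] != ext[, s - 2L]
  }
  p <- pmax(post, 1e-12)
  al <- matrix(0, ncw, n)
  logscale <- numeric(ncw)
  pt <- matrix(p[1L, ][ext], ncw, n)
  al[, 1] <- p[1L, 1L]
  al[, 2] <- pt[, 2]
  al[, -(1:2)] <- 0
  for (t in seq_len(nrow(post))[-1]) {
    shifted1 <- cbind(0, al[, -n, drop = FALSE])
    shifted2 <- cbind(0, 0, al[, -c(n - 1L, n), drop = FALSE]) * allow
    al <- (al + shifted1 + shifted2) * matrix(p[t, ][ext], ncw, n)
    mx <- pmax(apply(al, 1L, max), 1e-300)
    al <- al / mx
    logscale <- logscale + log(mx)
  }
  logscale + log(al[, n] + al[, n - 1L])
}

# All 5^T state paths of length T, grouped by their collapsed sequence,
# with total probability per collapsed sequence.
oracle_enumerate_paths <- function(post) {
  Tn <- nrow(post)
  states <- c("b", "A", "C", "G", "T")
  grid <- do.call(expand.grid, rep(list(1:5), Tn))
  probs <- rep(1, nrow(grid))
  for (t in seq_len(Tn)) probs <- probs * post[t, grid[, t]]
  collapsed <- apply(grid, 1L, function(ix) {
    r <- rle(states[ix])$values
    paste(r[r != "b"], collapse = "")
  })
  agg <- tapply(probs, collapsed, sum)
  sort(agg, decreasing = TRUE)
}

# Deterministic small fixtures ----------------------------------------------

random_bits <- function(n) sample(0:1, n, replace = TRUE)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Small experiment config used by several pipeline tests.
small_config <- function(...) {
  args <- list(...)
  base <- list(conv = conv_spec(6, "1/2"), rs = rs_params(k = 8, p = 2),
               message_bits_per_oligo = 96L,
               coverage = coverage_model("uniform", total_reads = 60L),
               channel = channel_params(), seed = 11L)
  do.call(experiment_config, utils::modifyList(base, args))
}

# A noiseless channel: deterministic sharp rows, no error events.
noiseless_channel <- function() {
  channel_params(target_error_rate = 0, ins_rate = 0, del_rate = 0,
                 sub_rate = 0, confusion_temperature = 1e-9)
}
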