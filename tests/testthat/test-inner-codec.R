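# Inner code: convolutional encoder/decoder, puncturing, CRC framing.

test_that("encoder matches an independent shift-register simulation", {
  sp <- conv_spec(m = 2, taps = c(0x7, 0x5))
  expect_identical(conv_encode(c(1, 0, 1, 1), sp),
                   oracle_conv_encode(c(1L, 0L, 1L, 1L), 2L, c(0x7L, 0x5L)))
  set.seed(101)
  for (i in 1:20) {
    msg <- random_bits(sample(1:40, 1))
    expect_identical(conv_encode(msg, sp),
                     oracle_conv_encode(as.integer(msg), 2L, c(0x7L, 0x5L)))
  }
  sp6 <- conv_spec(6)
  msg <- random_bits(16)
  expect_identical(conv_encode(msg, sp6),
                   oracle_conv_encode(as.integer(msg), 6L, sp6$taps))
})

test_that("rate-1/2 output is 2 bits per input bit plus termination flush", {
  sp <- conv_spec(6, "1/2")
  for (n in c(1, 7, 64)) {
    msg <- random_bits(n)
    expect_length(conv_encode(msg, sp, terminate = FALSE), 2 * n)
    expect_length(conv_encode(msg, sp), 2 * n + 2 * sp$m)
  }
  # empty message: only the termination flush
  expect_length(conv_encode(integer(0), sp), 2 * sp$m)
})

test_that("encoding is linear over GF(2)", {
  sp <- conv_spec(6, "1/2")
  set.seed(7)
  for (i in 1:10) {
    x <- random_bits(32)
    y <- random_bits(32)
    expect_identical(bitwXor(conv_encode(x, sp, punctured = FALSE),
                             conv_encode(y, sp, punctured = FALSE)),
                     conv_encode(bitwXor(x, y), sp, punctured = FALSE))
  }
})

test_that("puncturing selects the pattern and depuncture marks erasures", {
  sp <- conv_spec(6, "1/2")
  x <- random_bits(20)
  expect_identical(puncture(x, sp), as.integer(x))  # identity pattern
  sp34 <- conv_spec(6, "3/4")
  # 3 input steps -> 6 mother bits -> 4 transmitted
  mother <- random_bits(6)
  expect_length(puncture(mother, sp34), 4L)
  # round trip: erasures exactly at masked positions
  steps <- 9
  mother <- random_bits(2 * steps)
  dep <- depuncture(puncture(mother, sp34), sp34)
  mask <- rep(as.logical(sp34$puncture), length.out = 2 * steps)
  expect_identical(is.na(dep), !mask)
  expect_identical(dep[mask], as.integer(mother)[mask])
})

test_that("realized rates follow the puncture patterns", {
  rates <- c("1/2" = 1 / 2, "2/3" = 2 / 3, "3/4" = 3 / 4, "5/6" = 5 / 6,
             "7/8" = 7 / 8)
  for (nm in names(rates))
    expect_equal(conv_spec(6, nm)$rate, rates[[nm]], tolerance = 1e-12)
  expect_error(conv_spec(6, taps = c(0L, 5L)), "nonzero")
})

test_that("noiseless round trips hold for every memory x rate", {
  set.seed(42)
  specs <- expand.grid(m = c(6, 8, 11),
                       r = c("1/2", "2/3", "3/4", "5/6", "7/8"),
                       stringsAsFactors = FALSE)
  n_msgs <- 1000L
  per <- ceiling(n_msgs / nrow(specs))
  for (s in seq_len(nrow(specs))) {
    sp <- conv_spec(specs$m[s], specs$r[s])
    for (i in seq_len(per)) {
      msg <- random_bits(sample(8:128, 1))
      dec <- viterbi_decode_hard(conv_encode(msg, sp), sp)
      expect_identical(dec$message, as.integer(msg))
      expect_identical(dec$path_metric, 0L)
    }
  }
})

test_that("hard decoding is maximum likelihood (exhaustive check, m = 2)", {
  sp <- conv_spec(2, taps = c(0x7, 0x5))
  nb <- 10L
  # codebook of every message
  book <- t(vapply(0:(2^nb - 1), function(v) {
    conv_encode(as.integer(intToBits(v))[nb:1], sp)
  }, integer(2 * (nb + 2))))
  msgs <- t(vapply(0:(2^nb - 1), function(v)
    as.integer(intToBits(v))[nb:1], integer(nb)))
  set.seed(303)
  for (i in 1:100) {
    truth <- sample.int(2^nb, 1)
    recv <- book[truth, ]
    flips <- sample(seq_along(recv), sample(0:3, 1))
    recv[flips] <- 1L - recv[flips]
    dists <- rowSums(book != matrix(recv, nrow(book), ncol(book),
                                    byrow = TRUE))
    dec <- viterbi_decode_hard(recv, sp)
    expect_identical(dec$path_metric, as.integer(min(dists)))
    # the decoded message must be one of the ML codewords
    expect_true(any(apply(msgs[dists == min(dists), , drop = FALSE], 1,
                          identical, y = dec$message)))
  }
})

test_that("single substitutions are corrected and erasures cost nothing", {
  sp <- conv_spec(2, taps = c(0x7, 0x5))
  set.seed(5)
  msg <- random_bits(16)
  cw <- conv_encode(msg, sp)
  for (pos in c(1, 10, length(cw))) {
    noisy <- cw
    noisy[pos] <- 1L - noisy[pos]
    expect_identical(viterbi_decode_hard(noisy, sp)$message, as.integer(msg))
  }
  # all-erasure input: tie-break returns the all-zero message at metric 0
  blank <- rep(NA_integer_, length(cw))
  dec <- viterbi_decode_hard(blank, sp)
  expect_identical(dec$message, integer(16))
  expect_identical(dec$path_metric, 0L)
})

test_that("CRC matches a bitwise oracle and flags single-bit errors", {
  sp <- crc_spec()
  # published-style check input, value computed with the independent oracle
  bits <- bytes_to_bits(charToRaw("123456789"))
  expect_identical(bits_to_int(utils::tail(crc_append(bits, sp), 8)),
                   oracle_crc(bits))
  # zero message under a zero-init CRC gives the zero check byte
  z <- crc_spec(init = 0x00)
  expect_identical(bits_to_int(utils::tail(crc_append(integer(16), z), 8)), 0)
  set.seed(77)
  for (i in 1:50) {
    msg <- random_bits(sample(8:64, 1))
    fr <- crc_append(msg, sp)
    expect_true(all(crc_verify(fr, sp)))
    expect_identical(bits_to_int(utils::tail(fr, 8)),
                     oracle_crc(as.integer(msg)))
    flip <- sample(seq_along(fr), 1)
    fr[flip] <- 1L - fr[flip]
    expect_false(all(crc_verify(fr, sp)))
  }
})

test_that("CRC detects all single-bit and all <= 8-bit burst errors", {
  sp <- crc_spec()
  set.seed(88)
  for (i in 1:1000) {
    msg <- random_bits(48)
    fr <- crc_append(msg, sp)
    blen <- sample(1:8, 1)
    start <- sample(seq_len(length(fr) - blen + 1), 1)
    pat <- random_bits(blen)
    pat[1] <- 1L
    pat[blen] <- 1L  # genuine burst of exactly blen
    fr2 <- fr
    fr2[start:(start + blen - 1)] <- bitwXor(fr2[start:(start + blen - 1)],
                                             pat)
    expect_false(all(crc_verify(fr2, sp)))
  }
})

test_that("two-segment CRC localizes damage to one half", {
  sp <- crc_spec(segments = 2L)
  msg <- random_bits(40)
  fr <- crc_append(msg, sp)
  expect_identical(crc_verify(fr, sp), c(TRUE, TRUE))
  fr1 <- fr
  fr1[3] <- 1L - fr1[3]   # first half
  expect_identical(crc_verify(fr1, sp), c(FALSE, TRUE))
  fr2 <- fr
  fr2[35] <- 1L - fr2[35] # second half
  expect_identical(crc_verify(fr2, sp), c(TRUE, FALSE))
})
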