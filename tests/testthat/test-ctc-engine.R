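# CTC engine: collapse, greedy, beam search, joint list-Viterbi decoding.

test_that("greedy collapse merges runs and blanks break them", {
  expect_identical(greedy_collapse("AAAbCCbCCCGGbbbTTT"), "ACCGT")
  expect_identical(greedy_collapse("bbbb"), "")
  expect_identical(greedy_collapse(""), "")
  expect_identical(greedy_collapse("AbA"), "AA")
  expect_identical(greedy_collapse("CCbCC"), "CC")
})

test_that("greedy basecall takes the argmax path with blank-first ties", {
  post <- one_hot_posterior("AC", dwell = 2)
  expect_identical(greedy_basecall(post), "AC")
  uni <- matrix(0.2, nrow = 4, ncol = 5)
  expect_identical(greedy_basecall(uni), "")
  # zero-noise channel reproduces the sequence exactly
  seqs <- vapply(1:5, function(i) random_dna(60), character(1))
  for (i in seq_along(seqs)) {
    post <- simulate_posterior(seqs[i], noiseless_channel(), seed = i)
    expect_identical(greedy_basecall(post), seqs[i])
  }
})

test_that("posterior validation rejects malformed matrices", {
  expect_error(greedy_basecall(matrix(1, 2, 4)), "5")
  bad <- matrix(0.25, 2, 5)
  expect_error(greedy_basecall(bad), "sum")
})

test_that("beam search equals exhaustive path enumeration for tiny T", {
  set.seed(31)
  for (i in 1:5) {
    Tn <- sample(4:6, 1)
    post <- matrix(rexp(Tn * 5), Tn)
    post <- post / rowSums(post)
    oracle <- oracle_enumerate_paths(post)
    res <- beam_search_basecall(post, beam_width = 5^Tn)
    # compare the top 5 collapsed sequences and their total probabilities
    top <- head(names(oracle), 5)
    expect_identical(res$sequence[1:5], top)
    expect_equal(res$log_prob[1:5], as.numeric(log(oracle[top])),
                 tolerance = 1e-8)
  }
})

test_that("beam search degenerates to greedy for dominant rows", {
  post <- one_hot_posterior("GATTACA", dwell = 2)
  res <- beam_search_basecall(post, beam_width = 1)
  expect_identical(res$sequence, "GATTACA")
  # tiny positive drift comes from the 1e-12 probability floor
  expect_lt(abs(res$log_prob), 1e-8)
})

test_that("noiseless posteriors list-decode to the exact message at rank 1", {
  crc <- crc_spec()
  for (r in c("1/2", "2/3", "3/4", "5/6", "7/8")) {
    sp <- conv_spec(6, r)
    set.seed(41)
    framed <- crc_append(random_bits(24), crc)
    cw <- conv_encode(framed, sp)
    if (length(cw) %% 2) cw <- c(cw, 0L)
    post <- one_hot_posterior(bits_to_bases(cw), dwell = 2)
    res <- conv_ctc_list_decode(post, sp, crc, L = 4,
                                expected_message_bits = length(framed))
    expect_identical(res$messages[[1]], as.integer(framed))
    expect_true(res$candidates$crc_pass[1])
    expect_equal(res$candidates$log_score[1], 0, tolerance = 1e-9)
  }
})

test_that("exhaustive list decoding matches codeword-by-codeword CTC scoring", {
  sp <- conv_spec(2, taps = c(0x7, 0x5))
  crc <- crc_spec()
  fb <- 12L  # framed bits per message: the decoder searches all 2^12
  frames <- t(vapply(0:(2^fb - 1), function(v)
    as.integer(intToBits(v))[fb:1], integer(fb)))
  labs <- t(apply(frames, 1, function(f) {
    b <- conv_encode(f, sp)
    match(strsplit(bits_to_bases(b), "")[[1]], c("A", "C", "G", "T"))
  }))
  set.seed(51)
  for (i in 1:10) {
    truth <- sample.int(2^fb, 1)
    post <- one_hot_posterior(bits_to_bases(conv_encode(frames[truth, ], sp)),
                              dwell = 2)
    noise <- matrix(rexp(length(post)), nrow(post))
    post <- 0.55 * post + 0.45 * noise / rowSums(noise)
    oracle <- oracle_ctc_forward_batch(post, labs)
    res <- conv_ctc_list_decode(post, sp, crc, L = 2^fb,
                                expected_message_bits = fb,
                                max_active = Inf, prune_margin = Inf)
    best <- which.max(oracle)
    expect_identical(res$messages[[1]], frames[best, ])
    expect_equal(res$candidates$log_score[1], max(oracle), tolerance = 1e-6)
    # the top candidates carry exactly their oracle scores, in oracle order
    ord <- order(oracle, decreasing = TRUE)[1:16]
    got <- vapply(res$messages[1:16], function(m)
      bits_to_int(m), numeric(1))
    expect_equal(res$candidates$log_score[1:16], unname(oracle[ord]),
                 tolerance = 1e-6)
    expect_setequal(got, ord - 1)
  }
})

test_that("CRC filter takes the best passing candidate or rejects", {
  sp <- conv_spec(2, taps = c(0x7, 0x5))
  crc <- crc_spec()
  set.seed(61)
  framed <- crc_append(random_bits(8), crc)
  post <- one_hot_posterior(bits_to_bases(conv_encode(framed, sp)), dwell = 2)
  res <- conv_ctc_list_decode(post, sp, crc, L = 4,
                              expected_message_bits = length(framed))
  f <- crc_filter(res, crc)
  expect_true(f$accepted)
  expect_identical(f$rank, 1L)
  expect_identical(f$message, as.integer(framed))
  # synthetic result with planted ranks: rank 1 fails, rank 3 passes
  fake <- structure(list(candidates = data.frame(
    log_score = c(-1, -2, -3),
    crc_pass = c(FALSE, FALSE, TRUE)),
    messages = list(1:2, 3:4, as.integer(framed)), L = 3L),
    class = "list_decode_result")
  f3 <- crc_filter(fake, crc)
  expect_identical(f3$rank, 3L)
  expect_identical(f3$message, as.integer(framed))
  # all failing -> rejection
  fake$candidates$crc_pass <- c(FALSE, FALSE, FALSE)
  expect_false(crc_filter(fake, crc)$accepted)
})

test_that("a posterior fitting no codeword is rejected via the CRC", {
  sp <- conv_spec(2, taps = c(0x7, 0x5))
  crc <- crc_spec()
  set.seed(71)
  # garbage posterior of plausible length
  framed <- crc_append(random_bits(8), crc)
  n_bases <- (length(framed) + sp$m)
  post <- matrix(rexp(3 * n_bases * 5), ncol = 5)
  post <- post / rowSums(post)
  res <- conv_ctc_list_decode(post, sp, crc, L = 8,
                              expected_message_bits = length(framed))
  if (nrow(res$candidates)) {
    f <- crc_filter(res, crc)
    # with high probability nothing passes; accept only if truly passing
    expect_identical(f$accepted, any(res$candidates$crc_pass))
  } else {
    expect_identical(nrow(res$candidates), 0L)
  }
  # posterior too short to emit the codeword errors out
  expect_error(conv_ctc_list_decode(post[1:5, ], sp, crc, L = 2,
                                    expected_message_bits = length(framed)),
               "too short")
})

test_that("undetected-error rate stays near the CRC floor", {
  # weak m = 2 code at high noise: most reads fail, and accepted-but-wrong
  # messages should appear at about the 2^-8 CRC collision floor
  sp <- conv_spec(2, taps = c(0x7, 0x5))
  crc <- crc_spec()
  nb <- 8L
  n_dec <- 10000L
  set.seed(81)
  frames <- t(vapply(seq_len(50), function(i)
    crc_append(random_bits(nb), crc), integer(nb + 8L)))
  posts <- lapply(seq_len(50), function(i)
    one_hot_posterior(bits_to_bases(conv_encode(frames[i, ], sp)), dwell = 2))
  wrong_accepts <- 0L
  for (d in seq_len(n_dec)) {
    i <- (d - 1L) %% 50L + 1L
    post <- posts[[i]]
    noise <- matrix(rexp(length(post)), nrow(post))
    post <- 0.5 * post + 0.5 * noise / rowSums(noise)
    res <- conv_ctc_list_decode(post, sp, crc, L = 8,
                                expected_message_bits = nb + 8L)
    f <- crc_filter(res, crc)
    if (f$accepted && !identical(f$message, frames[i, ]))
      wrong_accepts <- wrong_accepts + 1L
  }
  p0 <- 2^-8
  bound <- p0 + 3 * sqrt(p0 * (1 - p0) / n_dec)
  expect_lte(wrong_accepts / n_dec, bound)
})

test_that("decoded-read fraction is monotone in the list size", {
  cfg <- small_config(message_bits_per_oligo = 48L, rs = rs_params(4, 1),
                      coverage = coverage_model("uniform",
                                                total_reads = 150L))
  enc <- encode_pool(with_seed(1, as.raw(sample(0:255, 24, TRUE))), cfg)
  rs <- simulate_pool_reads(enc$pool, cfg$coverage, cfg$channel, seed = 17L)
  frac <- vapply(c(1L, 2L, 4L, 8L), function(L) {
    dec <- decode_reads(rs$posteriors, enc$manifest, cfg, L = L)
    correct_decode_fraction(dec, rs$truth, enc$frames, enc$pool)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[4], 0.3)
})
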