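# Shared experiment harness for the decoding-performance studies: one
# fixed 24-byte payload, small RS geometry, 48-bit frames, and the default
# calibrated channel. Returns the fraction of reads decoded to their true
# message.
decode_fraction_study <- function(m, rate, L, n_reads, seed = 33L,
                                  prune_margin = 18) {
  cfg <- experiment_config(conv = conv_spec(m, rate), rs = rs_params(4, 1),
                           message_bits_per_oligo = 48L,
                           coverage = coverage_model("uniform",
                                                     total_reads = n_reads),
                           channel = channel_params(), seed = seed,
                           prune_margin = prune_margin)
  data <- oligostore:::with_seed(1001, as.raw(sample(0:255, 24, TRUE)))
  enc <- encode_pool(data, cfg)
  readset <- simulate_pool_reads(enc$pool, cfg$coverage, cfg$channel,
                                 seed = seed)
  vapply(L, function(l) {
    dec <- decode_reads(readset$posteriors, enc$manifest, cfg, L = l)
    correct_decode_fraction(dec, readset$truth, enc$frames, enc$pool)
  }, numeric(1))
}
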