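# Cost metrics and end-to-end pipeline orchestration.

test_that("cost arithmetic and the coverage identity", {
  expect_equal(writing_cost(1000, 10, 100), 1.0)
  expect_equal(reading_cost(1000, 30, 100), 3.0)
  expect_equal(coding_density(1000, 10, 100), 1.0)
  rep <- oligostore:::cost_report(1000, 10, 100, 30)
  expect_equal(rep$coverage * rep$writing_cost, rep$reading_cost,
               tolerance = 1e-12)
  expect_equal(rep$coverage, 3.0)
  expect_error(writing_cost(0, 10, 100))
})

test_that("encode -> zero-noise channel -> decode recovers the file exactly", {
  cfg <- small_config(channel = noiseless_channel(),
                      coverage = coverage_model("uniform",
                                                total_reads = 40L))
  res <- run_experiment(config = cfg, payload_bytes = 64L)
  expect_true(res$exact)
  expect_identical(res$recovered, res$data)
  expect_identical(mean(res$decres$outcomes$status == "decoded"), 1)
  expect_equal(res$report$coverage * res$report$writing_cost,
               res$report$reading_cost, tolerance = 1e-12)
})

test_that("identical configs and seeds reproduce the experiment exactly", {
  cfg <- small_config(coverage = coverage_model("uniform",
                                                total_reads = 30L))
  r1 <- run_experiment(config = cfg, payload_bytes = 48L)
  r2 <- run_experiment(config = cfg, payload_bytes = 48L)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$decres$outcomes, r2$decres$outcomes)
  expect_identical(r1$readset$reads, r2$readset$reads)
})

test_that("minimum-reads search finds a sharp, sane threshold", {
  cfg <- small_config(channel = noiseless_channel(),
                      rs = rs_params(k = 4, p = 1),
                      coverage = coverage_model("uniform",
                                                total_reads = 120L),
                      n_trials = 5L)
  res <- run_experiment(config = cfg, payload_bytes = 48L, min_reads = TRUE)
  expect_true(res$exact)
  mr <- res$min_reads
  expect_false(is.na(mr$min_reads))
  # need at least k segments per block observed: coupon-collector floor
  man <- res$manifest
  expect_gte(mr$min_reads, man$n_data)
  expect_lte(mr$min_reads, 120L)
  # the full set succeeds by precondition
  expect_identical(utils::tail(mr$curve$success, 1), 1)
})

test_that("raising the channel error rate never lowers min_reads", {
  base <- list(rs = rs_params(4, 1),
               coverage = coverage_model("uniform", total_reads = 150L),
               n_trials = 3L, message_bits_per_oligo = 64L)
  cfg_lo <- do.call(small_config, c(base, list(
    channel = channel_params(target_error_rate = 0.02, ins_rate = 0.005,
                             del_rate = 0.007))))
  cfg_hi <- do.call(small_config, c(base, list(
    channel = channel_params(target_error_rate = 0.08, ins_rate = 0.018,
                             del_rate = 0.026))))
  r_lo <- run_experiment(config = cfg_lo, payload_bytes = 32L,
                         min_reads = TRUE)
  r_hi <- run_experiment(config = cfg_hi, payload_bytes = 32L,
                         min_reads = TRUE)
  expect_true(r_lo$exact)
  if (r_hi$exact) {
    expect_gte(r_hi$min_reads$min_reads, r_lo$min_reads$min_reads)
  } else {
    succeed("higher-error channel failed outright, which is consistent")
  }
})

test_that("at writing cost near 1 base/bit the reading cost stays single-digit", {
  cfg <- experiment_config(conv = conv_spec(8, "3/4"), rs = rs_params(8, 2),
                           message_bits_per_oligo = 96L,
                           coverage = coverage_model("uniform",
                                                     total_reads = 150L),
                           channel = channel_params(), seed = 9L,
                           prune_margin = 20)
  res <- run_experiment(config = cfg, payload_bytes = 128L, min_reads = TRUE)
  expect_true(res$exact)
  expect_lt(abs(res$report$writing_cost - 1), 0.4)
  rc <- reading_cost(8 * 128, res$min_reads$min_reads,
                     res$manifest$payload_len_bases)
  expect_lt(rc, 10)
  expect_gt(rc, res$report$writing_cost)
})

test_that("disk pipeline round trips and refuses mismatched manifests", {
  dir <- tempfile("pipe")
  cfg <- small_config(channel = noiseless_channel(),
                      coverage = coverage_model("uniform",
                                                total_reads = 30L))
  run_pipeline(cfg, "encode", dir, payload_bytes = 48L)
  expect_true(file.exists(file.path(dir, "pool.fasta")))
  man <- read_manifest(file.path(dir, "manifest.json"))
  expect_identical(man$file_len_bytes, 48L)
  run_pipeline(cfg, "simulate", dir)
  expect_true(file.exists(file.path(dir, "posteriors.txt")))
  expect_true(file.exists(file.path(dir, "reads.fastq")))
  run_pipeline(cfg, "decode", dir)
  decoded <- readBin(file.path(dir, "decoded.bin"), "raw", 100)
  original <- readBin(file.path(dir, "payload.bin"), "raw", 100)
  expect_identical(decoded, original)
  # decoding under a different inner code must be refused
  cfg_bad <- small_config(conv = conv_spec(8, "1/2"),
                          channel = noiseless_channel())
  expect_error(run_pipeline(cfg_bad, "decode", dir), "mismatch")
  unlink(dir, recursive = TRUE)
})

test_that("the sweep verb reports decoded fractions over the m x r grid", {
  dir <- tempfile("sweep")
  cfg <- small_config(message_bits_per_oligo = 48L, rs = rs_params(4, 1),
                      coverage = coverage_model("uniform",
                                                total_reads = 25L))
  tab <- run_pipeline(cfg, "report", dir, payload_bytes = 24L,
                      sweep = list(m = c(6, 8), rate = c("1/2")))
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$decoded_fraction >= 0 & tab$decoded_fraction <= 1))
  expect_true(file.exists(file.path(dir, "sweep.csv")))
  unlink(dir, recursive = TRUE)
})
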