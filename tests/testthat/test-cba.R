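# Combinatorial barcode addresses: design, decoding, failure inference,
# hierarchical traversal.

test_that("designs are pairwise k-mer disjoint with full k-mer complements", {
  des <- design_barcode_set(seed = 4)
  seqs <- c(des$barcodes, des$scaffolds)
  expect_length(des$barcodes, 48L)
  expect_length(des$scaffolds, 7L)
  # brute-force pairwise check with an independent k-mer enumeration
  kmers <- lapply(seqs, function(s)
    unique(substring(s, 1:(nchar(s) - 8), 9:nchar(s))))
  expect_true(all(vapply(kmers, length, integer(1)) == 12L))
  for (i in seq_along(kmers)) {
    others <- unlist(kmers[-i])
    expect_false(any(kmers[[i]] %in% others))
  }
  # determinism and single-sequence edge case
  expect_identical(design_barcode_set(seed = 4)$barcodes, des$barcodes)
  one <- design_barcode_set(n_sequences = 1, seed = 2)
  expect_length(one$barcodes, 1L)
})

test_that("address space scales exponentially in the subunit count", {
  expect_identical(address_space(6, 8),
                   list(addresses = 262144, oligos_needed = 48))
  expect_identical(address_space(1, 1),
                   list(addresses = 1, oligos_needed = 1))
  expect_identical(address_space(3, 2),
                   list(addresses = 8, oligos_needed = 6))
})

test_that("assembly is injective and parses back exactly", {
  des <- design_barcode_set(seed = 4)
  a0 <- rep(0L, 6)
  con <- assemble_cba(a0, des)
  # layout: scaffold_i then that subunit's state-0 barcode, then scaffold 7
  expect_identical(substr(con, 1, 20), des$scaffolds[1])
  expect_identical(substr(con, 21, 40), des$barcodes[1])
  expect_identical(substr(con, 241, 260), des$scaffolds[7])
  set.seed(55)
  for (i in 1:10) {
    addr <- sample(0:7, 6, TRUE)
    con <- assemble_cba(addr, des)
    dec <- decode_cba(con, des, mode = "strict")
    expect_true(dec$strict_pass)
    expect_identical(dec$address, as.integer(addr))
    addr2 <- addr
    addr2[3] <- (addr2[3] + 1L) %% 8L
    expect_false(identical(assemble_cba(addr2, des), con))
  }
})

test_that("k-mer subunit decoding counts and degrades as designed", {
  des <- design_barcode_set(seed = 4)
  bc <- des$barcodes[1]
  r <- kmer_decode_subunit(bc, des, 1)
  expect_identical(r$best_state, 0L)
  expect_identical(max(r$counts), 12L)
  expect_identical(r$runner_up, 0L)
  # a substitution at position 10 kills the 9 covering k-mers: 12 - 9 = 3
  win <- bc
  old <- substr(win, 10, 10)
  substr(win, 10, 10) <- setdiff(c("A", "C", "G", "T"), old)[1]
  r2 <- kmer_decode_subunit(win, des, 1)
  expect_identical(r2$best_state, 0L)
  expect_identical(max(r2$counts), 3L)
  expect_identical(r2$runner_up, 0L)
  # unrelated windows almost never hit any candidate k-mer
  set.seed(66)
  calls <- vapply(1:1000, function(i) {
    rr <- kmer_decode_subunit(random_dna(20), des, 1)
    is.na(rr$best_state) && max(rr$counts) == 0L
  }, logical(1))
  expect_gte(mean(calls), 0.99)
})

test_that("full decoding fails only at the scrambled subunit", {
  des <- design_barcode_set(seed = 4)
  addr <- c(2L, 7L, 0L, 5L, 3L, 1L)
  con <- assemble_cba(addr, des)
  # scramble subunit 4's barcode (layout positions 141..160)
  set.seed(90)
  scr <- paste0(substr(con, 1, 140), random_dna(20), substr(con, 161, 260))
  dec <- decode_cba(scr, des, mode = "best_match")
  expect_false(dec$success)
  expect_true(is.na(dec$per_subunit$best_state[4]))
  expect_identical(dec$per_subunit$best_state[-4], addr[-4])
  # a read with no scaffold anchors is excluded from the denominator
  none <- decode_cba(random_dna(250), des)
  expect_identical(none$status, "no_cba_tag")
})

test_that("per-subunit failure inverts the independence model", {
  expect_equal(per_subunit_failure(0.70, 6), 1 - 0.70^(1 / 6),
               tolerance = 1e-12)
  expect_identical(per_subunit_failure(1, 6), 0)
  expect_equal(per_subunit_failure(0.25, 2), 0.5, tolerance = 1e-12)
  for (s in c(0.3, 0.7, 0.95)) {
    f <- per_subunit_failure(s, 6)
    expect_equal((1 - f)^6, s, tolerance = 1e-12)
  }
})

test_that("noisy CBA reads: strict <= best-match and independence holds", {
  des <- design_barcode_set(seed = 4)
  set.seed(77)
  n_reads <- 150L
  addrs <- matrix(sample(0:7, n_reads * 6, TRUE), ncol = 6)
  pars <- channel_params()
  strictok <- logical(n_reads)
  bestok <- logical(n_reads)
  sub_ok <- matrix(NA, n_reads, 6)
  for (i in seq_len(n_reads)) {
    con <- assemble_cba(addrs[i, ], des)
    call <- greedy_basecall(simulate_posterior(con, pars, seed = i))
    d_strict <- decode_cba(call, des, mode = "strict")
    d_best <- decode_cba(call, des, mode = "best_match")
    strictok[i] <- d_strict$success &&
      identical(d_strict$address, addrs[i, ])
    bestok[i] <- d_best$success && identical(d_best$address, addrs[i, ])
    if (!is.null(d_best$per_subunit))
      sub_ok[i, ] <- !is.na(d_best$per_subunit$best_state) &
        d_best$per_subunit$best_state == addrs[i, ]
  }
  expect_lte(mean(strictok), mean(bestok))
  expect_gt(mean(bestok), 0.4)
  # full-decode fraction ~ product of per-subunit success rates (+/- 10 pp)
  prod_rate <- prod(colMeans(sub_ok, na.rm = TRUE))
  expect_lte(abs(mean(bestok) - prod_rate), 0.10)
})

test_that("hierarchical traversal enriches the target exponentially", {
  des_sub <- 6L
  set.seed(88)
  n <- 10000L
  addrs <- matrix(sample(0:7, n * des_sub, TRUE), ncol = des_sub)
  target <- addrs[1, ]
  # perfect selection: only full matches remain at leak 0
  tv0 <- traverse_address(addrs, rep(1, n), target, gain = 100, leak = 0)
  full <- rowSums(addrs == matrix(target, n, des_sub, byrow = TRUE)) ==
    des_sub
  expect_true(all(tv0$abundance[!full] == 0))
  # identity when gain 1, leak 1
  tv1 <- traverse_address(addrs, rep(1, n), target, gain = 1, leak = 1)
  expect_equal(tv1$abundance, rep(1 / n, n), tolerance = 1e-12)
  # defaults: fold enrichment beyond 1e4 like a six-round nested selection
  tv <- traverse_address(addrs, rep(1, n), target)
  expect_gt(tv$fold_vs_median, 1e4)
})

test_that("design FASTA export names subunits and scaffolds", {
  des <- design_barcode_set(seed = 4)
  path <- tempfile(fileext = ".fasta")
  write_cba_design(des, path)
  x <- Biostrings::readDNAStringSet(path)
  expect_length(x, 55L)
  expect_identical(names(x)[1], "su1_state0")
  expect_identical(names(x)[55], "scaffold7")
  unlink(path)
})
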