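#' Experiment configuration
#'
#' Bundles every knob of an encode/simulate/decode experiment so that two
#' runs from the same config (and seed) are identical. The config is
#' fully serializable through the manifest.
#'
#' @param conv a [conv_spec()].
#' @param crc a [crc_spec()].
#' @param rs an [rs_params()].
#' @param message_bits_per_oligo framed message bits per oligo.
#' @param primers one-row primer data.frame (`file_id`, `fwd`, `rev`).
#' @param channel a [channel_params()].
#' @param coverage a [coverage_model()].
#' @param L list size of the inner decoder.
#' @param n_trials subsample trials in the minimum-reads search.
#' @param seed master seed.
#' @param whitening_seed keystream seed for payload whitening.
#' @param max_active,prune_margin decoder search bounds (see
#'   [conv_ctc_list_decode()]).
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(conv = conv_spec(), crc = crc_spec(),
                              rs = rs_params(), message_bits_per_oligo = 96L,
                              primers = make_primers(1), channel = channel_params(),
                              coverage = coverage_model(), L = 8L,
                              n_trials = 10L, seed = 1L, whitening_seed = 1L,
                              max_active = 50000L, prune_margin = 25) {
  structure(list(conv = conv, crc = crc, rs = rs,
                 message_bits_per_oligo = as.integer(message_bits_per_oligo),
                 primers = primers, channel = channel, coverage = coverage,
                 L = as.integer(L), n_trials = as.integer(n_trials),
                 seed = as.integer(seed),
                 whitening_seed = as.integer(whitening_seed),
                 max_active = max_active, prune_margin = prune_margin),
            class = "experiment_config")
}

# --- segment framing -------------------------------------------------------

# message layout per oligo: [index | data | filler zeros] + CRC field
frame_segment <- function(index, payload_bits, manifest, crc) {
  crc_append(c(int_to_bits(index, manifest$index_width), payload_bits,
               integer(manifest$filler_bits)), crc)
}

deframe_message <- function(framed, manifest, crc) {
  msg <- crc_strip(framed, crc)
  w <- manifest$index_width
  list(index = as.integer(bits_to_int(msg[seq_len(w)])),
       payload = msg[(w + 1L):(w + manifest$data_bits)])
}

# --- encoding --------------------------------------------------------------

#' Encode a byte payload into an oligo pool
#'
#' Whitens, segments, extends with Reed-Solomon parity, frames each
#' segment with index and CRC, applies the inner convolutional code, maps
#' to bases and attaches primers. The returned manifest carries
#' everything needed to decode (and nothing about the payload content).
#'
#' @param data raw vector.
#' @param config an [experiment_config()].
#' @return List with `pool` (oligo data.frame), `manifest`, `frames`
#'   (matrix of framed message bits, one row per oligo — ground truth for
#'   simulation studies), and `segments`.
#' @export
encode_pool <- function(data, config) {
  segs <- segment_file(data, config$message_bits_per_oligo, config$rs,
                       config$crc, whitening_seed = config$whitening_seed)
  segs <- rs_extend(segs)
  man <- segs$manifest
  n <- length(segs$index)
  frames <- matrix(0L, nrow = n, ncol = config$message_bits_per_oligo)
  oligos <- vector("list", n)
  pad_bit <- 0L
  fwd <- config$primers$fwd[1]
  rev <- config$primers$rev[1]
  fid <- config$primers$file_id[1]
  for (i in seq_len(n)) {
    framed <- frame_segment(segs$index[i], segs$payload[i, ], man, config$crc)
    frames[i, ] <- framed
    cw <- conv_encode(framed, config$conv)
    if (length(cw) %% 2L) cw <- c(cw, pad_bit)
    oligos[[i]] <- assemble_oligo(cw, fwd, rev, file_id = fid,
                                  index = segs$index[i])
  }
  pool <- do.call(rbind, oligos)
  man$pad_bit <- pad_bit
  man$payload_len_bases <- nchar(pool$payload[1])
  man$primer_len <- nchar(fwd)
  man$conv <- serialize_conv(config$conv)
  man$L <- config$L
  man$file_id <- fid
  list(pool = pool, manifest = man, frames = frames, segments = segs)
}

serialize_conv <- function(spec) {
  list(m = spec$m, taps_octal = sprintf("%o", spec$taps),
       puncture = apply(spec$puncture, 1L, function(r)
         paste(as.integer(r), collapse = "")),
       rate = spec$rate)
}

deserialize_conv <- function(x) {
  punc <- do.call(rbind, lapply(x$puncture, function(r)
    as.integer(strsplit(r, "")[[1]]) == 1L))
  conv_spec(m = x$m, taps = strtoi(unlist(x$taps_octal), 8L),
            puncture = punc)
}

#' Manifest I/O
#'
#' The manifest is a JSON sidecar holding file length, padding, index
#' width, RS geometry, whitening seed, CRC parameters and the inner-code
#' spec — sufficient to decode a pool with no other context.
#'
#' @param manifest manifest list from [encode_pool()].
#' @param path JSON path.
#' @return `read_manifest()` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  man$crc <- as.list(man$crc)
  man$conv <- as.list(man$conv)
  man
}

# --- decoding --------------------------------------------------------------

# Posterior rows spanning the called-base window [s, e) (0-based), with
# the flanking blank rows up to the neighbouring primer bases.
posterior_window <- function(post, times, s, e) {
  n <- length(times$start_row)
  if (e <= s || s < 0L || e > n) return(NULL)
  t0 <- if (s == 0L) 1L else times$end_row[s] + 1L
  t1 <- if (e == n) nrow(post) else times$start_row[e + 1L] - 1L
  if (t1 < t0) return(NULL)
  post[t0:t1, , drop = FALSE]
}

#' Decode a set of reads from their CTC posteriors
#'
#' Per read: greedy basecall, primer trimming on the basecall, extraction
#' of the posterior rows spanning the payload window, list-Viterbi
#' decoding, CRC filtering, and deframing to (index, payload).
#'
#' @param posteriors list of `T x 5` posterior matrices.
#' @param manifest decoding manifest ([encode_pool()]).
#' @param config an [experiment_config()] (decoder knobs; its conv/crc
#'   must match the manifest).
#' @param L list size override (defaults to the manifest's).
#' @return List with `outcomes` (data.frame: `read_id`, `status` in
#'   decoded/crc_rejected/trim_failed/window_failed, `index`, `rank`,
#'   trim coordinates) and `messages` (framed bits per decoded read,
#'   `NULL` otherwise).
#' @export
decode_reads <- function(posteriors, manifest, config, L = NULL) {
  check_manifest_config(manifest, config)
  if (is.null(L)) L <- manifest$L
  crc <- do.call(crc_spec, manifest$crc)
  conv <- deserialize_conv(manifest$conv)
  trellis <- build_base_trellis(conv, manifest$message_bits, manifest$pad_bit)
  n <- length(posteriors)
  ids <- names(posteriors)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_len(n))
  fwd <- config$primers$fwd[1]
  rev <- config$primers$rev[1]
  out <- data.frame(read_id = ids, status = "trim_failed",
                    index = NA_integer_, rank = NA_integer_,
                    start = NA_integer_, end = NA_integer_,
                    stringsAsFactors = FALSE)
  msgs <- vector("list", n)
  times_all <- lapply(posteriors, greedy_basecall_times)
  calls <- vapply(times_all, `[[`, character(1), "sequence")
  trims <- trim_reads(calls, fwd, rev)
  for (r in seq_len(n)) {
    if (trims$status[r] == "not_found") next
    out$start[r] <- trims$start[r]
    out$end[r] <- trims$end[r]
    win <- posterior_window(posteriors[[r]], times_all[[r]],
                            trims$start[r], trims$end[r])
    if (is.null(win) || nrow(win) < 1L) {
      out$status[r] <- "window_failed"
      next
    }
    res <- tryCatch(
      conv_ctc_list_decode(win, conv, crc, L = L,
                           expected_message_bits = manifest$message_bits,
                           max_active = config$max_active,
                           prune_margin = config$prune_margin,
                           pad_bit = manifest$pad_bit, trellis = trellis),
      error = function(e) NULL)
    if (is.null(res) || !nrow(res$candidates)) {
      out$status[r] <- "window_failed"
      next
    }
    f <- crc_filter(res, crc)
    if (!f$accepted) {
      out$status[r] <- "crc_rejected"
      next
    }
    df <- deframe_message(f$message, manifest, crc)
    if (df$index >= manifest$total_segments) {
      out$status[r] <- "crc_rejected"  # accepted bits, impossible index
      next
    }
    out$status[r] <- "decoded"
    out$index[r] <- df$index
    out$rank[r] <- f$rank
    msgs[[r]] <- f$message
  }
  list(outcomes = out, messages = msgs)
}

check_manifest_config <- function(manifest, config) {
  sc <- serialize_conv(config$conv)
  mc <- manifest$conv
  if (!identical(as.integer(mc$m), sc$m) ||
      !identical(unname(unlist(mc$taps_octal)), unname(sc$taps_octal)) ||
      !identical(unname(unlist(mc$puncture)), unname(sc$puncture)))
    stop("manifest/config mismatch: inner code specs differ; refusing to decode",
         call. = FALSE)
  if (!identical(as.integer(manifest$crc$polynomial),
                 config$crc$polynomial) ||
      !identical(as.integer(manifest$crc$segments), config$crc$segments))
    stop("manifest/config mismatch: CRC specs differ; refusing to decode",
         call. = FALSE)
  invisible(TRUE)
}

# Recover file bytes from per-read decode results (subsample optional).
recover_from_outcomes <- function(decres, manifest, crc, subset = NULL) {
  ok <- which(decres$outcomes$status == "decoded")
  if (!is.null(subset)) ok <- intersect(ok, subset)
  if (!length(ok)) stop("no decoded segments", call. = FALSE)
  idx <- decres$outcomes$index[ok]
  pl <- do.call(rbind, lapply(ok, function(r)
    deframe_message(decres$messages[[r]], manifest, crc)$payload))
  rs_recover(idx, pl, manifest)
}

#' Minimum reads for full recovery
#'
#' Random subsampling search: decode outcomes for the full read set are
#' subsampled at a geometric grid of sizes (factor 1.25), with `n_trials`
#' seeded subsamples per size; the smallest size at which *all* trials
#' recover the file byte-exactly is refined by bisection. Per-read inner
#' decoding is done once; only the outer recovery is repeated.
#'
#' @param decres [decode_reads()] result for the full read set.
#' @param manifest the decoding manifest.
#' @param config an [experiment_config()] (`n_trials`, `seed`, `crc`).
#' @param data the original payload bytes to compare against.
#' @return List with `min_reads` and `curve` (data.frame of subsample
#'   size and success fraction).
#' @export
min_reads_for_decode <- function(decres, manifest, config, data) {
  crc <- do.call(crc_spec, manifest$crc)
  n <- nrow(decres$outcomes)
  trial_ok <- function(size, trial) {
    sub <- with_seed(derive_seed(config$seed, paste0("sub", size, "_", trial)),
                     sample.int(n, size))
    out <- tryCatch(recover_from_outcomes(decres, manifest, crc, sub),
                    error = function(e) NULL)
    !is.null(out) && identical(out, data)
  }
  all_ok <- function(size)
    all(vapply(seq_len(config$n_trials), function(tr) trial_ok(size, tr),
               logical(1)))
  succ_frac <- function(size)
    mean(vapply(seq_len(config$n_trials), function(tr) trial_ok(size, tr),
                logical(1)))
  # full set must decode (precondition)
  full <- tryCatch(recover_from_outcomes(decres, manifest, crc),
                   error = function(e) NULL)
  if (is.null(full) || !identical(full, data)) {
    return(list(min_reads = NA_integer_,
                curve = data.frame(size = n, success = 0)))
  }
  sizes <- unique(c(manifest$total_segments,
                    ceiling(manifest$total_segments * 1.25^(1:20)), n))
  sizes <- sizes[sizes <= n]
  curve <- data.frame(size = sizes, success = NA_real_)
  lo <- 1L
  hi <- n
  for (i in seq_along(sizes)) {
    curve$success[i] <- succ_frac(sizes[i])
    if (curve$success[i] == 1) { hi <- sizes[i]; break }
    lo <- sizes[i]
  }
  curve <- curve[!is.na(curve$success), , drop = FALSE]
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (all_ok(mid)) hi <- mid else lo <- mid
  }
  list(min_reads = hi, curve = curve)
}

# --- end-to-end ------------------------------------------------------------

#' Run a full encode/simulate/decode experiment in memory
#'
#' @param data raw payload; if `NULL`, a seeded random payload of
#'   `payload_bytes` is used.
#' @param config an [experiment_config()].
#' @param payload_bytes size of the synthetic payload.
#' @param min_reads also run the minimum-reads subsampling search.
#' @return List with `pool`, `manifest`, `readset`, `decres` (per-read
#'   outcomes), `recovered` (raw or `NULL`), `exact` (byte-exact?),
#'   `report` (a cost report), `min_reads` (when requested).
#' @export
run_experiment <- function(data = NULL, config = experiment_config(),
                           payload_bytes = 256L, min_reads = FALSE) {
  if (is.null(data))
    data <- with_seed(derive_seed(config$seed, "payload"),
                      as.raw(sample(0:255, payload_bytes, replace = TRUE)))
  enc <- encode_pool(data, config)
  readset <- simulate_pool_reads(enc$pool, config$coverage, config$channel,
                                 seed = derive_seed(config$seed, "reads"),
                                 primer_len = enc$manifest$primer_len)
  decres <- decode_reads(readset$posteriors, enc$manifest, config)
  crc <- do.call(crc_spec, enc$manifest$crc)
  recovered <- tryCatch(recover_from_outcomes(decres, enc$manifest, crc),
                        error = function(e) NULL)
  exact <- !is.null(recovered) && identical(recovered, data)
  mr <- if (min_reads && exact)
    min_reads_for_decode(decres, enc$manifest, config, data) else NULL
  n_reads <- nrow(decres$outcomes)
  report <- cost_report(8L * length(data), nrow(enc$pool),
                        enc$manifest$payload_len_bases,
                        if (!is.null(mr) && !is.na(mr$min_reads))
                          mr$min_reads else n_reads,
                        decoded_fraction =
                          mean(decres$outcomes$status == "decoded"),
                        min_reads = if (!is.null(mr)) mr$min_reads
                                    else NA_integer_)
  list(pool = enc$pool, manifest = enc$manifest, frames = enc$frames,
       data = data, readset = readset, decres = decres,
       recovered = recovered, exact = exact, report = report,
       min_reads = mr)
}

#' Fraction of reads decoded to their true message
#'
#' Compares each decoded read's framed message with the frame of its
#' source oligo (from the simulator's truth table).
#'
#' @param decres [decode_reads()] result.
#' @param truth truth table from [simulate_pool_reads()].
#' @param frames frame matrix from [encode_pool()].
#' @param pool the oligo pool (row order matches `frames`).
#' @return Fraction of reads whose decoded message is exactly the true
#'   one.
#' @export
correct_decode_fraction <- function(decres, truth, frames, pool) {
  n <- nrow(decres$outcomes)
  ok <- vapply(seq_len(n), function(r) {
    if (decres$outcomes$status[r] != "decoded") return(FALSE)
    row <- match(truth$oligo[r], pool$name)
    identical(decres$messages[[r]], as.integer(frames[row, ]))
  }, logical(1))
  mean(ok)
}

# --- disk-backed pipeline --------------------------------------------------

#' Disk-backed pipeline verbs
#'
#' `encode` writes `pool.fasta` + `manifest.json`; `simulate` writes
#' `posteriors.txt`, `reads.fastq`, `truth.tsv`; `decode` writes
#' `decoded.bin` + `report.json` (refusing when manifest and config
#' disagree); `report` writes a decoded-fraction sweep over a memory x
#' rate grid to `sweep.csv`.
#'
#' @param config an [experiment_config()].
#' @param verb one of `"encode"`, `"simulate"`, `"decode"`, `"report"`.
#' @param out_dir artifact directory.
#' @param data raw payload (encode verb); seeded random bytes if `NULL`.
#' @param payload_bytes synthetic payload size.
#' @param sweep list with `m` and `rate` vectors (report verb).
#' @return Invisibly, the artifact paths (or the sweep data.frame).
#' @export
run_pipeline <- function(config, verb = c("encode", "simulate", "decode",
                                          "report"),
                         out_dir = ".", data = NULL, payload_bytes = 256L,
                         sweep = list(m = c(6, 8), rate = c("1/2", "3/4"))) {
  verb <- match.arg(verb)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  if (verb == "encode") {
    if (is.null(data))
      data <- with_seed(derive_seed(config$seed, "payload"),
                        as.raw(sample(0:255, payload_bytes, replace = TRUE)))
    enc <- encode_pool(data, config)
    write_pool(enc$pool, pth("pool.fasta"))
    write_manifest(enc$manifest, pth("manifest.json"))
    writeBin(data, pth("payload.bin"))
    invisible(c(pth("pool.fasta"), pth("manifest.json")))
  } else if (verb == "simulate") {
    man <- read_manifest(pth("manifest.json"))
    pool <- read_pool(pth("pool.fasta"), primer_len = man$primer_len)
    readset <- simulate_pool_reads(pool, config$coverage, config$channel,
                                   seed = derive_seed(config$seed, "reads"),
                                   primer_len = man$primer_len)
    names(readset$posteriors) <- readset$reads$read_id
    write_posteriors(readset$posteriors, pth("posteriors.txt"))
    write_fastq(readset$reads, pth("reads.fastq"))
    utils::write.table(readset$truth, pth("truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(c(pth("posteriors.txt"), pth("reads.fastq"), pth("truth.tsv")))
  } else if (verb == "decode") {
    man <- read_manifest(pth("manifest.json"))
    posts <- read_posteriors(pth("posteriors.txt"))
    decres <- decode_reads(posts, man, config)
    crc <- do.call(crc_spec, man$crc)
    recovered <- recover_from_outcomes(decres, man, crc)
    writeBin(recovered, pth("decoded.bin"))
    rep <- cost_report(8L * man$file_len_bytes, man$total_segments,
                       man$payload_len_bases, length(posts),
                       decoded_fraction =
                         mean(decres$outcomes$status == "decoded"))
    jsonlite::write_json(unclass(rep), pth("report.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(c(pth("decoded.bin"), pth("report.json")))
  } else {
    rows <- list()
    for (m in sweep$m) for (r in sweep$rate) {
      cfg <- config
      cfg$conv <- conv_spec(m = m, rate = r)
      res <- run_experiment(data = data, config = cfg,
                            payload_bytes = payload_bytes)
      rows[[length(rows) + 1L]] <-
        data.frame(m = m, rate = r,
                   decoded_fraction = res$report$decoded_fraction,
                   writing_cost = res$report$writing_cost,
                   exact = res$exact)
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, pth("sweep.csv"), sep = ",", row.names = FALSE,
                       quote = FALSE)
    invisible(tab)
  }
}
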