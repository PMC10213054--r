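#' Synthetic nanopore channel parameters
#'
#' The channel emulates a CTC basecaller's *output*: a row-stochastic
#' posterior over (blank, A, C, G, T) per time step, not raw current.
#' Each true base occupies a geometric dwell of time steps whose rows
#' favor that base, separated by blank-favored rows; substitution,
#' insertion and deletion events perturb which base a dwell favors or
#' whether it exists. Defaults are calibrated so the greedy-basecall edit
#' error of the default channel falls inside the mid-single-digit window
#' typical of the targeted flowcells (4.5-7%): the event rates sum to
#' `target_error_rate` and the row sharpness at `confusion_temperature =
#' 1` contributes almost nothing extra.
#'
#' @param target_error_rate total per-base event budget (default 0.055);
#'   when `sub_rate` is `NULL` it is split as `target_error_rate -
#'   ins_rate - del_rate` substitutions.
#' @param dwell_mean expected time steps per base (geometric, >= 1).
#' @param blank_bias probability of a blank separator row between
#'   different consecutive bases (equal neighbours always get one so the
#'   collapse cannot merge them).
#' @param confusion_temperature scale of Gaussian logit noise added to
#'   every row; larger values flatten rows and raise the basecall error.
#' @param ins_rate,del_rate per-base insertion/deletion event
#'   probabilities.
#' @param sub_rate per-base substitution probability; `NULL` derives it
#'   from the budget.
#' @param chimera_rate fraction of reads carrying a foreign fragment
#'   prefix.
#' @param sharpness logit advantage of the favored state at temperature 1.
#' @return An object of class `"channel_params"`.
#' @export
channel_params <- function(target_error_rate = 0.055, dwell_mean = 2.5,
                           blank_bias = 0.5, confusion_temperature = 1,
                           ins_rate = 0.013, del_rate = 0.019,
                           sub_rate = NULL, chimera_rate = 0,
                           sharpness = 6.5) {
  if (is.null(sub_rate)) sub_rate <- max(0, target_error_rate - ins_rate - del_rate)
  stopifnot(dwell_mean >= 1, ins_rate >= 0, ins_rate <= 1, del_rate >= 0,
            del_rate <= 1, sub_rate >= 0, sub_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(list(target_error_rate = target_error_rate,
                 dwell_mean = dwell_mean, blank_bias = blank_bias,
                 confusion_temperature = confusion_temperature,
                 ins_rate = ins_rate, del_rate = del_rate,
                 sub_rate = sub_rate, chimera_rate = chimera_rate,
                 sharpness = sharpness),
            class = "channel_params")
}

#' Per-oligo coverage model
#'
#' @param distribution `"uniform"`, `"lognormal"` (mean-1 weights with
#'   log-sd `sigma`, emulating the elevated coverage variance of
#'   bead-bound pools), or `"empirical"` (explicit `weights`).
#' @param sigma log-sd of the lognormal weights.
#' @param dropout_prob per-oligo probability of zero reads (synthesis
#'   dropout).
#' @param total_reads number of reads to draw.
#' @param weights optional explicit per-oligo weights.
#' @return An object of class `"coverage_model"`.
#' @export
coverage_model <- function(distribution = c("lognormal", "uniform",
                                            "empirical"),
                           sigma = 0.5, dropout_prob = 0, total_reads = 1000L,
                           weights = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, total_reads >= 1)
  structure(list(distribution = distribution, sigma = sigma,
                 dropout_prob = dropout_prob,
                 total_reads = as.integer(total_reads), weights = weights),
            class = "coverage_model")
}

# Draw one dwell length (>= 1) with mean `mu`.
rdwell <- function(n, mu) 1L + rgeom(n, prob = 1 / mu)

#' Draw per-oligo read counts from a coverage model
#'
#' Separated from the read simulation so coverage properties (dropout
#' counts, depth distribution) can be studied at any depth without
#' generating posteriors.
#'
#' @param coverage a [coverage_model()].
#' @param n_oligo number of oligos in the pool.
#' @param seed RNG seed.
#' @return List with `counts` (reads per oligo), `weights`, and
#'   `dropped` (logical: zeroed by dropout, not by sampling).
#' @export
draw_coverage <- function(coverage, n_oligo, seed = 1L) {
  with_seed(seed, {
    w <- switch(coverage$distribution,
                uniform = rep(1, n_oligo),
                lognormal = rlnorm(n_oligo, 0, coverage$sigma),
                empirical = {
                  stopifnot(length(coverage$weights) == n_oligo)
                  coverage$weights
                })
    dropped <- runif(n_oligo) < coverage$dropout_prob
    w[dropped] <- 0
    if (all(w == 0)) stop("all oligos dropped out", call. = FALSE)
    counts <- as.integer(stats::rmultinom(1L, coverage$total_reads,
                                          w / sum(w)))
    list(counts = counts, weights = w, dropped = dropped)
  })
}

#' Simulate a CTC posterior for one sequence
#'
#' @param true_bases DNA string pushed through the channel.
#' @param params a [channel_params()].
#' @param seed RNG seed (deterministic given seed).
#' @param provenance if `TRUE`, attach attribute `"source"`: for every
#'   posterior row the 1-based position of the true base it derives from
#'   (blank separators and insertions carry the preceding base's
#'   position, 0 before the first).
#' @return A `T x 5` row-stochastic matrix, columns (blank, A, C, G, T).
#' @export
simulate_posterior <- function(true_bases, params = channel_params(),
                               seed = 1L, provenance = FALSE) {
  stopifnot(nzchar(true_bases))
  with_seed(seed, {
    base_idx <- match(strsplit(true_bases, "")[[1]], c("A", "C", "G", "T"))
    n <- length(base_idx)
    # per-base events
    del <- runif(n) < params$del_rate
    sub <- runif(n) < params$sub_rate
    ins <- runif(n) < params$ins_rate
    shift <- sample(1:3, n, replace = TRUE)
    emit_idx <- ifelse(sub, (base_idx - 1L + shift) %% 4L + 1L, base_idx)
    # build the emission plan: favored state per row (0 = blank) + source
    fav <- integer(0)
    src <- integer(0)
    prev_emit <- 0L
    for (i in seq_len(n)) {
      if (del[i]) next
      if (length(fav)) {
        # separator blank: mandatory for equal neighbours, else Bernoulli
        if (emit_idx[i] == prev_emit || runif(1) < params$blank_bias) {
          fav <- c(fav, 0L)
          src <- c(src, i - 1L)
        }
      }
      fav <- c(fav, rep(emit_idx[i], rdwell(1L, params$dwell_mean)))
      src <- c(src, rep(i, length(fav) - length(src)))
      prev_emit <- emit_idx[i]
      if (ins[i]) {
        extra <- sample(4L, 1L)
        fav <- c(fav, 0L, rep(extra, rdwell(1L, params$dwell_mean)))
        src <- c(src, rep(i, length(fav) - length(src)))
        prev_emit <- extra
      }
    }
    if (!length(fav)) { # everything deleted: one blank row
      fav <- 0L
      src <- 0L
    }
    nT <- length(fav)
    logits <- matrix(params$confusion_temperature * stats::rnorm(nT * 5L),
                     nrow = nT)
    logits[cbind(seq_len(nT), fav + 1L)] <-
      logits[cbind(seq_len(nT), fav + 1L)] + params$sharpness
    w <- exp(logits - apply(logits, 1L, max))
    post <- w / rowSums(w)
    if (provenance) attr(post, "source") <- src
    post
  })
}

#' Simulate reads for a whole oligo pool
#'
#' Reads are drawn per the coverage model (multinomial over per-oligo
#' weights, with dropout zeroing some oligos); each read passes the full
#' oligo (primers included) through the channel. A `chimera_rate`
#' fraction of reads gets a random fragment of another oligo prepended.
#' The truth table records, per read, the source oligo and the payload
#' window both in true-sequence and in greedy-basecall coordinates
#' (0-based, half-open).
#'
#' @param pool oligo pool data.frame ([assemble_oligo()] rows).
#' @param coverage a [coverage_model()].
#' @param params a [channel_params()].
#' @param seed RNG seed.
#' @param primer_len primer length (payload window ground truth).
#' @return A list with `posteriors` (list of matrices), `reads`
#'   (data.frame `read_id`, `sequence` (greedy basecall), `quality`),
#'   and `truth` (data.frame).
#' @export
simulate_pool_reads <- function(pool, coverage = coverage_model(),
                                params = channel_params(), seed = 1L,
                                primer_len = 25L) {
  stopifnot(nrow(pool) >= 1)
  n_oligo <- nrow(pool)
  counts <- draw_coverage(coverage, n_oligo,
                          seed = derive_seed(seed, "coverage"))$counts
  oligo_of <- rep(seq_len(n_oligo), counts)
  n_reads <- length(oligo_of)
  chim <- with_seed(derive_seed(seed, "chimera"),
                    runif(n_reads) < params$chimera_rate)
  chim_src <- with_seed(derive_seed(seed, "chimsrc"),
                        sample.int(n_oligo, n_reads, replace = TRUE))
  posts <- vector("list", n_reads)
  reads <- character(n_reads)
  quals <- character(n_reads)
  truth <- data.frame(read_id = sprintf("read%05d", seq_len(n_reads)),
                      oligo = pool$name[oligo_of],
                      file_id = pool$file_id[oligo_of],
                      index = pool$index[oligo_of],
                      chimeric = chim,
                      true_start = NA_integer_, true_end = NA_integer_,
                      call_start = NA_integer_, call_end = NA_integer_,
                      stringsAsFactors = FALSE)
  frag_len <- with_seed(derive_seed(seed, "fraglen"),
                        sample.int(80L, n_reads, replace = TRUE))
  for (r in seq_len(n_reads)) {
    seq <- pool$sequence[oligo_of[r]]
    prefix <- 0L
    if (chim[r]) {
      other <- pool$sequence[chim_src[r]]
      fl <- min(frag_len[r], nchar(other))
      seq <- paste0(substr(other, nchar(other) - fl + 1L, nchar(other)), seq)
      prefix <- fl
    }
    post <- simulate_posterior(seq, params, seed = derive_seed(seed, r),
                               provenance = TRUE)
    src <- attr(post, "source")
    attr(post, "source") <- NULL
    posts[[r]] <- post
    bc <- greedy_basecall_times(post)
    reads[r] <- bc$sequence
    # per-base quality: max posterior over the base's run, Phred/Sanger
    if (nchar(bc$sequence)) {
      pmaxv <- vapply(seq_along(bc$start_row), function(i)
        max(post[bc$start_row[i]:bc$end_row[i], -1L]), numeric(1))
      q <- pmin(40L, as.integer(round(-10 * log10(pmax(1 - pmaxv, 1e-4)))))
      quals[r] <- intToUtf8(q + 33L)
    } else quals[r] <- ""
    # ground-truth payload window
    ts <- prefix + primer_len             # 0-based start in true seq
    te <- prefix + nchar(pool$sequence[oligo_of[r]]) - primer_len
    truth$true_start[r] <- ts
    truth$true_end[r] <- te
    if (nchar(bc$sequence)) {
      bsrc <- src[bc$start_row]           # source position per called base
      inwin <- which(bsrc > ts & bsrc <= te)
      if (length(inwin)) {
        truth$call_start[r] <- inwin[1L] - 1L
        truth$call_end[r] <- inwin[length(inwin)]
      }
    }
  }
  list(posteriors = posts,
       reads = data.frame(read_id = truth$read_id, sequence = reads,
                          quality = quals, stringsAsFactors = FALSE),
       truth = truth)
}

#' Write simulated reads as FASTQ
#'
#' Qualities are the per-base maximum posterior, Phred-scaled with the
#' Sanger (+33) offset.
#'
#' @param reads the `reads` data.frame from [simulate_pool_reads()].
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    writeLines(c(paste0("@", reads$read_id[i]), reads$sequence[i], "+",
                 reads$quality[i]), con)
  }
  invisible(path)
}

#' Posterior container I/O
#'
#' One dense matrix per read in a plain-text container: a header line
#' `#<read_id> <T>` followed by `T` rows of five probabilities in column
#' order (blank, A, C, G, T).
#'
#' @param posteriors named list of `T x 5` matrices.
#' @param path file path.
#' @return `read_posteriors()` returns the named list.
#' @export
write_posteriors <- function(posteriors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- names(posteriors)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(posteriors))
  for (i in seq_along(posteriors)) {
    m <- posteriors[[i]]
    writeLines(paste0("#", ids[i], " ", nrow(m)), con)
    utils::write.table(format(m, digits = 8), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_posteriors
#' @export
read_posteriors <- function(path) {
  lines <- readLines(path)
  heads <- grep("^#", lines)
  out <- vector("list", length(heads))
  ids <- character(length(heads))
  for (i in seq_along(heads)) {
    hd <- strsplit(sub("^#", "", lines[heads[i]]), " ")[[1]]
    ids[i] <- hd[1]
    nT <- as.integer(hd[2])
    block <- lines[(heads[i] + 1L):(heads[i] + nT)]
    out[[i]] <- matrix(as.numeric(unlist(strsplit(trimws(block), "[ ]+"))),
                       nrow = nT, byrow = TRUE)
  }
  names(out) <- ids
  out
}

#' Greedy basecall error of a read set
#'
#' Mean edit distance between greedy basecalls and the true sequences,
#' normalized by true length — the channel's calibration metric.
#'
#' @param sequences character vector of basecalled reads.
#' @param truths character vector of true sequences.
#' @return Mean normalized edit distance.
#' @export
basecall_error_rate <- function(sequences, truths) {
  d <- mapply(function(a, b) utils::adist(a, b), sequences, truths)
  mean(d / nchar(truths))
}
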