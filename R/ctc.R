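#' CTC collapse and greedy basecalling
#'
#' A CTC basecaller emits, per time step, a probability distribution over
#' the states (blank, A, C, G, T). A state path is collapsed to a base
#' sequence by merging runs of identical non-blank states and removing
#' blanks; a blank breaks a run, so `"CCbCC"` collapses to `"CC"` while
#' `"CCCC"` collapses to `"C"`.
#'
#' @param states character scalar over `A`, `C`, `G`, `T`, `b` (blank).
#' @return `greedy_collapse()` returns the collapsed DNA string.
#' @examples
#' greedy_collapse("AAAbCCbCCCGGbbbTTT") # "ACCGT"
#' @export
greedy_collapse <- function(states) {
  if (!nzchar(states)) return("")
  ch <- strsplit(states, "")[[1]]
  r <- rle(ch)$values
  paste(r[r != "b"], collapse = "")
}

# Validate a T x 5 posterior matrix, columns (blank, A, C, G, T).
check_posterior <- function(posterior) {
  if (!is.matrix(posterior) || ncol(posterior) != 5)
    stop("posterior must be a T x 5 matrix (blank, A, C, G, T)", call. = FALSE)
  if (any(posterior < 0))
    stop("posterior entries must be nonnegative", call. = FALSE)
  if (any(abs(rowSums(posterior) - 1) > 1e-9))
    stop("posterior rows must sum to 1", call. = FALSE)
  posterior
}

# Per-row argmax states; ties resolve to blank, then alphabetical, which is
# the column order (blank, A, C, G, T).
posterior_argmax <- function(posterior) {
  c("b", "A", "C", "G", "T")[max.col(posterior, ties.method = "first")]
}

#' @rdname greedy_collapse
#' @param posterior numeric `T x 5` matrix of row-stochastic probabilities
#'   in column order (blank, A, C, G, T).
#' @return `greedy_basecall()` returns the collapsed argmax sequence;
#'   `greedy_basecall_times()` additionally returns, per emitted base, the
#'   first and last posterior row of its run (0-based, half-open is *not*
#'   used here: both are inclusive row indices, 1-based).
#' @export
greedy_basecall <- function(posterior) {
  check_posterior(posterior)
  greedy_collapse(paste(posterior_argmax(posterior), collapse = ""))
}

# Greedy basecall plus the posterior-row extent of every emitted base.
greedy_basecall_times <- function(posterior) {
  check_posterior(posterior)
  st <- posterior_argmax(posterior)
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "b"
  list(sequence = paste(r$values[keep], collapse = ""),
       start_row = starts[keep], end_row = ends[keep])
}

#' Beam-search basecalling
#'
#' Prefix beam search over the CTC posterior: each candidate sequence's
#' probability is the sum over all state paths that collapse to it,
#' tracked as separate blank-ending and non-blank-ending path masses and
#' merged in the log domain. The beam is pruned to `beam_width` after each
#' step's merge.
#'
#' @param posterior numeric `T x 5` row-stochastic matrix.
#' @param beam_width maximum number of candidate sequences retained.
#' @return A data.frame with columns `sequence` and `log_prob`, ranked by
#'   decreasing log probability.
#' @export
beam_search_basecall <- function(posterior, beam_width = 8L) {
  check_posterior(posterior)
  stopifnot(beam_width >= 1)
  lp <- log(pmax(posterior, 1e-12))
  res <- cpp_beam_search(lp, as.integer(beam_width))
  data.frame(sequence = as.character(res$sequences),
             log_prob = as.numeric(res$log_probs),
             stringsAsFactors = FALSE)
}

# Vectorized parity of integer vectors (for tap outputs).
parity_int <- function(x) {
  x <- bitwXor(x, bitwShiftR(x, 1L))
  x <- bitwXor(x, bitwShiftR(x, 2L))
  x <- bitwXor(x, bitwShiftR(x, 4L))
  x <- bitwXor(x, bitwShiftR(x, 8L))
  bitwAnd(x, 1L)
}

#' Joint code/CTC trellis over base positions
#'
#' Builds, for every base position of an inner-code codeword, the set of
#' allowed transitions of the joint trellis whose states are
#' (convolutional-code state, position in the base sequence). Each base
#' carries two transmitted bits; puncturing makes the correspondence
#' between encoder steps and bases non-uniform, so a transition may consume
#' zero, one or two fresh message bits, and a half-consumed encoder step
#' leaves one "pending" transmitted bit that is folded into the node
#' identity of the next position. If the transmitted bit count is odd the
#' final base is completed with a fixed pad bit (recorded in the manifest).
#'
#' @param spec a [conv_spec()].
#' @param n_message_bits number of free message bits (CRC included) per
#'   oligo; flush bits are appended automatically.
#' @param pad_bit bit used to complete a trailing half-filled base.
#' @return A list with `transitions` (one integer matrix per position with
#'   columns from, to, base, nfree, freebits), `n_bases`, `node_span`,
#'   `n_tx_bits`.
#' @keywords internal
#' @export
build_base_trellis <- function(spec, n_message_bits, pad_bit = 0L) {
  m <- spec$m
  S <- length(spec$taps)
  if (S != 2L)
    stop("the base trellis assumes a rate-1/2 mother code (2 streams)",
         call. = FALSE)
  steps <- n_message_bits + spec$termination_bits
  mask <- puncture_mask(spec, steps)
  slot_step <- rep(seq_len(steps) - 1L, each = S)[mask]  # 0-based step per tx bit
  n_tx <- length(slot_step)
  n_bases <- as.integer(ceiling(n_tx / 2))
  nstates <- 2L^m
  states <- 0:(nstates - 1L)

  # which streams each step transmits (phase of the puncture pattern)
  period <- ncol(spec$puncture)
  kept_streams <- lapply(seq_len(steps), function(t)
    which(spec$puncture[, (t - 1L) %% period + 1L]) - 1L)
  # first transmitted-slot index (0-based) of each step
  first_slot <- vapply(0:(steps - 1L), function(t)
    match(t, slot_step) - 1L, numeric(1))

  out <- vector("list", n_bases)
  for (p in seq_len(n_bases) - 1L) {
    slots <- 2L * p + c(0L, 1L)
    slots <- slots[slots < n_tx]
    nslots <- length(slots)
    stepsp <- slot_step[slots + 1L]
    # a pending bit enters when the first slot's step started in base p - 1
    pend_in <- first_slot[stepsp[1] + 1L] < 2L * p
    new_steps <- unique(if (pend_in) stepsp[-1] else stepsp)
    free_steps <- new_steps[new_steps < n_message_bits]
    nfree <- length(free_steps)

    combos <- if (nfree > 0) 0:(2L^nfree - 1L) else 0L
    pvals <- if (pend_in) c(0L, 1L) else 0L
    grid <- expand.grid(state = states, combo = combos, pend = pvals,
                        KEEP.OUT.ATTRS = FALSE)
    st <- grid$state
    produced <- list()
    for (tstep in new_steps) {
      bit <- if (tstep < n_message_bits) {
        j <- match(tstep, free_steps)
        bitwAnd(bitwShiftR(grid$combo, nfree - j), 1L)
      } else rep(0L, nrow(grid))
      reg <- bitwShiftL(bit, m) + st
      for (s in kept_streams[[tstep + 1L]])
        produced[[length(produced) + 1L]] <-
          parity_int(bitwAnd(reg, spec$taps[s + 1L]))
      st <- bitwShiftR(reg, 1L)
    }
    # this base's two bits: pending first, then produced bits in order; a
    # missing trailing slot is completed by the fixed pad bit
    queue <- c(if (pend_in) list(grid$pend), produced)
    b1 <- if (length(queue) >= 1L) queue[[1L]] else rep(pad_bit, nrow(grid))
    b2 <- if (nslots == 2L && length(queue) >= 2L) queue[[2L]]
          else rep(pad_bit, nrow(grid))
    leftover <- if (length(queue) > nslots) queue[[nslots + 1L]] else NULL

    from_node <- grid$state + nstates * grid$pend
    to_node <- st + if (!is.null(leftover)) nstates * leftover else 0L
    freebits <- if (nfree > 0L) grid$combo else rep(0L, nrow(grid))
    out[[p + 1L]] <- cbind(from = from_node, to = to_node,
                           base = 2L * b1 + b2,
                           nfree = rep(nfree, nrow(grid)),
                           freebits = freebits)
  }
  list(transitions = out, n_bases = n_bases, node_span = 2L * nstates,
       n_tx_bits = n_tx, n_message_bits = n_message_bits, pad_bit = pad_bit)
}

#' List-Viterbi decoding over a CTC posterior
#'
#' The core decoder: a dynamic program over joint states
#' (convolutional-code state, position in the base sequence). Only base
#' extensions consistent with some input-bit extension of the code are
#' allowed; per state the top-`L` candidate message prefixes are retained,
#' with separate blank-ending and non-blank-ending path scores merged by
#' logsumexp whenever paths recombine on the same prefix. The `L` best
#' full-length messages ending in the all-zero code state are returned,
#' CRC-checked.
#'
#' Probabilities are floored at 1e-12 before the log transform. Candidates
#' with equal scores are ordered by lexicographically smaller message.
#' `max_active` and `prune_margin` bound the active search front; set them
#' to `Inf` for exact list decoding on small problems.
#'
#' @param posterior numeric `T x 5` row-stochastic matrix covering only the
#'   payload window (primers already trimmed).
#' @param conv a [conv_spec()].
#' @param crc a [crc_spec()].
#' @param L list size (default 8).
#' @param expected_message_bits framed message length (payload + index +
#'   CRC bits), known from the manifest.
#' @param max_active cap on simultaneously active candidates.
#' @param prune_margin drop candidates more than this many log units below
#'   the current best.
#' @param pad_bit bit completing a trailing half base (manifest-recorded).
#' @param trellis optional precomputed [build_base_trellis()] result,
#'   reused across the reads of one experiment.
#' @return An object of class `"list_decode_result"`: a list with
#'   `candidates` (data.frame of `log_score`, `crc_pass` and, in
#'   two-segment mode, `crc_pass1`/`crc_pass2`) and `messages` (list of
#'   framed bit vectors), sorted by decreasing score.
#' @examples
#' sp <- conv_spec(m = 2, taps = c(0x7, 0x5))
#' crc <- crc_spec()
#' framed <- crc_append(c(1, 0, 1, 0), crc)
#' bases <- bits_to_bases(conv_encode(framed, sp))
#' post <- one_hot_posterior(bases, dwell = 2)
#' res <- conv_ctc_list_decode(post, sp, crc, L = 4,
#'                             expected_message_bits = length(framed))
#' res$candidates$crc_pass[1]
#' @export
conv_ctc_list_decode <- function(posterior, conv, crc, L = 8L,
                                 expected_message_bits,
                                 max_active = 50000L, prune_margin = 25,
                                 pad_bit = 0L, trellis = NULL) {
  check_posterior(posterior)
  if (is.null(trellis))
    trellis <- build_base_trellis(conv, expected_message_bits, pad_bit)
  if (nrow(posterior) < trellis$n_bases)
    stop("posterior too short to emit ", trellis$n_bases, " bases",
         call. = FALSE)
  lp <- log(pmax(posterior, 1e-12))
  ma <- if (is.finite(max_active)) as.integer(max_active) else -1L
  res <- cpp_ctc_list_decode(lp, trellis$transitions, trellis$node_span,
                             as.integer(L), ma, as.numeric(prune_margin))
  msgs <- res$messages
  if (length(msgs) == 0)
    return(structure(list(candidates = data.frame(log_score = numeric(0),
                                                  crc_pass = logical(0)),
                          messages = list(), L = L),
                     class = "list_decode_result"))
  checks <- lapply(msgs, crc_verify, spec = crc)
  cand <- data.frame(log_score = as.numeric(res$log_scores),
                     crc_pass = vapply(checks, all, logical(1)))
  if (crc$segments == 2L) {
    cand$crc_pass1 <- vapply(checks, `[`, logical(1), 1L)
    cand$crc_pass2 <- vapply(checks, `[`, logical(1), 2L)
  }
  structure(list(candidates = cand, messages = msgs, L = L),
            class = "list_decode_result")
}

#' @export
print.list_decode_result <- function(x, ...) {
  cat(sprintf("list decode: %d candidate(s), %d passing CRC\n",
              nrow(x$candidates), sum(x$candidates$crc_pass)))
  invisible(x)
}

#' Accept the best CRC-passing candidate
#'
#' The highest-scoring candidate that passes the CRC wins; if none passes,
#' the read is rejected. In two-segment mode each half is taken from the
#' first candidate whose CRC for that half passes, so a read is usable as
#' long as at least one half decodes correctly.
#'
#' @param result a [conv_ctc_list_decode()] result.
#' @param crc the [crc_spec()] used at encoding time.
#' @return A list with `accepted` (logical), `message` (framed bits, CRC
#'   included, or `NULL`), `rank` (1-based rank of the winning candidate,
#'   `NA` when halves come from different candidates), and in two-segment
#'   mode `half_ok` (logical pair).
#' @export
crc_filter <- function(result, crc = crc_spec()) {
  cand <- result$candidates
  if (crc$segments == 1L || is.null(cand$crc_pass1)) {
    hit <- which(cand$crc_pass)
    if (!length(hit))
      return(list(accepted = FALSE, message = NULL, rank = NA_integer_))
    list(accepted = TRUE, message = result$messages[[hit[1]]],
         rank = hit[1])
  } else {
    h1 <- which(cand$crc_pass1)
    h2 <- which(cand$crc_pass2)
    if (!length(h1) && !length(h2))
      return(list(accepted = FALSE, message = NULL, rank = NA_integer_,
                  half_ok = c(FALSE, FALSE)))
    both <- which(cand$crc_pass1 & cand$crc_pass2)
    if (length(both))
      return(list(accepted = TRUE, message = result$messages[[both[1]]],
                  rank = both[1], half_ok = c(TRUE, TRUE)))
    # stitch halves from the first candidate passing each half
    n <- length(result$messages[[1]]) - 2L * crc$width
    h <- crc_halves(n)
    pick <- function(idx, part) {
      if (!length(idx)) return(NULL)
      crc_strip(result$messages[[idx[1]]], crc)[part]
    }
    half1 <- pick(h1, h[[1]])
    half2 <- pick(h2, h[[2]])
    if (is.null(half1) || is.null(half2))
      return(list(accepted = FALSE, message = NULL, rank = NA_integer_,
                  half_ok = c(length(h1) > 0, length(h2) > 0)))
    list(accepted = TRUE,
         message = crc_append(c(half1, half2), crc),
         rank = NA_integer_, half_ok = c(TRUE, TRUE))
  }
}

#' One-hot posterior for a base sequence
#'
#' Builds a noiseless CTC posterior spelling `bases`, with `dwell` rows per
#' base and a blank row between consecutive bases. Useful for tests and
#' worked examples.
#'
#' @param bases DNA string.
#' @param dwell rows per base.
#' @return A `T x 5` one-hot matrix (blank, A, C, G, T).
#' @export
one_hot_posterior <- function(bases, dwell = 2L) {
  ch <- strsplit(bases, "")[[1]]
  idx <- match(ch, c("A", "C", "G", "T")) + 1L
  cols <- unlist(lapply(seq_along(idx), function(i) {
    c(rep(idx[i], dwell), if (i < length(idx)) 1L)
  }))
  mat <- matrix(0, nrow = length(cols), ncol = 5)
  mat[cbind(seq_along(cols), cols)] <- 1
  mat
}
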