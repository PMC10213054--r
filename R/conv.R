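#' Convolutional code specification
#'
#' The inner code is a feed-forward convolutional code of memory `m`
#' (state = the last `m` input bits), encoded at a mother rate of
#' 1/`length(taps)` and punctured up to the requested rate. Default
#' generator taps are published maximum-free-distance polynomials for each
#' memory; default puncturing patterns are standard rate-compatible
#' patterns derived from the rate-1/2 mother code. Termination is
#' zero-tail: `m` zero flush bits return the encoder to the all-zero
#' state.
#'
#' Taps are bitmasks of width `m + 1` with the *current* input bit as the
#' most significant position, so octal 133 with `m = 6` means
#' \eqn{1 + D + D^2 + D^3 + D^6}.
#'
#' @param m code memory (number of state bits), at least 1.
#' @param rate one of `"1/2"`, `"2/3"`, `"3/4"`, `"5/6"`, `"7/8"`, or a
#'   numeric giving the same value.
#' @param taps integer vector of generator polynomials (one per output
#'   stream); `NULL` selects the published default for `m`.
#' @param puncture logical matrix (streams x period) marking transmitted
#'   positions; `NULL` selects the standard pattern for `rate`.
#' @return An object of class `"conv_spec"` with elements `m`, `taps`,
#'   `puncture`, `rate` (realized rate), `termination_bits`.
#' @examples
#' sp <- conv_spec(m = 6, rate = "1/2")
#' sp$rate
#' @export
conv_spec <- function(m = 6L, rate = "1/2", taps = NULL, puncture = NULL) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  if (is.null(taps)) {
    taps <- switch(as.character(m),
      "2" = c(0x7L, 0x5L),                      # octal 7, 5
      "6" = c(strtoi("133", 8L), strtoi("171", 8L)),
      "8" = c(strtoi("561", 8L), strtoi("753", 8L)),
      "11" = c(strtoi("5537", 8L), strtoi("6131", 8L)),
      stop("no default taps for m = ", m, "; supply `taps`", call. = FALSE))
  }
  taps <- as.integer(taps)
  if (any(taps == 0L)) stop("generator taps must be nonzero", call. = FALSE)
  if (any(taps >= 2^(m + 1)))
    stop("taps wider than m + 1 bits", call. = FALSE)
  if (is.null(puncture)) {
    rate_key <- if (is.numeric(rate)) {
      kn <- c("1/2" = 1 / 2, "2/3" = 2 / 3, "3/4" = 3 / 4,
              "5/6" = 5 / 6, "7/8" = 7 / 8)
      nm <- names(kn)[which(abs(kn - rate) < 1e-9)]
      if (!length(nm)) stop("no standard puncturing for rate ", rate, call. = FALSE)
      nm
    } else as.character(rate)
    puncture <- switch(rate_key,
      "1/2" = matrix(TRUE, 2, 1),
      "2/3" = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2),
      "3/4" = matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE), 2, 3),
      "5/6" = matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                       TRUE, FALSE, FALSE, TRUE), 2, 5),
      "7/8" = matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                       FALSE, TRUE, TRUE, FALSE, FALSE, TRUE), 2, 7),
      stop("no standard puncturing for rate ", rate_key, call. = FALSE))
  }
  puncture <- matrix(as.logical(puncture), nrow = length(taps))
  if (any(colSums(puncture) < 1))
    stop("puncture pattern must transmit at least one bit per step", call. = FALSE)
  structure(list(m = m, taps = taps, puncture = puncture,
                 rate = ncol(puncture) / sum(puncture),
                 termination_bits = m),
            class = "conv_spec")
}

#' @export
print.conv_spec <- function(x, ...) {
  cat(sprintf("convolutional code: m = %d, taps (octal) %s, rate %d/%d\n",
              x$m, paste(sprintf("%o", x$taps), collapse = "/"),
              ncol(x$puncture), sum(x$puncture)))
  invisible(x)
}

# Keep-mask over the interleaved mother stream for `steps` encoder steps.
puncture_mask <- function(spec, steps) {
  period <- ncol(spec$puncture)
  phase <- (seq_len(steps) - 1L) %% period + 1L
  as.vector(spec$puncture[, phase])
}

#' Convolutional encoding and puncturing
#'
#' `conv_encode()` runs the shift-register encoder over the message plus
#' `m` zero flush bits and applies the puncturing pattern, returning the
#' transmitted bit stream. `puncture()` / `depuncture()` convert between
#' the mother-rate stream and the transmitted stream; depunctured streams
#' carry `NA` at punctured positions, which downstream decoders treat as
#' zero-information erasures.
#'
#' @param message,stream 0/1 integer bit vectors (`depuncture()` input may
#'   contain `NA` erasures from the channel).
#' @param spec a [conv_spec()].
#' @param punctured if `FALSE`, return the unpunctured mother-rate stream.
#' @param terminate if `FALSE`, omit the zero-tail flush (used by the
#'   linearity property; normal framing always terminates).
#' @return `conv_encode()` and `puncture()` return 0/1 integer vectors;
#'   `depuncture()` returns an integer vector with `NA` erasure marks.
#' @examples
#' sp <- conv_spec(m = 2, taps = c(0x7, 0x5), rate = "1/2")
#' conv_encode(c(1, 0, 1, 1), sp)
#' @export
conv_encode <- function(message, spec, punctured = TRUE, terminate = TRUE) {
  message <- check_bits(message)
  mother <- cpp_conv_encode(message, spec$m, spec$taps,
                            if (terminate) spec$termination_bits else 0L)
  if (!punctured) return(mother)
  puncture(mother, spec)
}

#' @rdname conv_encode
#' @export
puncture <- function(stream, spec) {
  steps <- length(stream) %/% length(spec$taps)
  if (length(stream) %% length(spec$taps) != 0)
    stop("mother stream length must be a multiple of the stream count",
         call. = FALSE)
  stream[puncture_mask(spec, steps)]
}

#' @rdname conv_encode
#' @export
depuncture <- function(stream, spec) {
  # Find the number of encoder steps consistent with the transmitted length.
  period <- ncol(spec$puncture)
  per_period <- sum(spec$puncture)
  kept_cum <- cumsum(colSums(spec$puncture))
  full <- length(stream) %/% per_period
  rem <- length(stream) %% per_period
  extra <- if (rem == 0) 0L else {
    w <- which(kept_cum == rem)
    if (!length(w))
      stop("transmitted length not consistent with puncture pattern",
           call. = FALSE)
    w[1]
  }
  steps <- full * period + extra
  mask <- puncture_mask(spec, steps)
  out <- rep(NA_integer_, length(mask))
  out[mask] <- as.integer(stream)
  out
}

#' Hard-decision Viterbi decoding
#'
#' Maximum-likelihood decoding of a transmitted stream under the Hamming
#' metric. The input is the transmitted (punctured) stream; punctured
#' positions are reinserted as erasures and, like `NA` channel erasures,
#' contribute nothing to the path metric. Ties are broken deterministically
#' (smaller predecessor state survives, so the all-zero message wins on a
#' fully erased input).
#'
#' @param received 0/1 integer vector, possibly with `NA` erasures, in the
#'   transmitted domain.
#' @param spec a [conv_spec()].
#' @return A list with `message` (decoded bits) and `path_metric` (Hamming
#'   distance between `received` and the re-encoded codeword).
#' @examples
#' sp <- conv_spec(m = 2, taps = c(0x7, 0x5))
#' cw <- conv_encode(c(1, 0, 1, 1), sp)
#' viterbi_decode_hard(cw, sp)$message
#' @export
viterbi_decode_hard <- function(received, spec) {
  mother <- depuncture(received, spec)
  S <- length(spec$taps)
  steps <- length(mother) %/% S
  if (length(mother) %% S != 0)
    stop("received length inconsistent with an integer number of trellis steps",
         call. = FALSE)
  n_msg <- steps - spec$termination_bits
  if (n_msg < 0) stop("received stream shorter than the termination tail",
                      call. = FALSE)
  mother[is.na(mother)] <- -1L
  res <- cpp_viterbi_hard(as.integer(mother), spec$m, spec$taps, n_msg)
  list(message = res$message, path_metric = res$metric)
}
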