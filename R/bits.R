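#' Bit vector utilities
#'
#' Messages, codewords and CRC frames are plain integer vectors over
#' \{0, 1\}. These helpers convert between bytes (raw), integers and bit
#' vectors. Bit order within a byte is most-significant-bit first, so
#' `bytes_to_bits(as.raw(1))` ends in a 1.
#'
#' @param bits integer vector of 0/1.
#' @param bytes raw vector.
#' @param x non-negative integer scalar.
#' @param width number of bits for fixed-width integer encoding.
#' @return `bytes_to_bits()` and `int_to_bits()` return a 0/1 integer
#'   vector; `bits_to_bytes()` returns a raw vector; `bits_to_int()`
#'   returns a numeric scalar.
#' @examples
#' bytes_to_bits(as.raw(c(0xA5)))
#' bits_to_int(c(1, 0, 1))
#' @name bits
NULL

check_bits <- function(bits) {
  if (length(bits) && !all(bits %in% c(0L, 1L)))
    stop("bit vector may contain only 0 and 1", call. = FALSE)
  as.integer(bits)
}

#' @rdname bits
#' @export
bytes_to_bits <- function(bytes) {
  if (!length(bytes)) return(integer(0))
  m <- vapply(7:0, function(s) bitwAnd(bitwShiftR(as.integer(bytes), s), 1L),
              integer(length(bytes)))
  as.integer(t(matrix(m, ncol = 8)))
}

#' @rdname bits
#' @export
bits_to_bytes <- function(bits) {
  bits <- check_bits(bits)
  if (length(bits) %% 8 != 0)
    stop("bit length must be a multiple of 8", call. = FALSE)
  if (!length(bits)) return(raw(0))
  m <- matrix(bits, nrow = 8)
  as.raw(colSums(m * 2^(7:0)))
}

#' @rdname bits
#' @export
int_to_bits <- function(x, width) {
  if (x < 0 || (width < 64 && x >= 2^width))
    stop("integer does not fit in ", width, " bits", call. = FALSE)
  out <- integer(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- x %% 2
    x <- x %/% 2
  }
  as.integer(out)
}

#' @rdname bits
#' @export
bits_to_int <- function(bits) {
  bits <- check_bits(bits)
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}
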