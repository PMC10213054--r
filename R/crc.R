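#' CRC framing for oligo segments
#'
#' Each oligo segment carries an 8-bit cyclic redundancy check so that a
#' residual error left by the inner decoder can be detected and the read
#' discarded. The default variant is CRC-8 with polynomial 0x07, initial
#' value 0xFF and zero final XOR. The nonzero init matters: with a zero
#' init, a bit-shifted copy of a valid frame is again a multiple of the
#' generator polynomial, and shifted frames are exactly what a misaligned
#' payload window makes the inner decoder produce, so shifted garbage
#' would pass the check systematically. In two-segment mode the message
#' is split into halves of `ceiling(n/2)` and `floor(n/2)` bits and each
#' half gets its own CRC, so a burst that corrupts only one half still
#' leaves the other verifiable.
#'
#' @param width CRC width in bits (8).
#' @param polynomial generator polynomial bitmask, x^width implied.
#' @param init initial register value.
#' @param final_xor value XORed into the register at the end.
#' @param segments 1 (one CRC over the whole message) or 2 (one per half).
#' @return `crc_spec()` returns an object of class `"crc_spec"`.
#' @examples
#' sp <- crc_spec()
#' framed <- crc_append(bytes_to_bits(charToRaw("hi")), sp)
#' crc_verify(framed, sp)
#' @export
crc_spec <- function(width = 8L, polynomial = 0x07, init = 0xFF,
                     final_xor = 0x00, segments = 1L) {
  stopifnot(width == 8L, segments %in% c(1L, 2L))
  structure(list(width = as.integer(width), polynomial = as.integer(polynomial),
                 init = as.integer(init), final_xor = as.integer(final_xor),
                 segments = as.integer(segments)),
            class = "crc_spec")
}

# Bitwise CRC register update over a 0/1 bit vector (MSB-first).
crc_bits <- function(bits, spec) {
  reg <- spec$init
  poly <- spec$polynomial
  top <- bitwShiftL(1L, spec$width - 1L)
  mask <- bitwShiftL(1L, spec$width) - 1L
  for (b in bits) {
    fb <- bitwXor(b, ifelse(bitwAnd(reg, top) != 0L, 1L, 0L))
    reg <- bitwAnd(bitwShiftL(reg, 1L), mask)
    if (fb) reg <- bitwXor(reg, poly)
  }
  bitwXor(reg, spec$final_xor)
}

crc_halves <- function(n) {
  h1 <- ceiling(n / 2)
  list(seq_len(h1), if (n > h1) (h1 + 1L):n else integer(0))
}

#' @rdname crc_spec
#' @param message,framed 0/1 integer bit vectors.
#' @export
crc_append <- function(message, spec = crc_spec()) {
  message <- check_bits(message)
  if (spec$segments == 1L) {
    c(message, int_to_bits(crc_bits(message, spec), spec$width))
  } else {
    if (length(message) < 2L)
      stop("two-segment CRC needs at least 2 message bits", call. = FALSE)
    h <- crc_halves(length(message))
    c(message,
      int_to_bits(crc_bits(message[h[[1]]], spec), spec$width),
      int_to_bits(crc_bits(message[h[[2]]], spec), spec$width))
  }
}

#' @rdname crc_spec
#' @return `crc_verify()` returns a logical vector with one element per
#'   protected segment (length 1 or 2).
#' @export
crc_verify <- function(framed, spec = crc_spec()) {
  framed <- check_bits(framed)
  ncrc <- spec$segments * spec$width
  if (length(framed) < ncrc)
    stop("framed message shorter than its CRC field", call. = FALSE)
  n <- length(framed) - ncrc
  message <- framed[seq_len(n)]
  crcs <- framed[(n + 1L):length(framed)]
  if (spec$segments == 1L) {
    crc_bits(message, spec) == bits_to_int(crcs)
  } else {
    h <- crc_halves(n)
    c(crc_bits(message[h[[1]]], spec) == bits_to_int(crcs[1:spec$width]),
      crc_bits(message[h[[2]]], spec) ==
        bits_to_int(crcs[(spec$width + 1L):(2L * spec$width)]))
  }
}

# Strip the CRC field, returning the protected message bits.
crc_strip <- function(framed, spec = crc_spec()) {
  framed <- check_bits(framed)
  framed[seq_len(length(framed) - spec$segments * spec$width)]
}
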