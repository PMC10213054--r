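#' Map bits to DNA bases and back
#'
#' The codebook is the standard 2-bits-per-base mapping 00:A, 01:C, 10:G,
#' 11:T. `bits_to_bases()` requires an even bit count; `bases_to_bits()`
#' inverts it exactly.
#'
#' @param bits 0/1 integer vector of even length.
#' @param bases a character scalar over A/C/G/T.
#' @return `bits_to_bases()` returns a character scalar of length
#'   `length(bits) / 2`; `bases_to_bits()` returns the bit vector.
#' @examples
#' bits_to_bases(c(0, 0, 0, 1, 1, 0, 1, 1)) # "ACGT"
#' @export
bits_to_bases <- function(bits) {
  bits <- check_bits(bits)
  if (length(bits) %% 2 != 0)
    stop("bit length must be even to map 2 bits per base", call. = FALSE)
  if (!length(bits)) return("")
  idx <- 2L * bits[c(TRUE, FALSE)] + bits[c(FALSE, TRUE)] + 1L
  paste(c("A", "C", "G", "T")[idx], collapse = "")
}

#' @rdname bits_to_bases
#' @export
bases_to_bits <- function(bases) {
  if (!nzchar(bases)) return(integer(0))
  ch <- strsplit(bases, "")[[1]]
  idx <- match(ch, c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("bases must be over A/C/G/T", call. = FALSE)
  as.integer(rbind((idx - 1L) %/% 2L, (idx - 1L) %% 2L))
}
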