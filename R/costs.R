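#' Writing and reading cost
#'
#' Writing cost is bases synthesized per information bit; reading cost is
#' bases sequenced per information bit; coverage is their ratio. Primer
#' bases are excluded from the oligo length by convention. Coding density
#' (bits per base) is the reciprocal of the writing cost.
#'
#' @param file_bits information content of the file in bits.
#' @param n_oligos number of distinct oligos synthesized.
#' @param n_reads_used number of reads consumed for decoding.
#' @param payload_len_bases payload bases per oligo (primers excluded).
#' @return Cost in bases per bit.
#' @examples
#' writing_cost(1000, 10, 100) # 1 base/bit
#' @export
writing_cost <- function(file_bits, n_oligos, payload_len_bases) {
  stopifnot(file_bits > 0, n_oligos > 0, payload_len_bases > 0)
  n_oligos * payload_len_bases / file_bits
}

#' @rdname writing_cost
#' @export
reading_cost <- function(file_bits, n_reads_used, payload_len_bases) {
  stopifnot(file_bits > 0, n_reads_used > 0, payload_len_bases > 0)
  n_reads_used * payload_len_bases / file_bits
}

#' @rdname writing_cost
#' @export
coding_density <- function(file_bits, n_oligos, payload_len_bases) {
  1 / writing_cost(file_bits, n_oligos, payload_len_bases)
}

# Assemble a cost report; coverage = reading / writing by construction.
cost_report <- function(file_bits, n_oligos, payload_len_bases,
                        n_reads_used, decoded_fraction = NA_real_,
                        min_reads = NA_integer_) {
  wc <- writing_cost(file_bits, n_oligos, payload_len_bases)
  rc <- reading_cost(file_bits, n_reads_used, payload_len_bases)
  structure(list(writing_cost = wc, reading_cost = rc, coverage = rc / wc,
                 decoded_fraction = decoded_fraction, min_reads = min_reads,
                 file_bits = file_bits, n_oligos = n_oligos,
                 payload_len_bases = payload_len_bases,
                 n_reads_used = n_reads_used),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf(paste0("cost report: writing %.3f bases/bit, reading %.3f ",
                     "bases/bit, coverage %.2fx\n"),
              x$writing_cost, x$reading_cost, x$coverage))
  if (!is.na(x$decoded_fraction))
    cat(sprintf("  decoded fraction: %.3f\n", x$decoded_fraction))
  if (!is.na(x$min_reads))
    cat(sprintf("  minimum reads for full recovery: %d\n", x$min_reads))
  invisible(x)
}
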