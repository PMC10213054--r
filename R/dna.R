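#' Assemble oligos from inner-code codewords
#'
#' An oligo is `fwd_primer + payload + rev_primer`, with the payload the
#' 2-bits-per-base image of the (punctured, padded) codeword. Primers are
#' 25 nt by convention; oligos at or above 200 nt total trigger a warning
#' (or an error with `hard_fail = TRUE`) to mirror synthesis length
#' limits.
#'
#' @param codeword 0/1 integer vector (padded to even length by the
#'   caller).
#' @param fwd,rev primer sequences.
#' @param file_id,index used for the FASTA record name `fileID_index`.
#' @param hard_fail error instead of warn on length violation.
#' @return A one-row data.frame (an oligo record) with columns `name`,
#'   `file_id`, `index`, `fwd`, `payload`, `rev`, `sequence`.
#' @export
assemble_oligo <- function(codeword, fwd, rev, file_id = "f0", index = 0L,
                           hard_fail = FALSE) {
  payload <- bits_to_bases(codeword)
  seq <- paste0(fwd, payload, rev)
  if (nchar(seq) >= 200L) {
    msg <- sprintf("oligo %s_%d is %d nt (>= 200 nt synthesis limit)",
                   file_id, index, nchar(seq))
    if (hard_fail) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  data.frame(name = paste0(file_id, "_", index), file_id = file_id,
             index = as.integer(index), fwd = fwd, payload = payload,
             rev = rev, sequence = seq, stringsAsFactors = FALSE)
}

#' Write and read oligo pools as FASTA
#'
#' Records are named `fileID_index`. `read_pool()` reconstructs the
#' primer/payload split by the known primer length.
#'
#' @param pool data.frame of oligo records ([assemble_oligo()] rows).
#' @param path FASTA file path.
#' @param primer_len primer length used when splitting on read-back.
#' @return `read_pool()` returns the pool data.frame.
#' @export
write_pool <- function(pool, path) {
  x <- Biostrings::DNAStringSet(pool$sequence)
  names(x) <- pool$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path, primer_len = 25L) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  nm <- names(x)
  us <- regexpr("_[^_]*$", nm)
  file_id <- substr(nm, 1L, us - 1L)
  index <- as.integer(substring(nm, us + 1L))
  n <- nchar(seqs)
  data.frame(name = nm, file_id = file_id, index = index,
             fwd = substr(seqs, 1L, primer_len),
             payload = substr(seqs, primer_len + 1L, n - primer_len),
             rev = substr(seqs, n - primer_len + 1L, n),
             sequence = seqs, stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate random primer pairs
#'
#' Random A/C/G/T primers for subpool targeting; each subpool ("file")
#' gets a distinct forward/reverse pair.
#'
#' @param n number of pairs.
#' @param length primer length (25 nt by default).
#' @param seed RNG seed.
#' @return data.frame with columns `file_id`, `fwd`, `rev`.
#' @export
make_primers <- function(n, length = 25L, seed = 1L) {
  with_seed(seed, {
    draw <- function() paste(sample(c("A", "C", "G", "T"), length,
                                    replace = TRUE), collapse = "")
    data.frame(file_id = paste0("f", seq_len(n) - 1L),
               fwd = vapply(seq_len(n), function(i) draw(), character(1)),
               rev = vapply(seq_len(n), function(i) draw(), character(1)),
               stringsAsFactors = FALSE)
  })
}

#' @rdname make_primers
#' @param primers primer data.frame.
#' @param path tab-separated file with columns `file_id`, `fwd`, `rev`.
#' @export
write_primer_table <- function(primers, path) {
  utils::write.table(primers, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname make_primers
#' @export
read_primer_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# local-alignment scoring used for primer location
trim_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

#' Locate and trim primer flanks on reads
#'
#' Finds the best local alignment of the forward primer near the read
#' start and the reverse primer near the read end (affine gaps: match +1,
#' mismatch -1, gap open -2, extend -1). Primer bases missing from the
#' alignment are penalized at `penalty` per base — except bases that fall
#' off the read boundary (the signature of a clipped primer on a
#' truncated read), which instead shrink the attainable score that the
#' acceptance threshold is measured against. Complete primers are thus
#' preferred, clipped ones are kept, and spurious short matches in the
#' read interior are rejected. If the best forward hit starts beyond
#' `chimera_offset` the read is flagged as a chimera suspect and trimmed
#' at that hit. Coordinates are 0-based, half-open.
#'
#' @param reads character vector of basecalled reads.
#' @param fwd,rev primer pair.
#' @param penalty score penalty per missing terminal primer base.
#' @param threshold_frac acceptance threshold as a fraction of the
#'   maximum score (primer length).
#' @param chimera_offset forward-hit start beyond which the read is
#'   flagged `start_late_chimera_suspect`.
#' @return data.frame with one row per read: `start`, `end` (payload
#'   window, 0-based half-open), `fwd_score`, `rev_score`, `status`.
#' @export
trim_reads <- function(reads, fwd, rev, penalty = 0.5, threshold_frac = 0.6,
                       chimera_offset = 30L) {
  n <- length(reads)
  out <- data.frame(start = rep(NA_integer_, n), end = NA_integer_,
                    fwd_score = NA_real_, rev_score = NA_real_,
                    status = rep("not_found", n), stringsAsFactors = FALSE)
  ok <- nchar(reads) >= 1L
  if (!any(ok)) return(out)
  subj <- Biostrings::DNAStringSet(reads[ok])
  mat <- trim_submat()
  align1 <- function(primer) {
    Biostrings::pairwiseAlignment(subj, primer, type = "local",
                                  substitutionMatrix = mat,
                                  gapOpening = 2, gapExtension = 1)
  }
  af <- align1(fwd)
  ar <- align1(rev)
  fr <- Biostrings::pattern(af)   # ranges on the read
  rr <- Biostrings::pattern(ar)
  f_sub0 <- Biostrings::subject(af)
  r_sub0 <- Biostrings::subject(ar)
  rlen <- nchar(reads[ok])
  # fwd primer: bases before the alignment may hang off the read start
  f_before <- Biostrings::start(f_sub0) - 1L
  f_boundary <- pmax(0L, f_before - (Biostrings::start(fr) - 1L))
  f_missing <- (f_before - f_boundary) +
    (nchar(fwd) - Biostrings::end(f_sub0))
  f_attain <- pmax(nchar(fwd) - f_boundary, nchar(fwd) / 2)
  f_ok <- Biostrings::score(af) - penalty * f_missing >=
    threshold_frac * f_attain
  # rev primer: bases after the alignment may hang off the read end
  r_after <- nchar(rev) - Biostrings::end(r_sub0)
  r_boundary <- pmax(0L, r_after - (rlen - Biostrings::end(rr)))
  r_missing <- (r_after - r_boundary) + (Biostrings::start(r_sub0) - 1L)
  r_attain <- pmax(nchar(rev) - r_boundary, nchar(rev) / 2)
  r_ok <- Biostrings::score(ar) - penalty * r_missing >=
    threshold_frac * r_attain
  # account for primer bases clipped outside the local alignment: the
  # payload starts right after where the full fwd primer would end
  start0 <- Biostrings::end(fr) + (nchar(fwd) - Biostrings::end(f_sub0))
  end0 <- Biostrings::start(rr) - 1L - (Biostrings::start(r_sub0) - 1L)
  hit <- f_ok & r_ok & start0 < end0
  idx <- which(ok)
  out$fwd_score[idx] <- Biostrings::score(af)
  out$rev_score[idx] <- Biostrings::score(ar)
  out$start[idx[hit]] <- as.integer(start0[hit])
  out$end[idx[hit]] <- as.integer(end0[hit])
  st <- ifelse(Biostrings::start(fr) - 1L - (Biostrings::start(f_sub0) - 1L) >
                 chimera_offset,
               "start_late_chimera_suspect", "ok")
  out$status[idx[hit]] <- st[hit]
  out
}

#' @rdname trim_reads
#' @param read a single read.
#' @export
trim_read <- function(read, fwd, rev, penalty = 0.5, threshold_frac = 0.6,
                      chimera_offset = 30L) {
  trim_reads(read, fwd, rev, penalty, threshold_frac, chimera_offset)[1, ]
}
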