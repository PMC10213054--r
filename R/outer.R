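#' Whitening of file payloads
#'
#' XOR with a seeded pseudorandom keystream so the encoder input looks
#' random and the mapped bases avoid long homopolymers. The transform is
#' its own inverse under the same seed. This stands in for the compression
#' and encryption a real archive would apply before encoding; it adds no
#' secrecy and no compression.
#'
#' @param data raw vector.
#' @param seed integer keystream seed.
#' @return Raw vector of the same length.
#' @examples
#' x <- charToRaw("hello")
#' identical(dewhiten(whiten(x, 7), 7), x)
#' @export
whiten <- function(data, seed) {
  if (!is.raw(data)) stop("data must be a raw vector", call. = FALSE)
  if (!length(data)) return(data)
  xor(data, as.raw(keystream(length(data), seed)))
}

#' @rdname whiten
#' @export
dewhiten <- function(data, seed) whiten(data, seed)

# 32-bit LCG keystream (Numerical Recipes constants), high byte emitted.
# Exact in doubles: a * 2^32 + c < 2^53.
keystream <- function(n, seed) {
  state <- as.numeric(seed) %% 4294967296
  out <- integer(n)
  for (i in seq_len(n)) {
    state <- (1664525 * state + 1013904223) %% 4294967296
    out[i] <- as.integer(state %/% 16777216)
  }
  out
}

#' Reed-Solomon outer-code parameters
#'
#' The outer code treats each byte position across the `k` data segments
#' of a block as a Reed-Solomon codeword over GF(256), extended by `p`
#' parity bytes. Any `k` of the `k + p` segments of a block recover the
#' block; whole-oligo dropout is an erasure. Blocks are interleaved
#' round-robin over segment indices so that a run of adjacent dropouts
#' spreads across blocks.
#'
#' @param k data segments per block.
#' @param p parity segments per block.
#' @return An object of class `"rs_params"`.
#' @export
rs_params <- function(k = 16L, p = 4L) {
  k <- as.integer(k); p <- as.integer(p)
  if (k < 1L || p < 0L) stop("need k >= 1, p >= 0", call. = FALSE)
  if (k + p > 255L)
    stop("k + p must be at most 255 for 8-bit RS symbols", call. = FALSE)
  structure(list(k = k, p = p), class = "rs_params")
}

# Fixed-point solve of the index width: widening the index shrinks the
# per-segment data field, which can add segments, which can widen the index.
segment_geometry <- function(file_bits, message_bits_per_oligo, rs, crc) {
  crc_bits <- crc$segments * crc$width
  w <- 1L
  repeat {
    avail <- message_bits_per_oligo - w - crc_bits
    data_bits <- 8L * (avail %/% 8L)
    if (data_bits < 8L)
      stop("message_bits_per_oligo too small for index + CRC + one byte",
           call. = FALSE)
    n_data <- max(1L, as.integer(ceiling(file_bits / data_bits)))
    n_blocks <- as.integer(ceiling(n_data / rs$k))
    total <- n_data + n_blocks * rs$p
    w2 <- max(1L, as.integer(ceiling(log2(total + 1L))))
    if (w2 == w) {
      return(list(index_width = w, data_bits = data_bits,
                  filler_bits = avail - data_bits, n_data = n_data,
                  n_blocks = n_blocks, n_parity = n_blocks * rs$p,
                  total_segments = total))
    }
    w <- w2
  }
}

#' Split a whitened payload into indexed segments
#'
#' Divides the file bits into fixed-size per-oligo data fields. The index
#' width is the smallest that can address all data plus parity segments
#' (it scales logarithmically with file size); the data field is the
#' largest byte-aligned size that fits after index and CRC, with any
#' leftover bits per oligo recorded as filler. The last segment is
#' zero-padded and the pad length recorded in the manifest.
#'
#' @param data raw vector (already whitened by the caller or via
#'   `whitening_seed`).
#' @param message_bits_per_oligo framed message bits per oligo (index +
#'   data + filler + CRC), i.e. the inner-code input size.
#' @param rs an [rs_params()].
#' @param crc a [crc_spec()].
#' @param whitening_seed if non-`NULL`, whiten `data` first.
#' @return An object of class `"segment_set"`: list with `index` (0-based
#'   integer vector), `payload` (segments x data_bits 0/1 matrix),
#'   `is_parity` (logical), and `manifest` (decoding metadata).
#' @export
segment_file <- function(data, message_bits_per_oligo, rs = rs_params(),
                         crc = crc_spec(), whitening_seed = NULL) {
  if (!is.raw(data)) stop("data must be a raw vector", call. = FALSE)
  if (!length(data)) stop("cannot encode an empty file", call. = FALSE)
  if (!is.null(whitening_seed)) data <- whiten(data, whitening_seed)
  file_bits <- 8L * length(data)
  geo <- segment_geometry(file_bits, message_bits_per_oligo, rs, crc)
  bits <- bytes_to_bits(data)
  pad_bits <- geo$n_data * geo$data_bits - file_bits
  bits <- c(bits, integer(pad_bits))
  payload <- matrix(bits, nrow = geo$n_data, ncol = geo$data_bits,
                    byrow = TRUE)
  manifest <- list(file_len_bytes = length(data), pad_bits = pad_bits,
                   index_width = geo$index_width, data_bits = geo$data_bits,
                   filler_bits = geo$filler_bits,
                   message_bits = message_bits_per_oligo,
                   n_data = geo$n_data, n_blocks = geo$n_blocks,
                   rs_k = rs$k, rs_p = rs$p,
                   total_segments = geo$total_segments,
                   whitening_seed = whitening_seed,
                   crc = unclass(crc))
  structure(list(index = seq_len(geo$n_data) - 1L, payload = payload,
                 is_parity = rep(FALSE, geo$n_data), manifest = manifest),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment set: %d data + %d parity segments, %d data bits each\n",
              sum(!x$is_parity), sum(x$is_parity), ncol(x$payload)))
  invisible(x)
}

# Block membership of a data segment index (round-robin interleave).
block_of <- function(index, n_blocks) index %% n_blocks

# Index assigned to parity j (0-based) of block b.
parity_index <- function(b, j, n_data, n_blocks) n_data + j * n_blocks + b

#' Extend a segment set with Reed-Solomon parity segments
#'
#' For every block, each byte position across the block's `k` data
#' segments is interpolated as a polynomial of degree `< k` over GF(256)
#' and evaluated at `p` further points to give the parity segments. Parity
#' segments receive fresh indices after the data segments.
#'
#' @param segs a [segment_file()] result.
#' @param rs an [rs_params()]; defaults to the geometry in the manifest.
#' @return The extended `segment_set`.
#' @export
rs_extend <- function(segs, rs = NULL) {
  man <- segs$manifest
  if (is.null(rs)) rs <- rs_params(man$rs_k, man$rs_p)
  if (rs$p == 0L) return(segs)
  if (ncol(segs$payload) %% 8L != 0L)
    stop("segment payloads must be byte-aligned for RS", call. = FALSE)
  n_data <- man$n_data
  B <- man$n_blocks
  nbytes <- ncol(segs$payload) %/% 8L
  # bytes: n_data x nbytes
  byte_mat <- t(apply(segs$payload, 1L, function(r)
    as.integer(bits_to_bytes(r))))
  dim(byte_mat) <- c(n_data, nbytes)
  par_index <- integer(0)
  par_rows <- list()
  for (b in seq_len(B) - 1L) {
    members <- which(block_of(segs$index, B) == b & !segs$is_parity)
    kb <- length(members)  # last block may be short; still degree < k
    vals <- t(byte_mat[members, , drop = FALSE])     # nbytes x kb
    pts <- (seq_len(kb) - 1L)
    xs <- man$rs_k + (seq_len(rs$p) - 1L)
    par <- gf_lagrange_eval(pts, vals, xs)           # nbytes x p
    for (j in seq_len(rs$p) - 1L) {
      par_index <- c(par_index, parity_index(b, j, n_data, B))
      par_rows[[length(par_rows) + 1L]] <- bytes_to_bits(as.raw(par[, j + 1L]))
    }
  }
  segs$index <- c(segs$index, par_index)
  segs$payload <- rbind(segs$payload, do.call(rbind, par_rows))
  segs$is_parity <- c(segs$is_parity, rep(TRUE, length(par_index)))
  segs
}

#' Recover the file bytes from received segments
#'
#' Received segments are assumed CRC-clean (the inner code discards
#' failures upstream), so missing indices are erasures. Duplicate copies
#' of an index are resolved by per-byte majority vote with ties going to
#' the first received copy. Any block with more than `p` erasures makes
#' recovery fail with an error that lists the unrecoverable blocks.
#'
#' @param index integer vector of received segment indices (0-based,
#'   duplicates allowed).
#' @param payload 0/1 matrix, one row per received segment.
#' @param manifest the manifest from [segment_file()].
#' @return The original raw vector (de-padded, de-whitened).
#' @export
rs_recover <- function(index, payload, manifest) {
  man <- manifest
  if (length(index) != nrow(payload))
    stop("index/payload size mismatch", call. = FALSE)
  keep <- index < man$total_segments & index >= 0
  index <- index[keep]
  payload <- payload[keep, , drop = FALSE]
  # collapse duplicates: per-byte majority, ties to first received
  uidx <- unique(index)
  nbytes <- ncol(payload) %/% 8L
  seg_bytes <- matrix(0L, nrow = length(uidx), ncol = nbytes)
  for (i in seq_along(uidx)) {
    rows <- which(index == uidx[i])
    mats <- vapply(rows, function(r)
      as.integer(bits_to_bytes(payload[r, ])), integer(nbytes))
    mats <- matrix(mats, nrow = nbytes)
    if (length(rows) == 1L) {
      seg_bytes[i, ] <- mats[, 1L]
    } else {
      seg_bytes[i, ] <- vapply(seq_len(nbytes), function(bpos) {
        tab <- table(mats[bpos, ])
        winners <- names(tab)[tab == max(tab)]
        if (length(winners) > 1L) {
          # tie: first received copy whose byte is among the winners
          first <- mats[bpos, ][match(TRUE, mats[bpos, ] %in%
                                        as.integer(winners))]
          as.integer(first)
        } else as.integer(winners)
      }, integer(1))
    }
  }
  B <- man$n_blocks
  n_data <- man$n_data
  k <- man$rs_k
  p <- man$rs_p
  data_bytes <- matrix(NA_integer_, nrow = n_data, ncol = nbytes)
  bad_blocks <- integer(0)
  for (b in seq_len(B) - 1L) {
    dmembers <- which(block_of(0:(n_data - 1L), B) == b) - 1L  # data indices
    kb <- length(dmembers)
    pidx <- parity_index(b, seq_len(p) - 1L, n_data, B)
    have_d <- dmembers[dmembers %in% uidx]
    have_p <- pidx[pidx %in% uidx]
    n_miss <- kb - length(have_d)
    if (n_miss == 0L) {
      data_bytes[dmembers + 1L, ] <- seg_bytes[match(dmembers, uidx), ]
      next
    }
    if (length(have_d) + length(have_p) < kb) {
      bad_blocks <- c(bad_blocks, b)
      next
    }
    # erasure decode: interpolate from any kb known points
    pts_d <- match(have_d, dmembers) - 1L
    pts_p <- k + (match(have_p, pidx) - 1L)
    pts <- c(pts_d, pts_p)[seq_len(kb)]
    rows <- match(c(have_d, have_p)[seq_len(kb)], uidx)
    vals <- t(seg_bytes[rows, , drop = FALSE])       # nbytes x kb
    miss <- dmembers[!dmembers %in% uidx]
    xs <- match(miss, dmembers) - 1L
    rec <- gf_lagrange_eval(pts, vals, xs)           # nbytes x n_miss
    data_bytes[dmembers + 1L, ] <- 0L
    data_bytes[have_d + 1L, ] <- seg_bytes[match(have_d, uidx), ]
    data_bytes[miss + 1L, ] <- t(rec)
  }
  if (length(bad_blocks)) {
    stop(structure(class = c("oligostore_partial_decode", "error", "condition"),
                   list(message = paste0("unrecoverable erasures in block(s) ",
                                         paste(bad_blocks, collapse = ", ")),
                        call = sys.call(-1), bad_blocks = bad_blocks)))
  }
  # apply() stacks one segment per column; column-major read restores order
  bits <- as.integer(apply(data_bytes, 1L, function(r)
    bytes_to_bits(as.raw(r))))
  bits <- bits[seq_len(8L * man$file_len_bytes)]
  out <- bits_to_bytes(bits)
  if (!is.null(man$whitening_seed)) out <- dewhiten(out, man$whitening_seed)
  out
}
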