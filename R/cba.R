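#' Design a k-mer-disjoint barcode set
#'
#' Rejection sampling of random 20-mers: a proposal is accepted only if
#' none of its k-mers collides with any k-mer already in the accepted set
#' (and its own k-mers are distinct), so every pair of accepted sequences
#' shares no k-mer and every accepted `length`-mer contributes exactly
#' `length - k + 1` distinct k-mers. The first `subunits x states`
#' accepted sequences become barcodes (assigned 8 per subunit in order);
#' the next `subunits + 1` become the flanking scaffolds.
#'
#' @param n_sequences sequences to generate (55 = 48 barcodes + 7
#'   scaffolds).
#' @param length sequence length (20).
#' @param k k-mer size for the disjointness constraint (9).
#' @param seed RNG seed (design is deterministic given the seed).
#' @param subunits,states_per_subunit address geometry (6 x 8).
#' @param max_reject abort after this many consecutive rejections.
#' @return An object of class `"cba_design"`: `barcodes` (character),
#'   `scaffolds` (character), `subunits`, `states`, `k`, `length`, and
#'   `slot` (data.frame mapping each barcode to subunit and state).
#' @export
design_barcode_set <- function(n_sequences = 55L, length = 20L, k = 9L,
                               seed = 1L, subunits = 6L,
                               states_per_subunit = 8L,
                               max_reject = 1e6) {
  stopifnot(n_sequences >= 1L, length >= k)
  seqs <- character(0)
  pool <- character(0)  # accepted k-mers
  with_seed(seed, {
    rejects <- 0
    while (base::length(seqs) < n_sequences) {
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      km <- seq_kmers(cand, k)
      if (anyDuplicated(km) || any(km %in% pool)) {
        rejects <- rejects + 1
        if (rejects > max_reject)
          stop("barcode design infeasible: ", max_reject,
               " consecutive rejections", call. = FALSE)
        next
      }
      rejects <- 0
      seqs <- c(seqs, cand)
      pool <- c(pool, km)
    }
  })
  nb <- min(subunits * states_per_subunit, n_sequences)
  barcodes <- seqs[seq_len(nb)]
  scaffolds <- if (n_sequences > nb) seqs[(nb + 1L):n_sequences] else character(0)
  slot <- data.frame(barcode = barcodes,
                     subunit = (seq_len(nb) - 1L) %/% states_per_subunit + 1L,
                     state = (seq_len(nb) - 1L) %% states_per_subunit,
                     stringsAsFactors = FALSE)
  structure(list(barcodes = barcodes, scaffolds = scaffolds,
                 subunits = as.integer(subunits),
                 states = as.integer(states_per_subunit),
                 k = as.integer(k), length = as.integer(length), slot = slot),
            class = "cba_design")
}

#' @export
print.cba_design <- function(x, ...) {
  cat(sprintf("CBA design: %d barcodes + %d scaffolds (%d-mers), %d subunits x %d states, k = %d\n",
              length(x$barcodes), length(x$scaffolds), x$length, x$subunits,
              x$states, x$k))
  invisible(x)
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Size of the combinatorial address space
#'
#' `states ^ subunits` addresses reachable with only `subunits x states`
#' distinct barcode oligos.
#'
#' @param subunits number of barcode positions.
#' @param states states per position.
#' @return List with `addresses` and `oligos_needed`.
#' @examples
#' address_space(6, 8) # 262144 addresses from 48 oligos
#' @export
address_space <- function(subunits, states) {
  list(addresses = states^subunits, oligos_needed = subunits * states)
}

design_barcode <- function(design, subunit, state) {
  design$barcodes[(subunit - 1L) * design$states + state + 1L]
}

#' Assemble a CBA construct
#'
#' Layout: `scaffold1 barcode(1, d1) scaffold2 barcode(2, d2) ...
#' scaffold7 [linker] [payload]` — each address digit selects one of the
#' subunit's barcodes, flanked by the constant scaffolds used for
#' assembly and as decoding anchors.
#'
#' @param address integer vector of `subunits` digits in `0:(states-1)`.
#' @param design a [design_barcode_set()] result.
#' @param payload optional payload sequence appended after the linker.
#' @param linker constant joining sequence between CBA and payload.
#' @return The construct as a character scalar.
#' @export
assemble_cba <- function(address, design, payload = "", linker = "") {
  stopifnot(length(address) == design$subunits,
            all(address >= 0L & address < design$states),
            length(design$scaffolds) >= design$subunits + 1L)
  parts <- character(0)
  for (i in seq_len(design$subunits)) {
    parts <- c(parts, design$scaffolds[i], design_barcode(design, i, address[i]))
  }
  parts <- c(parts, design$scaffolds[design$subunits + 1L], linker, payload)
  paste(parts, collapse = "")
}

#' Decode one subunit window by k-mer matching
#'
#' Counts, for each of the subunit's candidate barcodes, how many of its
#' k-mers occur in the window. The best-scoring candidate is called;
#' a tie (including all-zero) yields no call.
#'
#' @param window DNA window believed to contain the subunit's barcode.
#' @param design a [design_barcode_set()] result.
#' @param subunit subunit position (1-based).
#' @return List with `best_state` (0-based, or `NA`), `counts` (per
#'   candidate state), `runner_up` (best count among other candidates).
#' @export
kmer_decode_subunit <- function(window, design, subunit) {
  stopifnot(nzchar(window))
  wk <- unique(seq_kmers(window, design$k))
  counts <- vapply(seq_len(design$states) - 1L, function(st) {
    sum(seq_kmers(design_barcode(design, subunit, st), design$k) %in% wk)
  }, integer(1))
  best <- which(counts == max(counts))
  if (max(counts) == 0L || length(best) > 1L) {
    list(best_state = NA_integer_, counts = counts,
         runner_up = max(counts))
  } else {
    list(best_state = best - 1L, counts = counts,
         runner_up = max(counts[-best]))
  }
}

# Estimate scaffold anchor start positions (0-based) in a read via shared
# k-mers; missing anchors are interpolated from the designed layout.
locate_scaffolds <- function(read, design) {
  k <- design$k
  rk <- seq_kmers(read, k)
  n_sc <- design$subunits + 1L
  unit <- design$length * 2L  # scaffold + barcode spacing in the layout
  pos <- rep(NA_real_, n_sc)
  hits <- integer(n_sc)
  for (s in seq_len(n_sc)) {
    sk <- seq_kmers(design$scaffolds[s], k)
    m <- match(rk, sk)
    found <- which(!is.na(m))
    if (length(found)) {
      pos[s] <- median(found - 1L - (m[found] - 1L))
      hits[s] <- length(found)
    }
  }
  if (sum(!is.na(pos)) >= 1L) {
    anchor <- which(!is.na(pos))
    for (s in which(is.na(pos))) {
      ref <- anchor[which.min(abs(anchor - s))]
      pos[s] <- pos[ref] + (s - ref) * unit
    }
  }
  list(pos = pos, hits = hits)
}

#' Decode a full combinatorial barcode address
#'
#' Locates the scaffold anchors by shared k-mers, cuts subunit windows
#' between consecutive anchor midpoints (with slack), and decodes each
#' window with [kmer_decode_subunit()]. The full address succeeds only if
#' all subunits call; in `strict` mode additionally every subunit's
#' runner-up count must be zero — the inclusion criterion used to build
#' ground-truth lookup tables.
#'
#' @param read the read sequence (forward orientation, pre-trimmed).
#' @param design a [design_barcode_set()] result.
#' @param mode `"strict"` or `"best_match"`.
#' @param slack extra bases on both sides of each subunit window.
#' @return List with `per_subunit` (data.frame), `address` (integer
#'   vector or `NULL`), `success`, `strict_pass`, `status` (`"ok"` or
#'   `"no_cba_tag"`).
#' @export
decode_cba <- function(read, design, mode = c("strict", "best_match"),
                       slack = 5L) {
  mode <- match.arg(mode)
  loc <- locate_scaffolds(read, design)
  if (sum(loc$hits > 0L) < 2L) {
    return(list(per_subunit = NULL, address = NULL, success = FALSE,
                strict_pass = FALSE, status = "no_cba_tag"))
  }
  n <- nchar(read)
  half <- design$length %/% 2L
  per <- data.frame(subunit = seq_len(design$subunits),
                    best_state = NA_integer_, best_count = NA_integer_,
                    runner_up_count = NA_integer_)
  for (i in seq_len(design$subunits)) {
    a <- max(0, floor(loc$pos[i] + half) - slack)
    b <- min(n, ceiling(loc$pos[i + 1L] + half) + slack)
    if (b - a < design$k) next
    res <- kmer_decode_subunit(substr(read, a + 1L, b), design, i)
    per$best_state[i] <- res$best_state
    per$best_count[i] <- max(res$counts)
    per$runner_up_count[i] <- res$runner_up
  }
  called <- !is.na(per$best_state)
  strict_pass <- all(called) && all(per$runner_up_count == 0L)
  success <- all(called) && (mode == "best_match" || strict_pass)
  list(per_subunit = per,
       address = if (all(called)) per$best_state else NULL,
       success = success, strict_pass = strict_pass, status = "ok")
}

#' Per-subunit failure rate under independence
#'
#' Inverts the independence model: if a fraction `overall_success` of
#' reads decodes at all `subunits` positions and subunit errors are
#' independent, each subunit fails at rate
#' `1 - overall_success^(1/subunits)`.
#'
#' @param overall_success fraction in (0, 1].
#' @param subunits number of independent subunits.
#' @return The per-subunit failure fraction.
#' @examples
#' per_subunit_failure(0.70, 6) # ~0.058
#' @export
per_subunit_failure <- function(overall_success, subunits) {
  stopifnot(overall_success > 0, overall_success <= 1)
  1 - overall_success^(1 / subunits)
}

#' Simulate hierarchical address traversal
#'
#' Deterministic gain/leak model of the six sequential amplification
#' rounds that walk the address tree: round `i` multiplies the abundance
#' of constructs whose digit `i` matches the target by `gain`, all others
#' by `gain * leak`, then renormalizes (the dilution between rounds).
#'
#' @param addresses integer matrix (constructs x subunits) of digits.
#' @param abundance initial abundance per construct.
#' @param target target address (integer vector).
#' @param gain per-round amplification of matching constructs.
#' @param leak fraction of the gain leaking to non-matching constructs.
#' @return List with `abundance` (final, normalized), `fold_vs_median`
#'   (target total vs median non-target construct), `by_round` (matrix of
#'   abundances after each round).
#' @export
traverse_address <- function(addresses, abundance, target, gain = 500,
                             leak = 0.05) {
  stopifnot(ncol(addresses) == length(target), nrow(addresses) ==
              length(abundance))
  a <- abundance / sum(abundance)
  rounds <- matrix(NA_real_, nrow = nrow(addresses), ncol = length(target))
  for (i in seq_along(target)) {
    match_i <- addresses[, i] == target[i]
    if (!any(match_i))
      warning("no construct matches target digit ", i,
              "; enrichment is empty", call. = FALSE)
    a <- a * ifelse(match_i, gain, gain * leak)
    a <- a / sum(a)
    rounds[, i] <- a
  }
  is_target <- rowSums(addresses == matrix(target, nrow(addresses),
                                           length(target), byrow = TRUE)) ==
    length(target)
  med <- median(a[!is_target])
  fold <- if (any(is_target) && med > 0) sum(a[is_target]) / med else Inf
  list(abundance = a, fold_vs_median = fold, by_round = rounds)
}

#' Export a CBA design as FASTA
#'
#' Barcodes named `su<i>_state<j>`, scaffolds `scaffold<i>`.
#'
#' @param design a [design_barcode_set()] result.
#' @param path output path.
#' @export
write_cba_design <- function(design, path) {
  seqs <- c(design$barcodes, design$scaffolds)
  names(seqs) <- c(sprintf("su%d_state%d", design$slot$subunit,
                           design$slot$state),
                   sprintf("scaffold%d", seq_along(design$scaffolds)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
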