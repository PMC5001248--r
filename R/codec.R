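# Reference-based codec.  Z = reference . target; the LPF/POS arrays
# over Z are scanned left to right across the target region: factors of
# length >= k become 12-byte (pT, pZ, l) triples, anything shorter is a
# literal byte.  Because lpf[i+1] >= lpf[i] - 1, skipping a short
# factor costs one literal while guaranteeing most of its length is
# still available one step later.

.case_upper <- function(b) b >= as.raw(65) & b <= as.raw(90)
.case_lower <- function(b) b >= as.raw(97) & b <= as.raw(122)

.fold_upper <- function(b) {
  lo <- .case_lower(b)
  b[lo] <- as.raw(as.integer(b[lo]) - 32L)
  b
}

.apply_case <- function(b, bits) {
  up <- .case_upper(b)
  lo <- .case_lower(b)
  raise <- lo & bits
  lower <- up & !bits
  b[raise] <- as.raw(as.integer(b[raise]) - 32L)
  b[lower] <- as.raw(as.integer(b[lower]) + 32L)
  b
}

.pack_bits <- function(bits) {
  pad <- (-length(bits)) %% 8L
  packBits(c(bits, rep(FALSE, pad)), type = "raw")
}

.unpack_bits <- function(bytes, n) {
  as.logical(rawToBits(bytes))[seq_len(n)]
}

.new_archive <- function(k, post, ref_len, target_len, triples = NULL,
                         symbols = NULL, payload = NULL, mask = NULL,
                         decompose = FALSE) {
  structure(list(version = 1L, k = as.integer(k), decompose = decompose,
                 post = post, ref_len = as.numeric(ref_len),
                 target_len = as.numeric(target_len), triples = triples,
                 symbols = symbols, payload = payload, mask = mask),
            class = "lcpf_archive")
}

#' Compress a target sequence against a reference
#'
#' Builds the LPF/POS arrays over `Z = reference . target` and scans
#' the target region left to right.  At position `i` of `Z` (starting
#' at `|R| + 1`): if `lpf[i] < k` the target symbol is appended to the
#' literal `symbols` stream and the scan advances by one; otherwise the
#' triple `(pT, pZ, l) = (i - |R|, pos[i], lpf[i])` is appended to the
#' `triples` stream and the scan jumps past the factor.  Factors may
#' point anywhere earlier in `Z`, so both reference copies and
#' self-referential target copies are exploited.
#'
#' @param reference,target Character scalars or raw vectors; both
#'   non-empty.  The combined length must stay below 2^32 so positions
#'   fit the fixed 4-byte container words.
#' @param k Factor-length threshold (default 31): the shortest factor
#'   worth spending a 12-byte triple on.
#' @param post Post-compression applied to both streams at
#'   serialization time: `"none"` or `"builtin"` (a general-purpose
#'   dictionary compressor; see [post_compress()]).
#' @return An object of class `lcpf_archive`.
#' @examples
#' a <- lpf_compress("ACGTACGT", "ACGTTTAC", k = 2)
#' a$triples
#' @export
lpf_compress <- function(reference, target, k = 31L, post = c("none", "builtin")) {
  post <- match.arg(post)
  rb <- .as_raw(reference)
  tb <- .as_raw(target)
  if (length(rb) == 0L) stop("reference is empty", call. = FALSE)
  if (length(tb) == 0L) stop("target is empty: nothing to compress", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (length(rb) + length(tb) >= 2^32) {
    stop("reference plus target exceeds 32-bit positions", call. = FALSE)
  }
  la <- cpp_lpf_pos(as.integer(c(rb, tb)))
  f <- cpp_factorize(la$lpf, la$pos, length(rb), as.integer(k))
  triples <- f$triples
  colnames(triples) <- c("pT", "pZ", "l")
  symbols <- tb[f$literals]
  if (sum(triples[, "l"]) + length(symbols) != length(tb)) {
    stop("internal error: factors and literals do not tile the target")
  }
  .new_archive(k, post, length(rb), length(tb),
               triples = triples, symbols = symbols)
}

#' Decompress an archive against its reference
#'
#' Left-to-right reconstruction: literal positions (those not covered
#' by any triple) are filled from the `symbols` stream first, then
#' triples are replayed in increasing `pT` order, copying from the
#' reference when the source index is `<= |R|` and from the
#' already-reconstructed target otherwise.  Self-overlapping factors
#' resolve byte by byte.  Malformed input (overlapping or out-of-range
#' factors, stream length mismatches) raises a corrupt-archive error.
#'
#' @param archive An `lcpf_archive`.
#' @param reference The same reference used at encode time.
#' @param as Return type: `"character"` (default) or `"raw"`.
#' @return The reconstructed target.
#' @export
lpf_decompress <- function(archive, reference, as = c("character", "raw")) {
  as <- match.arg(as)
  rb <- .as_raw(reference)
  if (length(rb) != archive$ref_len) {
    stop("reference length does not match the archive", call. = FALSE)
  }
  if (isTRUE(archive$decompose)) {
    pay <- lpf_decompress(archive$payload, .fold_upper(rb), as = "raw")
    maskb <- lpf_decompress(archive$mask, .pack_bits(.case_upper(rb)), as = "raw")
    bits <- .unpack_bits(maskb, archive$target_len)
    out <- .apply_case(pay, bits)
    return(if (as == "raw") out else rawToChar(out))
  }
  tl <- archive$target_len
  tr <- archive$triples
  rl <- archive$ref_len
  covered <- logical(tl)
  if (nrow(tr)) {
    if (is.unsorted(tr[, "pT"], strictly = TRUE)) {
      stop("corrupt archive: triples out of order", call. = FALSE)
    }
    for (t in seq_len(nrow(tr))) {
      pT <- tr[t, "pT"]; l <- tr[t, "l"]
      if (pT < 1 || l < 1 || pT + l - 1 > tl) {
        stop("corrupt archive: factor outside the target", call. = FALSE)
      }
      idx <- pT:(pT + l - 1)
      if (any(covered[idx])) {
        stop("corrupt archive: overlapping factors", call. = FALSE)
      }
      covered[idx] <- TRUE
    }
  }
  lit <- which(!covered)
  if (length(lit) != length(archive$symbols)) {
    stop("corrupt archive: symbol stream length mismatch", call. = FALSE)
  }
  out <- raw(tl)
  out[lit] <- archive$symbols
  for (t in seq_len(nrow(tr))) {
    pT <- tr[t, "pT"]; pZ <- tr[t, "pZ"]; l <- tr[t, "l"]
    if (pZ < 1 || pZ >= rl + pT) {
      stop("corrupt archive: factor source out of range", call. = FALSE)
    }
    last <- pZ + l - 1
    if (last <= rl) {
      out[pT:(pT + l - 1)] <- rb[pZ:last]
    } else if (last < rl + pT) {
      src <- pZ:last
      inref <- src <= rl
      vals <- raw(l)
      vals[inref] <- rb[src[inref]]
      vals[!inref] <- out[src[!inref] - rl]
      out[pT:(pT + l - 1)] <- vals
    } else {
      # factor overlaps its own output: strict left-to-right copy
      for (q in 0:(l - 1)) {
        j <- pZ + q
        out[pT + q] <- if (j <= rl) rb[j] else out[j - rl]
      }
    }
  }
  if (as == "raw") out else rawToChar(out)
}

#' Split a sequence into a one-case payload and a case bitstring
#'
#' The payload is the input mapped to upper case; the mask records one
#' bit per position, 1 exactly where the original held an upper-case
#' ASCII letter.  Caseless symbols (digits, `-`, ...) keep bit 0 and
#' pass through [recompose_case()] unchanged.
#'
#' @param raw_target A character scalar or raw vector.
#' @return A list with `payload` (same type as the input) and `mask`
#'   (a `case_mask`: logical `bits` plus `length`).
#' @examples
#' decompose_case("AcGt")$mask$bits  # TRUE FALSE TRUE FALSE
#' @export
decompose_case <- function(raw_target) {
  b <- .as_raw(raw_target)
  bits <- .case_upper(b)
  payload <- .fold_upper(b)
  list(
    payload = if (is.raw(raw_target)) payload else rawToChar(payload),
    mask = structure(list(bits = bits, length = length(b)), class = "case_mask")
  )
}

#' Reapply a case bitstring to a one-case payload
#'
#' Exact inverse of [decompose_case()]: letters take upper case where
#' the bit is 1 and lower case where it is 0; caseless symbols are
#' untouched by either bit.
#'
#' @param payload A character scalar or raw vector.
#' @param mask A `case_mask` or a logical vector, one bit per position.
#' @return The recased sequence, same type as `payload`.
#' @export
recompose_case <- function(payload, mask) {
  b <- .as_raw(payload)
  bits <- if (inherits(mask, "case_mask")) mask$bits else as.logical(mask)
  if (length(b) != length(bits)) {
    stop("payload and mask lengths differ", call. = FALSE)
  }
  out <- .apply_case(b, bits)
  if (is.raw(payload)) out else rawToChar(out)
}

#' Compress via payload/case-bitstring decomposition
#'
#' Folds both sequences to upper case, compresses the folded target
#' against the folded reference (the payload sub-archive), and
#' compresses the target's packed case bitstring against the
#' reference's packed case bitstring (the mask sub-archive), each with
#' the ordinary triples/symbols codec.  Shrinking the alphabet this way
#' exposes redundancy that mixed-case text hides; the price is a second
#' stream of one bit per position, which itself compresses well
#' whenever case structure is shared with the reference.
#'
#' @inheritParams lpf_compress
#' @return An `lcpf_archive` with `decompose = TRUE` and two nested
#'   sub-archives.
#' @export
lpf_compress_decomposed <- function(reference, target, k = 31L,
                                    post = c("none", "builtin")) {
  post <- match.arg(post)
  rb <- .as_raw(reference)
  tb <- .as_raw(target)
  if (length(rb) == 0L) stop("reference is empty", call. = FALSE)
  if (length(tb) == 0L) stop("target is empty: nothing to compress", call. = FALSE)
  payload <- lpf_compress(.fold_upper(rb), .fold_upper(tb), k = k, post = post)
  mask <- lpf_compress(.pack_bits(.case_upper(rb)), .pack_bits(.case_upper(tb)),
                       k = k, post = post)
  .new_archive(k, post, length(rb), length(tb),
               payload = payload, mask = mask, decompose = TRUE)
}

#' Post-compress or restore a byte stream
#'
#' `"none"` is the identity; `"builtin"` runs the stream through a
#' general-purpose dictionary compressor (DEFLATE via
#' [memCompress()]).  The codec never depends on which method ran: the
#' choice is recorded in the archive header flags and reversed on
#' read.
#'
#' @param stream A raw vector.
#' @param method `"none"` or `"builtin"`.
#' @return A raw vector.
#' @export
post_compress <- function(stream, method = c("none", "builtin")) {
  method <- match.arg(method)
  if (method == "none") return(stream)
  memCompress(stream, type = "gzip")
}

#' @rdname post_compress
#' @export
post_decompress <- function(stream, method = c("none", "builtin")) {
  method <- match.arg(method)
  if (method == "none") return(stream)
  memDecompress(stream, type = "gzip")
}

#' Byte accounting for an archive's streams
#'
#' Sizes before any post-compression: the triples stream costs 12
#' bytes per triple, the symbols stream one byte per literal.  For a
#' decomposed archive the payload and mask sub-archives are summed.
#'
#' @param archive An `lcpf_archive`.
#' @return A named numeric vector with `triples_bytes`,
#'   `symbols_bytes`, `total_bytes`.
#' @export
stream_sizes <- function(archive) {
  if (isTRUE(archive$decompose)) {
    p <- stream_sizes(archive$payload)
    m <- stream_sizes(archive$mask)
    return(p + m)
  }
  tb <- 12 * nrow(archive$triples)
  sb <- length(archive$symbols)
  c(triples_bytes = tb, symbols_bytes = sb, total_bytes = tb + sb)
}

#' @export
print.lcpf_archive <- function(x, ...) {
  sz <- stream_sizes(x)
  cat("lcpf archive: k =", x$k,
      if (x$decompose) "(decomposed)" else "",
      "| target", x$target_len, "bytes ->",
      sz[["total_bytes"]], "stream bytes",
      if (x$post != "none") paste0("(post: ", x$post, ")") else "", "\n")
  invisible(x)
}

#' Total stream bytes across a k sweep
#'
#' Computes the LPF/POS arrays once and re-scans the factorization for
#' each threshold, reporting the byte cost of both streams.  Small `k`
#' spends 12-byte triples on short factors; very large `k` gives up on
#' real factors and pays one literal byte per position, so the total
#' is minimized in an interior band.
#'
#' @param reference,target Character scalars or raw vectors.
#' @param ks Integer vector of thresholds to evaluate; defaults to
#'   `kmin:kmax`.
#' @param kmin,kmax Range used when `ks` is not given.
#' @return A data frame with columns `k`, `triples_bytes`,
#'   `symbols_bytes`, `total_bytes`.
#' @export
sweep_k <- function(reference, target, ks = NULL, kmin = 1L, kmax = 100L) {
  if (is.null(ks)) ks <- seq.int(kmin, kmax)
  rb <- .as_raw(reference)
  tb <- .as_raw(target)
  if (length(rb) == 0L || length(tb) == 0L) {
    stop("reference and target must be non-empty", call. = FALSE)
  }
  la <- cpp_lpf_pos(as.integer(c(rb, tb)))
  rows <- lapply(as.integer(ks), function(k) {
    f <- cpp_factorize(la$lpf, la$pos, length(rb), k)
    data.frame(k = k,
               triples_bytes = 12 * nrow(f$triples),
               symbols_bytes = length(f$literals))
  })
  out <- do.call(rbind, rows)
  out$total_bytes <- out$triples_bytes + out$symbols_bytes
  out
}
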