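#' Suffix array of a byte sequence
#'
#' Returns the permutation of `1..n` that sorts all suffixes of `text`
#' in strictly ascending lexicographic order.  Symbols are compared as
#' bytes, so the ordering over DNA letters is plain ASCII order.
#'
#' @param text A character scalar or raw vector; must be non-empty.
#' @return An integer vector: `out[r]` is the 1-based start position of
#'   the rank-`r` suffix.
#' @examples
#' build_suffix_array("banana")  # 6 4 2 1 5 3
#' @export
build_suffix_array <- function(text) {
  b <- .as_raw(text)
  if (length(b) == 0L) stop("text must be non-empty", call. = FALSE)
  cpp_suffix_array(as.integer(b))
}

.new_lpf_arrays <- function(text, lpf, pos) {
  structure(list(text = text, lpf = as.integer(lpf), pos = as.integer(pos)),
            class = "lpf_arrays")
}

#' Longest-previous-factor (LPF) and occurrence (POS) arrays
#'
#' For every position `i` of `text`, `lpf[i]` is the maximal length
#' `l` such that the substring starting at `i` also starts at some
#' earlier position `h < i`; `pos[i]` is the leftmost such `h`
#' (`pos[i] = 0` exactly when `lpf[i] = 0`).  Self-overlapping factors
#' (`h + l - 1 >= i`) are permitted, as in LZ factorization, so a run
#' `aaaa` yields `lpf = 0 3 2 1`.  The guaranteed slack property
#' `lpf[i+1] >= lpf[i] - 1` is what lets the codec skip a factor by a
#' single literal without losing much factor length downstream.
#'
#' Built from the suffix array and LCP array: nearest-neighbour lookups
#' in rank order over a shrinking linked list give the factor length,
#' and a range-minimum over the suffix array inside the widened
#' lcp-interval recovers the leftmost occurrence.
#'
#' @param text A character scalar or raw vector; must be non-empty.
#' @return An object of class `lpf_arrays`: a list with elements
#'   `text`, `lpf`, `pos`.
#' @seealso [lpf_bruteforce()] for the quadratic reference
#'   implementation used as a test oracle.
#' @examples
#' build_lpf_pos("abab")  # lpf 0 0 2 1, pos 0 0 1 2
#' @export
build_lpf_pos <- function(text) {
  b <- .as_raw(text)
  if (length(b) == 0L) stop("text must be non-empty", call. = FALSE)
  r <- cpp_lpf_pos(as.integer(b))
  .new_lpf_arrays(text, r$lpf, r$pos)
}

#' Quadratic brute-force LPF/POS oracle
#'
#' Same contract as [build_lpf_pos()], computed by directly comparing
#' every pair of start positions `(h, i)` with `h < i`, one diagonal
#' offset at a time.  Independent of the suffix-array path and intended
#' for testing at modest lengths (a few thousand symbols).
#'
#' @inheritParams build_lpf_pos
#' @return An `lpf_arrays` object.
#' @export
lpf_bruteforce <- function(text) {
  b <- as.integer(.as_raw(text))
  n <- length(b)
  if (n == 0L) stop("text must be non-empty", call. = FALSE)
  lpf <- integer(n)
  pos <- integer(n)
  if (n > 1L) {
    # offset d = i - h, largest first so the leftmost h wins ties
    for (d in (n - 1L):1L) {
      L <- n - d
      hs <- seq_len(L)
      is <- hs + d
      eq <- b[hs] == b[is]
      nf <- ifelse(eq, L + 1L, hs)          # next mismatch at or after h
      nf <- rev(cummin(rev(nf)))
      len <- nf - hs                         # match length between h and h+d
      upd <- len > lpf[is]
      lpf[is[upd]] <- len[upd]
      pos[is[upd]] <- hs[upd]
    }
  }
  .new_lpf_arrays(text, lpf, pos)
}

#' @export
print.lpf_arrays <- function(x, ...) {
  cat("LPF/POS arrays over", length(x$lpf), "symbols;",
      sum(x$lpf == 0L), "fresh positions\n")
  invisible(x)
}
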