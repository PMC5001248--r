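# Shared byte-level helpers.  Sequences move through the package as
# character scalars at the surface and raw vectors internally, so that
# arbitrary byte streams (e.g. packed case bitstrings) can ride through
# the same codec as DNA text.

.as_raw <- function(x) {
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L && !is.na(x)) return(charToRaw(x))
  stop("expected a single character string or a raw vector", call. = FALSE)
}

# Fixed-width little-endian unsigned integers.  Values are carried in
# doubles; widths up to 8 stay exact because every quantity written is
# below 2^53 (positions are capped at 2^32 - 1 upstream).
int_to_le <- function(x, width) {
  x <- as.numeric(x)
  out <- raw(width * length(x))
  if (length(x) == 0L) return(out)
  for (s in seq_len(width) - 1L) {
    out[(seq_along(x) - 1L) * width + s + 1L] <- as.raw((x %/% 256^s) %% 256)
  }
  out
}

le_to_int <- function(bytes, width) {
  if (length(bytes) == 0L) return(numeric(0))
  m <- matrix(as.integer(bytes), nrow = width)
  as.numeric(colSums(m * 256^(seq_len(width) - 1L)))
}

# Sequential reader over a raw buffer with truncation checks.
.reader <- function(buf) {
  pos <- 1L
  take <- function(n) {
    n <- as.integer(n)
    if (n == 0L) return(raw(0))
    if (pos + n - 1L > length(buf)) {
      stop("corrupt archive: truncated stream", call. = FALSE)
    }
    out <- buf[pos:(pos + n - 1L)]
    pos <<- pos + n
    out
  }
  list(
    take = take,
    uint = function(width) le_to_int(take(width), width),
    remaining = function() length(buf) - pos + 1L
  )
}
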