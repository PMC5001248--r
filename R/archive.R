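# Container format (all integers little-endian, positions 1-based):
#
#   magic "LCPF" | version (1 byte) | flags (1 byte)
#   k (4 bytes) | ref_len (8 bytes) | target_len (8 bytes)
#
# flags: bit 0 = decomposition mode, bit 1 = triples stream
# post-compressed, bit 2 = symbols stream post-compressed, bit 3 =
# multi-record FASTA container (see compress_fasta).
#
# Plain body: triple count (8 bytes); the triples stream (3 x 4-byte
# words per triple); symbols byte length (8 bytes); the symbols bytes.
# When a stream is post-compressed its stored byte length (8 bytes)
# precedes the stored bytes, since 12 * count no longer applies.
# Decomposition mode nests the payload and mask blocks, each in this
# same format, directly after the header.

.MAGIC <- "LCPF"

.serialize_archive <- function(a) {
  flags <- 0L
  if (isTRUE(a$decompose)) flags <- flags + 1L
  if (a$post != "none") flags <- flags + 2L + 4L
  header <- c(charToRaw(.MAGIC), as.raw(a$version), as.raw(flags),
              int_to_le(a$k, 4L), int_to_le(a$ref_len, 8L),
              int_to_le(a$target_len, 8L))
  if (isTRUE(a$decompose)) {
    return(c(header, .serialize_archive(a$payload), .serialize_archive(a$mask)))
  }
  tr_bytes <- int_to_le(as.vector(t(a$triples)), 4L)
  body <- int_to_le(nrow(a$triples), 8L)
  if (a$post != "none") {
    ct <- post_compress(tr_bytes, "builtin")
    cs <- post_compress(a$symbols, "builtin")
    body <- c(body, int_to_le(length(ct), 8L), ct,
              int_to_le(length(cs), 8L), cs)
  } else {
    body <- c(body, tr_bytes,
              int_to_le(length(a$symbols), 8L), a$symbols)
  }
  c(header, body)
}

.deserialize_archive <- function(rdr) {
  magic <- rawToChar(rdr$take(4L))
  if (magic != .MAGIC) stop("corrupt archive: bad magic", call. = FALSE)
  version <- as.integer(rdr$take(1L))
  if (version != 1L) stop("unsupported archive version ", version, call. = FALSE)
  flags <- as.integer(rdr$take(1L))
  k <- rdr$uint(4L)
  ref_len <- rdr$uint(8L)
  target_len <- rdr$uint(8L)
  decompose <- bitwAnd(flags, 1L) > 0L
  post_t <- bitwAnd(flags, 2L) > 0L
  post_s <- bitwAnd(flags, 4L) > 0L
  post <- if (post_t || post_s) "builtin" else "none"
  if (decompose) {
    payload <- .deserialize_archive(rdr)
    mask <- .deserialize_archive(rdr)
    return(.new_archive(k, post, ref_len, target_len,
                        payload = payload, mask = mask, decompose = TRUE))
  }
  ntrip <- rdr$uint(8L)
  tr_bytes <- if (post_t) {
    post_decompress(rdr$take(rdr$uint(8L)), "builtin")
  } else {
    rdr$take(12 * ntrip)
  }
  if (length(tr_bytes) != 12 * ntrip) {
    stop("corrupt archive: triples stream length mismatch", call. = FALSE)
  }
  vals <- le_to_int(tr_bytes, 4L)
  triples <- matrix(as.integer(vals), ncol = 3L, byrow = TRUE,
                    dimnames = list(NULL, c("pT", "pZ", "l")))
  symbols <- rdr$take(rdr$uint(8L))
  if (post_s) symbols <- post_decompress(symbols, "builtin")
  .new_archive(k, post, ref_len, target_len,
               triples = triples, symbols = symbols)
}

#' Write an archive to a file
#'
#' Serializes bit-exactly into the documented container (little-endian
#' words, 1-based positions, 12 bytes per triple).
#' `read_archive(write_archive(a, f))` restores `a` exactly.
#'
#' @param archive An `lcpf_archive`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_archive <- function(archive, path) {
  if (!inherits(archive, "lcpf_archive")) {
    stop("not an lcpf_archive", call. = FALSE)
  }
  writeBin(.serialize_archive(archive), path)
  invisible(path)
}

#' Read an archive (or multi-record container) from a file
#'
#' @param source A file path or a raw vector.
#' @return An `lcpf_archive`, or an `lcpf_container` when the file was
#'   produced by [compress_fasta()].
#' @export
read_archive <- function(source) {
  buf <- if (is.raw(source)) {
    source
  } else {
    readBin(source, "raw", n = file.size(source))
  }
  rdr <- .reader(buf)
  # peek: container files share magic/version but set flags bit 3
  magic <- rawToChar(rdr$take(4L))
  if (magic != .MAGIC) stop("corrupt archive: bad magic", call. = FALSE)
  version <- as.integer(rdr$take(1L))
  if (version != 1L) stop("unsupported archive version ", version, call. = FALSE)
  flags <- as.integer(rdr$take(1L))
  if (bitwAnd(flags, 8L) > 0L) {
    nrec <- rdr$uint(8L)
    records <- vector("list", nrec)
    for (r in seq_len(nrec)) {
      header <- rawToChar(rdr$take(rdr$uint(8L)))
      records[[r]] <- list(header = header, archive = .deserialize_archive(rdr))
    }
    return(structure(list(records = records), class = "lcpf_container"))
  }
  .deserialize_archive(.reader(buf))
}

#' @export
print.lcpf_container <- function(x, ...) {
  cat("lcpf container:", length(x$records), "record(s)\n")
  for (r in x$records) cat(" ", r$header, "\n")
  invisible(x)
}

#' Compress a FASTA target against a FASTA reference
#'
#' Every target record is compressed independently against the
#' concatenation of all reference records (mirroring per-chromosome
#' compression against a whole-genome reference); headers are stored
#' verbatim and uncompressed in the container.
#'
#' @param ref_path,target_path FASTA files.
#' @param out_path Output container path.
#' @param k Factor-length threshold.
#' @param decompose Use payload/case-bitstring decomposition?
#' @param post `"none"` or `"builtin"` post-compression.
#' @param split Also emit the raw `triples` and `symbols` streams
#'   (concatenated across records, before post-compression) as
#'   `<out_path>.triples` and `<out_path>.symbols`.
#' @param quiet Suppress the per-record log lines?
#' @return Invisibly, the list of per-record archives.
#' @export
compress_fasta <- function(ref_path, target_path, out_path, k = 31L,
                           decompose = FALSE, post = c("none", "builtin"),
                           split = FALSE, quiet = FALSE) {
  post <- match.arg(post)
  ref <- read_fasta(ref_path)
  tgt <- read_fasta(target_path)
  R <- paste(ref$residues, collapse = "")
  archives <- vector("list", nrow(tgt))
  buf <- list(charToRaw(.MAGIC), as.raw(1L), as.raw(8L),
              int_to_le(nrow(tgt), 8L))
  for (r in seq_len(nrow(tgt))) {
    a <- if (decompose) {
      lpf_compress_decomposed(R, tgt$residues[r], k = k, post = post)
    } else {
      lpf_compress(R, tgt$residues[r], k = k, post = post)
    }
    archives[[r]] <- a
    if (!quiet) {
      sz <- stream_sizes(a)
      message(sprintf("record '%s': k=%d triples=%d B symbols=%d B total=%d B",
                      tgt$header[r], as.integer(k), sz[["triples_bytes"]],
                      sz[["symbols_bytes"]], sz[["total_bytes"]]))
    }
    hb <- charToRaw(tgt$header[r])
    buf <- c(buf, list(int_to_le(length(hb), 8L), hb, .serialize_archive(a)))
  }
  writeBin(unlist(buf), out_path)
  if (split) {
    flat <- function(a) {
      if (isTRUE(a$decompose)) {
        p <- flat(a$payload); m <- flat(a$mask)
        list(triples = c(p$triples, m$triples), symbols = c(p$symbols, m$symbols))
      } else {
        list(triples = int_to_le(as.vector(t(a$triples)), 4L), symbols = a$symbols)
      }
    }
    parts <- lapply(archives, flat)
    writeBin(do.call(c, lapply(parts, `[[`, "triples")),
             paste0(out_path, ".triples"))
    writeBin(do.call(c, lapply(parts, `[[`, "symbols")),
             paste0(out_path, ".symbols"))
  }
  invisible(archives)
}

#' Decompress a FASTA container
#'
#' @param archive_path Container written by [compress_fasta()].
#' @param ref_path The reference FASTA used at encode time.
#' @param out_path Restored FASTA path.
#' @return `out_path`, invisibly.
#' @export
decompress_fasta <- function(archive_path, ref_path, out_path) {
  cont <- read_archive(archive_path)
  if (!inherits(cont, "lcpf_container")) {
    stop("not a multi-record container; use lpf_decompress()", call. = FALSE)
  }
  ref <- read_fasta(ref_path)
  R <- paste(ref$residues, collapse = "")
  recs <- data.frame(
    header = vapply(cont$records, `[[`, "", "header"),
    residues = vapply(cont$records, function(r) {
      lpf_decompress(r$archive, R)
    }, "")
  )
  write_fasta(recs, out_path)
  invisible(out_path)
}
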