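# FASTA I/O, delegated to Biostrings behind a small data-frame
# surface.  Residues are treated as raw bytes (case preserved, no
# alphabet validation) so extended IUPAC letters need no special
# handling anywhere downstream.

#' Read a FASTA file
#'
#' Accepts arbitrary line wrapping; header lines are kept verbatim
#' (without the leading `>`), residue bytes including case are
#' preserved, record order is preserved.  An empty file or residue
#' data before the first header is a format error.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `header` and `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("FASTA format error: empty file", call. = FALSE)
  head_lines <- readLines(path, n = 100L, warn = FALSE)
  first <- head_lines[nzchar(trimws(head_lines))][1L]
  if (is.na(first) || !startsWith(first, ">")) {
    stop("FASTA format error: data before first header", call. = FALSE)
  }
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("FASTA format error: no records", call. = FALSE)
  data.frame(header = names(x), residues = as.character(x))
}

#' Write records to a FASTA file
#'
#' Residues are wrapped at 60 columns; `read_fasta(write_fasta(x))`
#' restores headers and residues exactly.
#'
#' @param records A data frame with columns `header` and `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("header", "residues") %in% names(records)))
  x <- Biostrings::BStringSet(records$residues)
  names(x) <- records$header
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}
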