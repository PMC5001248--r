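# Shared fixtures and independent oracles, all built in code.

rand_string <- function(n, alphabet) {
  if (n == 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# alphabets exercised by the randomized suites
lcs_alphabets <- list(letters[1L], letters[1:2], c("A", "C", "G", "T"),
                      letters[1:20])
lpf_alphabets <- list(letters[1L], letters[1:2], c("A", "C", "G", "T"),
                      LETTERS[1:21])

# Brute-force evaluation of the max-table definitions: among real
# matches with ranks <= (i, j), maximize the primary coordinate, break
# ties towards the rightmost secondary one.  Returns a match id, or 0.
brute_tbl_cell <- function(ms, pv, i, j, primary = c("p1", "p2")) {
  primary <- match.arg(primary)
  real <- seq_len(ms$count) + 1L
  ok <- real[pv$r1[real] <= i & pv$r2[real] <= j]
  if (length(ok) == 0L) return(0L)
  a <- if (primary == "p1") ms$p1 else ms$p2
  b <- if (primary == "p1") ms$p2 else ms$p1
  ok <- ok[a[ok] == max(a[ok])]
  ok[which.max(b[ok])]
}

# Kahn's algorithm; returns TRUE iff the graph is acyclic.
kahn_acyclic <- function(dag) {
  N <- dag$n_nodes
  indeg <- tabulate(unlist(dag$gr), nbins = N)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    u <- queue[1L]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (v in dag$gr[[u]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) queue <- c(queue, v)
    }
  }
  seen == N
}

# id -> (p1, p2) pair lookup used when freezing expected parent sets
match_id_at <- function(ms, p1, p2) {
  ids <- seq_len(ms$count) + 1L
  ids[ms$p1[ids] == p1 & ms$p2[ids] == p2]
}

expect_roundtrip <- function(reference, target, k,
                             decompose = FALSE, post = "none") {
  arch <- if (decompose) {
    lpf_compress_decomposed(reference, target, k = k, post = post)
  } else {
    lpf_compress(reference, target, k = k, post = post)
  }
  expect_identical(lpf_decompress(arch, reference), target)
  # and through the serialized container
  f <- withr::local_tempfile()
  write_archive(arch, f)
  back <- read_archive(f)
  expect_identical(lpf_decompress(back, reference), target)
  invisible(arch)
}
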