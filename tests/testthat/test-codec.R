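test_that("compression scan emits the expected triples and literals", {
  a <- lpf_compress("ACGTACGT", "ACGTTTAC", k = 2)
  expect_identical(unname(a$triples),
                   matrix(c(1L, 1L, 4L, 5L, 12L, 2L, 7L, 1L, 2L),
                          ncol = 3L, byrow = TRUE))
  expect_identical(length(a$symbols), 0L)

  a <- lpf_compress("AAAA", "AAAC", k = 31)
  expect_identical(nrow(a$triples), 0L)
  expect_identical(rawToChar(a$symbols), "AAAC")

  # identical target: a single triple covering everything
  r <- strrep("ACGT", 100L)
  a <- lpf_compress(r, r, k = 31)
  expect_identical(unname(a$triples), matrix(c(1L, 1L, 400L), ncol = 3L))
  expect_identical(length(a$symbols), 0L)
  expect_identical(unname(stream_sizes(a)[["total_bytes"]]), 12)
})

test_that("compression rejects degenerate parameters and inputs", {
  expect_error(lpf_compress("ACGT", "ACGT", k = 0), "k must be")
  expect_error(lpf_compress("ACGT", ""), "target is empty")
  expect_error(lpf_compress("", "ACGT"), "reference is empty")
})

test_that("decompression inverts the scan, including self-overlap", {
  a <- lpf_compress("ACGTACGT", "ACGTTTAC", k = 2)
  expect_identical(lpf_decompress(a, "ACGTACGT"), "ACGTTTAC")

  a <- lpf_compress("A", "AAAA", k = 1)
  expect_identical(unname(a$triples), matrix(c(1L, 1L, 4L), ncol = 3L))
  expect_identical(lpf_decompress(a, "A"), "AAAA")
})

test_that("triple extents and literal positions tile the target", {
  set.seed(41)
  for (rep in 1:20) {
    R <- rand_string(sample(50:300, 1L), c("A", "C", "G", "T"))
    TT <- mutate_sequence(R, mutation_profile(sub_rate = 0.05,
                                              ins_rate = 0.02,
                                              del_rate = 0.02))
    k <- sample(c(1L, 4L, 12L, 31L), 1L)
    a <- lpf_compress(R, TT, k = k)
    cover <- integer(nchar(TT))
    for (t in seq_len(nrow(a$triples))) {
      idx <- a$triples[t, "pT"]:(a$triples[t, "pT"] + a$triples[t, "l"] - 1L)
      cover[idx] <- cover[idx] + 1L
    }
    expect_true(all(cover <= 1L))
    expect_identical(sum(cover == 0L), length(a$symbols))
    expect_true(all(a$triples[, "l"] >= k))
    expect_true(all(a$triples[, "pZ"] < nchar(R) + a$triples[, "pT"]))
    sz <- stream_sizes(a)
    expect_equal(unname(sz[["triples_bytes"]]), 12 * nrow(a$triples))
    expect_equal(unname(sz[["symbols_bytes"]]), length(a$symbols))
  }
})

test_that("k = 1 with a covering reference leaves the symbols stream empty", {
  set.seed(43)
  for (rep in 1:5) {
    R <- paste0("ACGT", rand_string(100L, c("A", "C", "G", "T")))
    TT <- rand_string(200L, c("A", "C", "G", "T"))
    a <- lpf_compress(R, TT, k = 1)
    expect_identical(length(a$symbols), 0L)
  }
})

test_that("case decomposition splits and restores byte-for-byte", {
  d <- decompose_case("AcGt")
  expect_identical(d$payload, "ACGT")
  expect_identical(d$mask$bits, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(decompose_case("acgt")$mask$bits, rep(FALSE, 4L))
  expect_identical(decompose_case("ACGT")$mask$bits, rep(TRUE, 4L))

  expect_identical(recompose_case("ACGT", c(TRUE, FALSE, TRUE, FALSE)), "AcGt")
  # caseless symbols ignore the bit entirely; letters follow it
  expect_identical(recompose_case("NNN", c(FALSE, TRUE, FALSE)), "nNn")
  expect_identical(recompose_case("A-1", c(FALSE, TRUE, TRUE)), "a-1")
  expect_error(recompose_case("AC", c(TRUE)), "lengths differ")

  set.seed(47)
  for (rep in 1:10) {
    x <- rand_string(sample(1:80, 1L),
                     c("A", "C", "G", "T", "a", "c", "g", "t", "N", "n", "-"))
    d <- decompose_case(x)
    expect_identical(recompose_case(d$payload, d$mask), x)
  }
})

test_that("decomposed compression folds case into a second codec pass", {
  R <- strrep("acgtACGTggcc", 100L)     # 1200 symbols, mixed case
  # identical target: both sub-archives collapse to single triples
  a <- lpf_compress_decomposed(R, R, k = 31)
  expect_identical(nrow(a$payload$triples), 1L)
  expect_identical(nrow(a$mask$triples), 1L)
  expect_identical(lpf_decompress(a, R), R)

  # case flips only: payload still one triple, mask carries the edits
  b <- charToRaw(R)
  for (start in c(11L, 500L, 900L)) {
    idx <- start:(start + 49L)
    v <- as.integer(b[idx])
    up <- v >= 65L & v <= 90L
    lo <- v >= 97L & v <= 122L
    v[up] <- v[up] + 32L
    v[lo] <- v[lo] - 32L
    b[idx] <- as.raw(v)
  }
  TT <- rawToChar(b)
  a <- lpf_compress_decomposed(R, TT, k = 31)
  expect_identical(nrow(a$payload$triples), 1L)
  expect_gt(stream_sizes(a$mask)[["total_bytes"]], 12)
  expect_identical(lpf_decompress(a, R), TT)
})

test_that("post-compression is reversible and shrinks repetitive streams", {
  expect_identical(post_compress(as.raw(1:10), "none"), as.raw(1:10))
  set.seed(53)
  x <- as.raw(sample(0:255, 4000L, replace = TRUE))
  expect_identical(post_decompress(post_compress(x, "builtin"), "builtin"), x)
  big <- charToRaw(strrep("a", 2^20))
  expect_lt(length(post_compress(big, "builtin")), length(big))
  expect_error(post_compress(raw(1), "lz4"))
})

test_that("archive container serializes bit-exactly", {
  R <- strrep("ACGTAC", 50L)
  TT <- mutate_sequence(R, mutation_profile(sub_rate = 0.05, seed = 9L))
  a <- lpf_compress(R, TT, k = 4)
  bytes <- lcpf:::.serialize_archive(a)
  # header(26) + count(8) + 12 per triple + length(8) + literals
  expect_identical(length(bytes),
                   26L + 8L + 12L * nrow(a$triples) + 8L + length(a$symbols))
  expect_identical(rawToChar(bytes[1:4]), "LCPF")

  f <- withr::local_tempfile()
  write_archive(a, f)
  b <- read_archive(f)
  expect_identical(b[names(b) != "triples"], a[names(a) != "triples"])
  expect_identical(unname(b$triples), unname(a$triples))

  # randomized archives, plain and decomposed, with and without post
  set.seed(59)
  for (rep in 1:10) {
    R <- rand_string(sample(40:200, 1L), c("A", "C", "G", "T", "a", "t"))
    TT <- mutate_sequence(R, mutation_profile(sub_rate = 0.03, ins_rate = 0.01,
                                              del_rate = 0.01))
    k <- sample(c(1L, 8L, 31L), 1L)
    post <- sample(c("none", "builtin"), 1L)
    a <- if (rep %% 2L) {
      lpf_compress(R, TT, k = k, post = post)
    } else {
      lpf_compress_decomposed(R, TT, k = k, post = post)
    }
    write_archive(a, f)
    b <- read_archive(f)
    expect_identical(lpf_decompress(b, R), TT)
    expect_identical(stream_sizes(b), stream_sizes(a))
  }
})

test_that("corrupt containers are rejected with clear errors", {
  a <- lpf_compress("ACGTACGT", "ACGTTTAC", k = 2)
  bytes <- lcpf:::.serialize_archive(a)
  bad <- bytes; bad[1:4] <- charToRaw("NOPE")
  expect_error(read_archive(bad), "bad magic")
  expect_error(read_archive(bytes[1:20]), "truncated")
  bad <- bytes; bad[5] <- as.raw(99)
  expect_error(read_archive(bad), "version")
  # tampered factor source
  b <- a; b$triples[1, "pZ"] <- 2000L
  expect_error(lpf_decompress(b, "ACGTACGT"), "out of range")
  b <- a; b$symbols <- as.raw(1:5)
  expect_error(lpf_decompress(b, "ACGTACGT"), "length mismatch")
  expect_error(lpf_decompress(a, "ACGT"), "reference length")
})

test_that("threshold sweep reuses one LPF pass and reports byte totals", {
  set.seed(61)
  R <- rand_string(3000L, c("A", "C", "G", "T"))
  TT <- mutate_sequence(R, mutation_profile(sub_rate = 0.01))
  df <- sweep_k(R, TT, ks = c(1L, 12L, 31L, 5000L))
  expect_identical(names(df), c("k", "triples_bytes", "symbols_bytes",
                                "total_bytes"))
  expect_equal(df$total_bytes, df$triples_bytes + df$symbols_bytes)
  # k beyond any factor length: pure literal coding, one byte per symbol
  expect_equal(df$total_bytes[df$k == 5000L], nchar(TT))
  # cross-check each row against a direct compression at that k
  for (r in seq_len(nrow(df))) {
    if (df$k[r] > 4000L) next
    sz <- stream_sizes(lpf_compress(R, TT, k = df$k[r]))
    expect_equal(df$total_bytes[r], unname(sz[["total_bytes"]]))
  }
})
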