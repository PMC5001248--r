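# Seeded simulator of resequencing divergence: a random reference and
# a target derived from it by point substitutions, short indels and
# case-toggled blocks, so every engine in the package can be exercised
# without downloading genomes.

#' Generate a random reference sequence
#'
#' Symbols are drawn i.i.d. uniformly from `alphabet`.
#'
#' @param length Sequence length (>= 1).
#' @param alphabet Character vector of single symbols.
#' @param seed Optional integer; the same seed reproduces the same
#'   sequence bit for bit.
#' @return A character scalar.
#' @export
generate_reference <- function(length, alphabet = c("A", "C", "G", "T"),
                               seed = NULL) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  if (base::length(alphabet) == 0L) stop("alphabet is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, length, replace = TRUE), collapse = "")
}

#' Mutation profile for the simulator
#'
#' Per-position probabilities of substitution (to a different symbol),
#' deletion, and post-position insertion, plus a number of random
#' blocks whose letter case is toggled (emulating masking changes
#' between assembly releases).  The defaults emulate a low-divergence
#' resequencing release: 1% substitutions, no indels, no case
#' toggling.
#'
#' @param sub_rate,ins_rate,del_rate Probabilities in `[0, 1]`;
#'   `sub_rate + del_rate` must not exceed 1.
#' @param case_blocks Number of case-toggled blocks.
#' @param case_block_len Mean block length (geometric).
#' @param alphabet Symbols used for substitutions and insertions.
#' @param seed Optional integer seed threading all randomness.
#' @return An object of class `mutation_profile`.
#' @export
mutation_profile <- function(sub_rate = 0.01, ins_rate = 0, del_rate = 0,
                             case_blocks = 0L, case_block_len = 500,
                             alphabet = c("A", "C", "G", "T"), seed = NULL) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (sub_rate + del_rate > 1) {
    stop("sub_rate + del_rate must not exceed 1", call. = FALSE)
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, case_blocks = as.integer(case_blocks),
                 case_block_len = case_block_len, alphabet = alphabet,
                 seed = seed),
            class = "mutation_profile")
}

.toggle_case <- function(b, idx) {
  up <- .case_upper(b[idx])
  lo <- .case_lower(b[idx])
  v <- as.integer(b[idx])
  v[up] <- v[up] + 32L
  v[lo] <- v[lo] - 32L
  b[idx] <- as.raw(v)
  b
}

#' Mutate a reference into a divergent target
#'
#' Applies, per position and in this order: substitution to a
#' different symbol, deletion, then with probability `ins_rate` one
#' random symbol inserted after the position; finally `case_blocks`
#' random blocks of geometric mean length have their letter case
#' toggled.  Deterministic under the profile's seed.
#'
#' @param reference A character scalar.
#' @param profile A [mutation_profile()].
#' @return The mutated target, a character scalar (possibly empty when
#'   `del_rate` is extreme).
#' @export
mutate_sequence <- function(reference, profile) {
  stopifnot(inherits(profile, "mutation_profile"))
  if (!is.null(profile$seed)) set.seed(profile$seed)
  s <- strsplit(reference, "", fixed = TRUE)[[1L]]
  n <- length(s)
  alph <- profile$alphabet
  u <- runif(n)
  is_sub <- u < profile$sub_rate
  is_del <- !is_sub & u < profile$sub_rate + profile$del_rate
  if (any(is_sub) && length(alph) > 1L) {
    idx <- which(is_sub)
    cur <- match(s[idx], alph)
    r <- sample.int(length(alph) - 1L, length(idx), replace = TRUE)
    # shift past the current symbol so the substitution always changes it
    pick <- ifelse(is.na(cur), r, r + (r >= cur))
    s[idx] <- alph[pick]
  }
  ins_after <- runif(n) < profile$ins_rate
  ins_sym <- ifelse(ins_after, sample(alph, n, replace = TRUE), "")
  base <- ifelse(is_del, "", s)
  out <- paste0(paste0(base, ins_sym), collapse = "")
  if (profile$case_blocks > 0L && nchar(out) > 0L) {
    b <- charToRaw(out)
    L <- length(b)
    starts <- sample.int(L, profile$case_blocks, replace = TRUE)
    lens <- 1L + rgeom(profile$case_blocks,
                       prob = 1 / max(profile$case_block_len, 1))
    for (q in seq_len(profile$case_blocks)) {
      idx <- starts[q]:min(L, starts[q] + lens[q] - 1L)
      b <- .toggle_case(b, idx)
    }
    out <- rawToChar(b)
  }
  out
}
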