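# LCS via a DAG over single-symbol match points.
#
# A match point records one position pair (p1, p2) with
# s1[p1] == s2[p2].  Two artificial match points bracket the set: the
# source S at (0, 0) with id 1, and the sink E at (n+1, m+1) with id
# eta+2.  Match ids index straight into the p1/p2 vectors, so the hot
# paths below work on plain integers; the exported accessors dress the
# same ids up as data frames.

#' Enumerate single-symbol match points between two sequences
#'
#' Produces exactly one match point for every pair `(i, j)` with
#' `s1[i] == s2[j]`, which is the depth-1 view of a generalized suffix
#' tree over the two sequences: occurrence lists are bucketed per
#' symbol and crossed.  Matches are ordered by (symbol, p1, p2) and
#' assigned ids `2..eta+1`; the source sentinel S takes id 1 at
#' coordinates (0, 0) and the sink E takes id `eta+2` at
#' `(n+1, m+1)`.
#'
#' @param s1,s2 Character scalars over a shared alphabet.
#' @return An object of class `match_set`: list with per-id coordinate
#'   vectors `p1`, `p2`, the match count `count` (eta), input lengths
#'   `n`, `m`, and the inputs `s1`, `s2`.
#' @examples
#' enumerate_matches("abba", "abab")$count  # 8
#' @export
enumerate_matches <- function(s1, s2) {
  c1 <- strsplit(s1, "", fixed = TRUE)[[1L]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1L]]
  n <- length(c1)
  m <- length(c2)
  syms <- sort(intersect(unique(c1), unique(c2)))
  eta_total <- 0
  occ1 <- lapply(syms, function(s) which(c1 == s))
  occ2 <- lapply(syms, function(s) which(c2 == s))
  eta_total <- sum(vapply(occ1, length, 1L) * vapply(occ2, length, 1L))
  if (eta_total > 5e7) {
    stop("too many match points (", eta_total,
         "); this engine targets desk-scale strings", call. = FALSE)
  }
  p1 <- integer(0)
  p2 <- integer(0)
  for (s in seq_along(syms)) {
    o1 <- occ1[[s]]
    o2 <- occ2[[s]]
    p1 <- c(p1, rep(o1, each = length(o2)))
    p2 <- c(p2, rep(o2, times = length(o1)))
  }
  eta <- length(p1)
  structure(list(
    p1 = c(0L, p1, n + 1L),
    p2 = c(0L, p2, m + 1L),
    count = eta, n = n, m = m, s1 = s1, s2 = s2
  ), class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat("match_set:", x$count, "match points between strings of length",
      x$n, "and", x$m, "\n")
  invisible(x)
}

#' Match points of a match set as a data frame
#'
#' @param ms A `match_set`.
#' @param sentinels Include the S and E sentinels?
#' @return A data frame with columns `id`, `p1`, `p2`.
#' @export
match_table <- function(ms, sentinels = FALSE) {
  ids <- if (sentinels) seq_len(ms$count + 2L) else seq_len(ms$count) + 1L
  data.frame(id = ids, p1 = ms$p1[ids], p2 = ms$p2[ids])
}

#' Build the PREV index (rank maps and max-tables) over a match set
#'
#' Distinct `p1` values (sentinel coordinates included) are renamed to
#' consecutive ranks `1..|p1|`, likewise for `p2`.  Two dense tables
#' are then filled over rank space:
#' `tbl1[i, j]` holds the match with maximal `p1` among all matches
#' whose ranks are `<= (i, j)`, ties broken towards the rightmost `p2`;
#' `tbl2` is the mirror image with `p2` maximised first.  Construction
#' seeds each cell with its own match, propagates down each column,
#' then sweeps each row left to right comparing the primary field.
#'
#' Tables are dense, so the rank-space area `|p1| * |p2|` is capped at
#' 5e7 cells; longer inputs belong to the codec, not this engine.
#'
#' @param ms A `match_set` from [enumerate_matches()].
#' @return An object of class `prev_index` with the rank value vectors
#'   (`p1_vals`, `p2_vals`), per-id ranks (`r1`, `r2`), integer id
#'   matrices `tbl1`, `tbl2` (0 encodes null), and the match set.
#' @export
build_prev <- function(ms) {
  p1_vals <- sort(unique(ms$p1))
  p2_vals <- sort(unique(ms$p2))
  K1 <- length(p1_vals)
  K2 <- length(p2_vals)
  if (as.numeric(K1) * K2 > 5e7) {
    stop("rank tables would need ", K1, " x ", K2,
         " cells; this engine targets desk-scale strings", call. = FALSE)
  }
  r1 <- match(ms$p1, p1_vals)
  r2 <- match(ms$p2, p2_vals)
  tbl1 <- matrix(0L, K1, K2)
  real <- seq_len(ms$count) + 1L
  if (length(real)) tbl1[cbind(r1[real], r2[real])] <- real
  tbl2 <- tbl1

  # propagate seeds down the columns (max rank1 so far per column)
  if (K1 > 1L) {
    for (i in 2:K1) {
      row <- tbl1[i, ]
      hole <- row == 0L
      row[hole] <- tbl1[i - 1L, ][hole]
      tbl1[i, ] <- row
    }
    tbl2 <- tbl1
  }
  # row sweeps: tbl1 keeps max p1 (tie -> rightmost p2, i.e. keep the
  # current column on equality); tbl2 keeps max p2 (tie -> rightmost p1)
  coord_of <- function(ids, coord) {
    v <- rep(-1L, length(ids))
    nz <- ids != 0L
    v[nz] <- coord[ids[nz]]
    v
  }
  p1_of <- function(ids) coord_of(ids, ms$p1)
  p2_of <- function(ids) coord_of(ids, ms$p2)
  if (K2 > 1L) {
    for (j in 2:K2) {
      cur <- tbl1[, j]
      left <- tbl1[, j - 1L]
      take <- p1_of(left) > p1_of(cur)
      cur[take] <- left[take]
      tbl1[, j] <- cur

      cur <- tbl2[, j]
      left <- tbl2[, j - 1L]
      take <- p2_of(left) > p2_of(cur)
      cur[take] <- left[take]
      tbl2[, j] <- cur
    }
  }
  structure(list(p1_vals = p1_vals, p2_vals = p2_vals, r1 = r1, r2 = r2,
                 tbl1 = tbl1, tbl2 = tbl2, ms = ms),
            class = "prev_index")
}

#' @export
print.prev_index <- function(x, ...) {
  cat("prev_index:", nrow(x$tbl1), "x", ncol(x$tbl1), "rank-space tables over",
      x$ms$count, "match points\n")
  invisible(x)
}

# id-level direct parents at rank coordinates (i, j); 0 encodes null
.dprnt <- function(pv, i, j) {
  if (i <= 1L || j <= 1L || i > nrow(pv$tbl1) || j > ncol(pv$tbl1)) {
    return(c(0L, 0L))
  }
  c(pv$tbl1[i - 1L, j - 1L], pv$tbl2[i - 1L, j - 1L])
}

.id_row <- function(ms, id) {
  if (id == 0L) NULL else data.frame(id = id, p1 = ms$p1[id], p2 = ms$p2[id])
}

#' Direct parents at a rank-space cell
#'
#' For a match `c` with ranks `(i, j)`, the direct parent w.r.t. `p1`
#' is `tbl1[i-1, j-1]` and w.r.t. `p2` is `tbl2[i-1, j-1]`; both are
#' null on the boundary (`i <= 1`, `j <= 1`, or ranks out of range).
#'
#' @param pv A `prev_index`.
#' @param i,j Rank coordinates (for a match `c`, the ranks of `c$p1`
#'   and `c$p2`).
#' @return A list with elements `d1`, `d2`, each a one-row data frame
#'   (`id`, `p1`, `p2`) or `NULL`.
#' @export
get_dprnt <- function(pv, i, j) {
  d <- .dprnt(pv, i, j)
  list(d1 = .id_row(pv$ms, d[1L]), d2 = .id_row(pv$ms, d[2L]))
}

# id-level parent set of the match with id cid
.prnts <- function(pv, cid) {
  ms <- pv$ms
  i <- pv$r1[cid]
  j <- pv$r2[cid]
  d <- .dprnt(pv, i, j)
  if (d[1L] == 0L) return(1L)          # nothing precedes: source only
  if (d[1L] == d[2L]) return(d[1L])    # unique nearest parent
  d1 <- d[1L]
  d2 <- d[2L]
  i1 <- ms$p1[d2]; i2 <- ms$p1[d1]
  j1 <- ms$p2[d1]; j2 <- ms$p2[d2]
  P <- c(d1, d2)
  # probe direct parents of theoretical matches across the rank gaps
  ri1 <- match(i1, pv$p1_vals); ri2 <- match(i2, pv$p1_vals)
  rj1 <- match(j1, pv$p2_vals); rj2 <- match(j2, pv$p2_vals)
  # a theoretical match with p1 anywhere in the open gap (i1, i2) sees,
  # as its direct parents, the table entries at the floor rank of its
  # p1 value, i.e. rows ri1 .. ri2-1 (and symmetrically for p2)
  rows <- ri1:(ri2 - 1L)
  cols <- rj1:(rj2 - 1L)
  cand <- c(pv$tbl1[rows, j - 1L], pv$tbl2[rows, j - 1L],
            pv$tbl1[i - 1L, cols], pv$tbl2[i - 1L, cols])
  cand <- unique(cand[cand != 0L])
  if (length(cand)) {
    inside <- ms$p1[cand] > i1 & ms$p1[cand] < i2 &
              ms$p2[cand] > j1 & ms$p2[cand] < j2
    P <- unique(c(P, cand[inside]))
  }
  # prune to an antichain: when two members are in series, the one
  # farther from c is the dominated one -- drop it
  if (length(P) > 1L) {
    dominated <- vapply(P, function(y) {
      any(ms$p1[P] > ms$p1[y] & ms$p2[P] > ms$p2[y])
    }, logical(1L))
    P <- P[!dominated]
  }
  P
}

#' Full parent set of a match
#'
#' Seeds from the two direct parents: with no direct parent the source
#' S is the sole parent; with identical direct parents that match is
#' the sole parent; otherwise both are kept and the open rectangle
#' strictly between their coordinates is probed through further
#' direct-parent lookups, after which any member dominated by another
#' member is pruned.  The result is an antichain: no two returned
#' parents are usable together in one common subsequence, while each
#' strictly precedes `L` in both coordinates.
#'
#' @param pv A `prev_index`.
#' @param L A match id (an integer; real matches are `2..eta+1`, the
#'   sink E is `eta+2`).
#' @return A data frame of parents with columns `id`, `p1`, `p2`.
#' @export
get_prnts <- function(pv, L) {
  L <- as.integer(L)
  ids <- .prnts(pv, L)
  data.frame(id = ids, p1 = pv$ms$p1[ids], p2 = pv$ms$p2[ids])
}

#' Construct the match-point DAG
#'
#' Adds, for every real match and for the sink E, one incoming edge
#' from each of its parents (see [get_prnts()]).  Every edge therefore
#' joins matches that strictly increase in both coordinates, so the
#' graph is acyclic, every node is reachable from S, and maximal chains
#' of matches appear as S-to-E paths.
#'
#' @param ms A `match_set`.
#' @param pv The `prev_index` built on `ms`.
#' @return An object of class `match_dag`: adjacency lists `gr` (child
#'   ids per node id) and out-degrees `sz`.
#' @export
construct_dag <- function(ms, pv) {
  N <- ms$count + 2L
  kids <- vector("list", N)
  for (a in c(seq_len(ms$count) + 1L, N)) {
    for (p in .prnts(pv, a)) {
      kids[[p]] <- c(kids[[p]], a)
    }
  }
  gr <- lapply(kids, function(v) if (is.null(v)) integer(0) else sort(v))
  structure(list(gr = gr, sz = lengths(gr), n_nodes = N),
            class = "match_dag")
}

#' @export
print.match_dag <- function(x, ...) {
  cat("match_dag:", x$n_nodes, "nodes,", sum(x$sz), "edges\n")
  invisible(x)
}

.new_lcs_result <- function(length, pairs, string) {
  structure(list(length = length, pairs = pairs, string = string),
            class = "lcs_result")
}

#' @export
print.lcs_result <- function(x, ...) {
  cat("LCS length", x$length, ":", x$string, "\n")
  invisible(x)
}

#' Longest S-to-E path in the match DAG
#'
#' Relaxes nodes in a topological order (sorting by coordinates, which
#' is valid because every edge strictly increases both), equivalent to
#' the textbook shortest-path-with-weight−1 formulation.  The LCS
#' length is the edge count of the best path minus one; the real
#' matches on the path spell the subsequence.  Among equal-length
#' paths, the first predecessor found in processing order is kept, so
#' the result is deterministic; any optimal path is equally valid.
#'
#' @param dag A `match_dag`.
#' @param ms The `match_set` the DAG was built on.
#' @param s1,s2 The original sequences.
#' @return An `lcs_result`: list with `length`, `pairs` (two-column
#'   matrix of positions, increasing in both), and `string`.
#' @export
longest_path_lcs <- function(dag, ms, s1 = ms$s1, s2 = ms$s2) {
  N <- dag$n_nodes
  ord <- order(ms$p1, ms$p2, seq_len(N))
  dist <- rep(-Inf, N)
  dist[1L] <- 0
  pred <- integer(N)
  for (u in ord) {
    if (!is.finite(dist[u])) next
    for (v in dag$gr[[u]]) {
      if (dist[u] + 1 > dist[v]) {
        dist[v] <- dist[u] + 1
        pred[v] <- u
      }
    }
  }
  path <- N
  while (path[1L] != 1L) path <- c(pred[path[1L]], path)
  real <- path[path != 1L & path != N]
  pairs <- cbind(u = ms$p1[real], v = ms$p2[real])
  chars <- strsplit(s1, "", fixed = TRUE)[[1L]]
  .new_lcs_result(as.integer(dist[N] - 1), pairs,
                  paste(chars[pairs[, "u"]], collapse = ""))
}

#' Longest common subsequence of two strings
#'
#' Full pipeline: match enumeration, PREV max-tables, DAG
#' construction, longest path.  See [lcs_dp()] for the classical
#' dynamic-programming formulation used as the cross-checking oracle.
#'
#' @param s1,s2 Character scalars.
#' @return An `lcs_result`.
#' @examples
#' lcs("abba", "abab")  # length 3; "abb" and "aba" are both optimal
#' @export
lcs <- function(s1, s2) {
  ms <- enumerate_matches(s1, s2)
  pv <- build_prev(ms)
  dag <- construct_dag(ms, pv)
  longest_path_lcs(dag, ms, s1, s2)
}

#' Dynamic-programming LCS oracle
#'
#' The classical quadratic table: cell `(i, j)` is `1 + L(i-1, j-1)`
#' on a symbol match and the row/column maximum otherwise, followed by
#' a traceback.  Independent of the DAG machinery; used to cross-check
#' it.
#'
#' @param s1,s2 Character scalars.
#' @param keep_table Attach the `(n+1) x (m+1)` DP table as attribute
#'   `"table"`?
#' @return An `lcs_result`.
#' @export
lcs_dp <- function(s1, s2, keep_table = FALSE) {
  c1 <- strsplit(s1, "", fixed = TRUE)[[1L]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1L]]
  n <- length(c1)
  m <- length(c2)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1L, j + 1L] <- if (c1[i] == c2[j]) {
        L[i, j] + 1L
      } else {
        max(L[i, j + 1L], L[i + 1L, j])
      }
    }
  }
  # traceback
  i <- n; j <- m
  u <- integer(0); v <- integer(0)
  while (i > 0L && j > 0L) {
    if (c1[i] == c2[j]) {
      u <- c(i, u); v <- c(j, v)
      i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  res <- .new_lcs_result(L[n + 1L, m + 1L], cbind(u = u, v = v),
                         paste(c1[u], collapse = ""))
  if (keep_table) attr(res, "table") <- L
  res
}

#' Is `sub` a subsequence of `s`?
#'
#' Greedy left-to-right containment scan, independent of both LCS
#' engines; the validity check used throughout the tests.
#'
#' @param sub,s Character scalars.
#' @return `TRUE` or `FALSE`.
#' @export
is_common_subsequence <- function(sub, s) {
  a <- strsplit(sub, "", fixed = TRUE)[[1L]]
  if (length(a) == 0L) return(TRUE)
  b <- strsplit(s, "", fixed = TRUE)[[1L]]
  p <- 0L
  for (ch in a) {
    w <- which(b == ch & seq_along(b) > p)
    if (length(w) == 0L) return(FALSE)
    p <- w[1L]
  }
  TRUE
}
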