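# Independent alignment-score oracles.
#
# gap cost model (must mirror the package's contract): a run of k gapped
# positions costs open + (k-1) * extend.
#
# oracle 1: direct-definition DP with explicit gap-length scan (cubic),
# no three-state machinery; handles both modes.
# oracle 2: exhaustive enumeration over all monotone alignment paths
# (free-end global only, tiny sequences), used to validate oracle 1.

gapcost <- function(k, open, extend) ifelse(k <= 0, 0, open + (k - 1) * extend)

oracle_score_cubic <- function(a, b, match = 5, mismatch = -4, open = 12,
                               extend = 3, mode = c("global", "local")) {
  mode <- match.arg(mode)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(-Inf, n + 1, m + 1)
  H[1, 1] <- 0
  # free leading overhang (global) / free restart anywhere (local)
  H[, 1] <- 0; H[1, ] <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    best <- H[i, j] + s
    for (k in seq_len(i)) best <- max(best, H[i - k + 1, j + 1] - gapcost(k, open, extend))
    for (k in seq_len(j)) best <- max(best, H[i + 1, j - k + 1] - gapcost(k, open, extend))
    if (mode == "local") best <- max(best, 0)
    H[i + 1, j + 1] <- best
  }
  if (mode == "local") return(max(0, max(H[-1, -1])))
  max(H[n + 1, ], H[, m + 1]) # free trailing overhang
}

oracle_score_enum <- function(a, b, match = 5, mismatch = -4, open = 12,
                              extend = 3) {
  # exhaustive enumeration, free-end-gaps global; terminal gap runs free
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i == n && j == m) {
      best <<- max(best, score_path(moves))
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(moves, "D"))
    if (i < n) rec(i + 1, j, c(moves, "U"))
    if (j < m) rec(i, j + 1, c(moves, "L"))
  }
  score_path <- function(moves) {
    L <- length(moves)
    # a free terminal overhang is a run of identical gap moves (one
    # sequence's unaligned tail); a mixed staircase is internal gapping
    lead <- 0
    while (lead < L && moves[lead + 1] != "D" &&
           moves[lead + 1] == moves[1]) lead <- lead + 1
    trail <- 0
    while (trail < L - lead && moves[L - trail] != "D" &&
           moves[L - trail] == moves[L]) trail <- trail + 1
    s <- 0; i <- 0; j <- 0; prev <- ""
    for (t in seq_len(L)) {
      mv <- moves[t]
      free <- t <= lead || t > L - trail
      if (mv == "D") {
        i <- i + 1; j <- j + 1
        s <- s + if (A[i] == B[j]) match else mismatch
      } else if (mv == "U") {
        i <- i + 1
        if (!free) s <- s - if (prev == "U") extend else open
      } else {
        j <- j + 1
        if (!free) s <- s - if (prev == "L") extend else open
      }
      prev <- mv
    }
    s
  }
  rec(0, 0, character(0))
  best
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
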