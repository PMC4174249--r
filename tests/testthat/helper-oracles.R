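# Independent brute-force oracles; each deliberately avoids the code path
# it checks.

# all ancestors of a taxid (self included), by naive parent climbing
ancestor_set <- function(tree, taxid) {
  pm <- setNames(tree$nodes$parent_taxid, as.character(tree$nodes$taxid))
  out <- taxid
  cur <- taxid
  repeat {
    p <- unname(pm[as.character(cur)])
    if (p == cur) break
    out <- c(out, p)
    cur <- p
  }
  out
}

node_depth <- function(tree, taxid) length(ancestor_set(tree, taxid))

# LCA by intersecting ancestor sets and taking the deepest member
lca_oracle <- function(tree, taxids) {
  common <- Reduce(intersect, lapply(taxids, ancestor_set, tree = tree))
  depths <- vapply(common, node_depth, 1L, tree = tree)
  common[which.max(depths)]
}

# N50 by exhaustive scan over all candidate lengths
n50_oracle <- function(lengths) {
  cand <- sort(unique(lengths), decreasing = TRUE)
  half <- sum(as.numeric(lengths)) / 2
  for (L in cand) {
    if (sum(as.numeric(lengths[lengths >= L])) >= half) return(L)
  }
  min(lengths)
}

# Exhaustive global-alignment oracle.  Enumerates every global alignment
# as a move string (D diagonal, U gap in b, L gap in a) by backwards
# tabulation, scores each, keeps the optimal ones, and selects the
# alignment a diagonal-then-up-then-left traceback would produce: the
# lexicographically first reversed move string under D < U < L.
align_enumerate <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  n <- length(a)
  m <- length(b)
  cells <- vector("list", (n + 1L) * (m + 1L))
  idx <- function(i, j) i * (m + 1L) + j + 1L
  cells[[idx(n, m)]] <- list(moves = "", score = 0, ident = 0L)
  for (i in n:0) {
    for (j in m:0) {
      if (i == n && j == m) next
      moves <- character(0); score <- numeric(0); ident <- integer(0)
      if (i < n && j < m) {
        nxt <- cells[[idx(i + 1L, j + 1L)]]
        s <- if (a[i + 1L] == b[j + 1L]) match else mismatch
        moves <- c(moves, paste0("D", nxt$moves))
        score <- c(score, nxt$score + s)
        ident <- c(ident, nxt$ident + (a[i + 1L] == b[j + 1L]))
      }
      if (i < n) {
        nxt <- cells[[idx(i + 1L, j)]]
        moves <- c(moves, paste0("U", nxt$moves))
        score <- c(score, nxt$score + gap)
        ident <- c(ident, nxt$ident)
      }
      if (j < m) {
        nxt <- cells[[idx(i, j + 1L)]]
        moves <- c(moves, paste0("L", nxt$moves))
        score <- c(score, nxt$score + gap)
        ident <- c(ident, nxt$ident)
      }
      cells[[idx(i, j)]] <- list(moves = moves, score = score,
                                 ident = ident)
    }
  }
  cells[[idx(0L, 0L)]]
}

pid_oracle <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(seq_a, "")[[1L]]
  b <- strsplit(seq_b, "")[[1L]]
  all_al <- align_enumerate(a, b, match, mismatch, gap)
  best <- max(all_al$score)
  keep <- abs(all_al$score - best) < 1e-9
  moves <- all_al$moves[keep]
  ident <- all_al$ident[keep]
  # traceback runs end-to-start preferring D, U, L: reverse each move
  # string and sort with D < U < L
  key <- chartr("DUL", "123",
                vapply(strsplit(moves, ""), function(x)
                  paste(rev(x), collapse = ""), ""))
  pick <- order(key)[1L]
  list(pid = 100 * ident[pick] / nchar(moves[pick]), score = best)
}
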