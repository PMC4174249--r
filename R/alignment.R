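#' Global percent identity of two sequences
#'
#' Needleman-Wunsch global alignment with linear gap costs, returning
#' 100 x (identical columns) / (alignment columns) of the optimal
#' alignment.  The traceback resolves score ties deterministically:
#' diagonal is preferred over a gap in the second sequence (up), which is
#' preferred over a gap in the first (left).  Defaults (match +1,
#' mismatch -1, gap -2) suit nucleotide comparisons; for proteins, supply
#' a named substitution matrix through `scoring$matrix`.
#'
#' The two inputs must share an alphabet: comparing a nucleotide string
#' against a protein string is an error.
#'
#' @param seq_a,seq_b non-empty residue strings.
#' @param scoring list with `match`, `mismatch`, `gap`, and optionally
#'   `matrix` (square numeric matrix with residue dimnames overriding
#'   match/mismatch).
#' @return Percent identity in [0, 100].  The attribute `alignment` holds
#'   the two gapped strings, `score` the optimal alignment score.
#' @examples
#' global_percent_identity("ACGT", "ACGA")  # 75
#' @export
global_percent_identity <- function(seq_a, seq_b,
                                    scoring = list(match = 1,
                                                   mismatch = -1,
                                                   gap = -2)) {
  a <- toupper(strsplit(seq_a, "", fixed = TRUE)[[1L]])
  b <- toupper(strsplit(seq_b, "", fixed = TRUE)[[1L]])
  if (length(a) == 0L || length(b) == 0L) stop("sequences must be non-empty")
  if (guess_alphabet(a) != guess_alphabet(b)) {
    stop("alphabet mismatch between the two sequences")
  }
  n <- length(a)
  m <- length(b)
  gap <- scoring$gap
  sub <- function(x, y) {
    if (!is.null(scoring$matrix)) return(scoring$matrix[x, y])
    if (x == y) scoring$match else scoring$mismatch
  }
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub(a[i], b[j]),
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback, tie-break: diagonal, then up (gap in b), then left
  i <- n
  j <- m
  ga <- character(0)
  gb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + sub(a[i], b[j])) {
      ga <- c(a[i], ga); gb <- c(b[j], gb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ga <- c(a[i], ga); gb <- c("-", gb); i <- i - 1L
    } else {
      ga <- c("-", ga); gb <- c(b[j], gb); j <- j - 1L
    }
  }
  ident <- sum(ga == gb & ga != "-")
  pid <- 100 * ident / length(ga)
  structure(pid,
            alignment = c(paste(ga, collapse = ""),
                          paste(gb, collapse = "")),
            score = S[n + 1L, m + 1L])
}

guess_alphabet <- function(chars) {
  if (all(chars %in% c("A", "C", "G", "T", "U", "N"))) "nt" else "aa"
}
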