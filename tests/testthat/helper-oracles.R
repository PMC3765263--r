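# Independent oracles used across the suite. These deliberately use
# different algorithms / decompositions than the package implementations.

pair_e <- function(a, b, gc = -3, au = -2, gu = -1) {
  code <- paste0(a, b)
  if (code %in% c("GC", "CG")) return(gc)
  if (code %in% c("AU", "UA")) return(au)
  if (code %in% c("GU", "UG")) return(gu)
  NA_real_
}

# Memoized first-position recursion for the minimum pairing energy of a
# nested structure (the package folds by a last-position C++ DP).
fold_oracle_energy <- function(seq, minloop = 3) {
  s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(s)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < minloop) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1, j)                      # i unpaired
    if (i + minloop + 1 <= j) {
      for (k in (i + minloop + 1):j) {
        e <- pair_e(s[i], s[k])
        if (is.na(e)) next
        inner <- if (k - 1 >= i + 1) rec(i + 1, k - 1) else 0
        rest <- if (k + 1 <= j) rec(k + 1, j) else 0
        best <- min(best, e + inner + rest)
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < 2) return(0)
  rec(1, n)
}

# Pure exhaustive enumeration of every nested structure's total energy
# (no memoization), used to validate the memoized oracle at small n.
fold_enumerate_energy <- function(seq, minloop = 3) {
  s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(s)
  enum_vals <- function(i, j) {
    if (j - i < minloop) return(0)
    vals <- enum_vals(i + 1, j)           # i unpaired, every sub-structure
    if (i + minloop + 1 <= j) {
      for (k in (i + minloop + 1):j) {
        e <- pair_e(s[i], s[k])
        if (is.na(e)) next
        inner <- enum_vals(i + 1, k - 1)
        rest <- if (k + 1 <= j) enum_vals(k + 1, j) else 0
        vals <- c(vals, as.vector(outer(inner + e, rest, "+")))
      }
    }
    vals
  }
  if (n < 2) return(0)
  min(0, min(enum_vals(1, n)))
}

# Naive both-strand substring mapping oracle.
map_oracle <- function(tag, genome_seq) {
  hitsets <- list()
  find_all <- function(pat, subject) {
    out <- integer(0); from <- 1
    repeat {
      p <- regexpr(pat, substr(subject, from, nchar(subject)), fixed = TRUE)
      if (p < 0) break
      out <- c(out, from + p - 1)
      from <- from + p
    }
    out
  }
  plus <- find_all(tag, genome_seq)
  minus <- find_all(reverse_complement(tag), genome_seq)
  dplyr::bind_rows(
    if (length(plus)) tibble::tibble(start = plus - 1L,
                                     end = plus - 1L + nchar(tag),
                                     strand = "+"),
    if (length(minus)) tibble::tibble(start = minus - 1L,
                                      end = minus - 1L + nchar(tag),
                                      strand = "-"))
}

# Brute-force Audic-Claverie two-sided p through the negative-binomial
# identity: given x, Y | x ~ NB(size = x + 1, prob = n1 / (n1 + n2)).
ac_oracle <- function(x, y, n1, n2) {
  p <- n1 / (n1 + n2)
  lower <- stats::pnbinom(y, size = x + 1, prob = p)
  upper <- if (y == 0) 1 else
    stats::pnbinom(y - 1, size = x + 1, prob = p, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# Hypergeometric upper tail by explicit enumeration of candidate draws.
hyper_enum <- function(N, n, M, m) {
  draws <- utils::combn(N, n)
  inside <- seq_len(M)
  overlaps <- apply(draws, 2, function(d) sum(d %in% inside))
  mean(overlaps >= m)
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")
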