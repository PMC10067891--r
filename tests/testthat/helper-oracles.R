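# Independent brute-force oracles used across the suite. These are
# deliberately naive re-implementations (character-level loops), kept
# separate from the package internals they check.

BASES <- c("A", "C", "G", "T")

random_words <- function(k, n) {
  vapply(seq_len(k), function(i) {
    paste(sample(BASES, n, replace = TRUE), collapse = "")
  }, character(1))
}

all_words <- function(n) {
  g <- do.call(expand.grid, rep(list(BASES), n))
  apply(g, 1, paste, collapse = "")
}

bf_hamming <- function(x, y) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  sum(a != b)
}

bf_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

bf_gc <- function(x) sum(strsplit(x, "")[[1]] %in% c("G", "C"))

bf_run_free <- function(x, max_run = 1) {
  r <- rle(strsplit(x, "")[[1]])
  max(r$lengths) <= max_run
}

# triple loop over (i, j, m) with 1-based starts and |i - j| > m
bf_secondary_structure <- function(x, min_stem) {
  n <- nchar(x)
  ch <- strsplit(x, "")[[1]]
  if (n < min_stem) return(FALSE)
  for (m in min_stem:(n - 1)) {
    for (i in 1:(n - m + 1)) {
      for (j in 1:(n - m + 1)) {
        if (abs(i - j) > m) {
          sub_i <- paste(ch[i:(i + m - 1)], collapse = "")
          sub_j <- paste(ch[j:(j + m - 1)], collapse = "")
          if (sub_i == bf_revcomp(sub_j)) return(TRUE)
        }
      }
    }
  }
  FALSE
}

# naive whole-set checker: double loop over every pair, per-word scans
bf_validate <- function(words, cons) {
  ok <- TRUE
  for (w in words) {
    if (cons$use_gc && !(bf_gc(w) %in% cons$gc_tolerance)) ok <- FALSE
    if (cons$use_nl && !bf_run_free(w, cons$max_run)) ok <- FALSE
    if (cons$use_ss && bf_secondary_structure(w, cons$ss_min_stem)) ok <- FALSE
  }
  K <- length(words)
  if (K > 1) {
    for (i in 1:(K - 1)) for (j in (i + 1):K) {
      if (bf_hamming(words[i], words[j]) < cons$d) ok <- FALSE
    }
  }
  if (cons$use_rc) {
    for (i in 1:K) for (j in 1:K) {
      if (i == j && !cons$rc_include_self) next
      if (bf_hamming(words[i], bf_revcomp(words[j])) < cons$d) ok <- FALSE
    }
  }
  ok
}

# naive candidate score: mirrors the definition, written independently
bf_candidate_score <- function(x, accepted, cons) {
  pen <- 0
  if (cons$use_gc) {
    g <- bf_gc(x)
    if (!(g %in% cons$gc_tolerance)) pen <- pen + min(abs(g - cons$gc_tolerance))
  }
  if (cons$use_nl) {
    r <- rle(strsplit(x, "")[[1]])
    pen <- pen + sum(pmax(0, r$lengths - cons$max_run))
  }
  if (cons$use_ss && bf_secondary_structure(x, cons$ss_min_stem)) pen <- pen + 1
  for (w in accepted) {
    pen <- pen + max(0, cons$d - bf_hamming(x, w))
    if (cons$use_rc) pen <- pen + max(0, cons$d - bf_hamming(x, bf_revcomp(w)))
  }
  if (cons$use_rc && cons$rc_include_self) {
    pen <- pen + max(0, cons$d - bf_hamming(x, bf_revcomp(x)))
  }
  pen
}

# exhaustive maximum code size: maximum clique over the compatibility
# graph of all single-word-valid sequences (igraph)
bf_max_code_size <- function(n, d, cons) {
  words <- all_words(n)
  keep <- vapply(words, function(w) {
    (!cons$use_gc || bf_gc(w) %in% cons$gc_tolerance) &&
      (!cons$use_nl || bf_run_free(w, cons$max_run)) &&
      (!cons$use_ss || !bf_secondary_structure(w, cons$ss_min_stem)) &&
      (!cons$use_rc || !cons$rc_include_self ||
         bf_hamming(w, bf_revcomp(w)) >= cons$d)
  }, logical(1))
  words <- words[keep]
  K <- length(words)
  if (K == 0) return(0)
  adj <- matrix(FALSE, K, K)
  for (i in 1:K) for (j in 1:K) {
    if (i < j) {
      ok <- bf_hamming(words[i], words[j]) >= d
      if (ok && cons$use_rc) {
        ok <- bf_hamming(words[i], bf_revcomp(words[j])) >= d &&
          bf_hamming(words[j], bf_revcomp(words[i])) >= d
      }
      adj[i, j] <- adj[j, i] <- ok
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::clique_num(g)
}

# exact rank-sum p by enumeration over all subsets (independent of the
# package's own enumeration: subset indices, not rank multisets)
bf_rank_sum_p <- function(x, y) {
  m <- length(x); N <- m + length(y)
  rk <- rank(c(x, y))
  w <- sum(rk[seq_len(m)])
  sets <- combn(N, m)
  ws <- apply(sets, 2, function(s) sum(rk[s]))
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}
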