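# Sequence primitives and constraint predicates.
#
# Codewords are plain uppercase character strings over {A, C, G, T}.
# Internally most set-level routines work on integer matrices with the
# digit encoding A=0, T=1, C=2, G=3 (the same bijection the storage codec
# uses), one row per word; the string representation is the user-facing
# form and the only one that appears in files.

DNA_BASES <- c("A", "T", "C", "G")

#' Check and canonicalize DNA words
#'
#' Validates that every element of `x` is a non-empty string over the
#' alphabet `A`, `C`, `G`, `T` (lowercase input is accepted and upcased).
#'
#' @param x Character vector of DNA words.
#' @param same_length If `TRUE`, additionally require all words to have a
#'   common length.
#' @return The canonical (uppercase) character vector, invisibly usable.
#' @examples
#' as_dna(c("acgt", "TTAA"))
#' @export
as_dna <- function(x, same_length = FALSE) {
  if (!is.character(x) || length(x) == 0) {
    stop("DNA input must be a non-empty character vector", call. = FALSE)
  }
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x) | nchar(x) == 0
  if (any(bad)) {
    stop("invalid DNA word(s) at position(s): ",
         paste(which(bad), collapse = ", "),
         " (alphabet is A, C, G, T)", call. = FALSE)
  }
  if (same_length && length(unique(nchar(x))) > 1) {
    stop("all words must have equal length", call. = FALSE)
  }
  x
}

# string vector -> integer matrix (one row per word), digits A=0 T=1 C=2 G=3
seq_to_int <- function(x) {
  x <- as_dna(x, same_length = TRUE)
  n <- nchar(x[1])
  m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)), DNA_BASES) - 1L,
              nrow = length(x), ncol = n, byrow = TRUE)
  m
}

# integer matrix -> string vector
int_to_seq <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  apply(m, 1, function(r) paste(DNA_BASES[r + 1L], collapse = ""))
}

# reverse-complement of one integer-coded row: complement swaps A<->T
# (0<->1) and C<->G (2<->3), then reverse
rc_int <- function(r) rev(c(1L, 0L, 3L, 2L)[r + 1L])

#' Reverse, complement, and reverse-complement
#'
#' `dna_reverse()` reverses the symbol order, `dna_complement()` applies the
#' Watson-Crick substitution (A<->T, C<->G) position-wise, and
#' `dna_revcomp()` composes the two. All three are involutions and are
#' vectorized over words.
#'
#' @param x Character vector of DNA words.
#' @return Character vector of transformed words.
#' @examples
#' dna_reverse("TCATGGAA")     # "AAGGTACT"
#' dna_complement("TCATGGAA")  # "AGTACCTT"
#' dna_revcomp("TCATGGAA")     # "TTCCATGA"
#' @export
dna_reverse <- function(x) {
  x <- as_dna(x)
  vapply(strsplit(x, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' @rdname dna_reverse
#' @export
dna_complement <- function(x) {
  chartr("ACGT", "TGCA", as_dna(x))
}

#' @rdname dna_reverse
#' @export
dna_revcomp <- function(x) {
  dna_reverse(dna_complement(x))
}

#' Hamming distance between equal-length words
#'
#' Number of positions at which `x` and `y` differ. Both arguments must be
#' single words of the same length.
#'
#' @param x,y DNA words (length-1 character vectors).
#' @return Non-negative integer count.
#' @examples
#' hamming_dist("CTGTGAC", "ATGTACG")  # 4
#' @export
hamming_dist <- function(x, y) {
  x <- as_dna(x); y <- as_dna(y)
  if (length(x) != 1 || length(y) != 1) {
    stop("hamming_dist() compares two single words", call. = FALSE)
  }
  if (nchar(x) != nchar(y)) {
    stop("length mismatch: ", nchar(x), " vs ", nchar(y), call. = FALSE)
  }
  sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
}

#' GC count of DNA words
#'
#' Number of positions holding `G` or `C`, vectorized over words.
#'
#' @param x Character vector of DNA words.
#' @return Integer vector of counts.
#' @examples
#' gc_count("CTGTGAC")  # 4
#' @export
gc_count <- function(x) {
  x <- as_dna(x)
  nchar(x) - nchar(gsub("[GC]", "", x))
}

#' Constraint-set specification for DNA coding sets
#'
#' Bundles the parameters of a coding set \eqn{C(n, W, d)}: word length
#' `n`, target GC count `W`, minimum pairwise Hamming distance `d`, and
#' flags selecting which constraints are enforced (GC content,
#' no-runlength, reverse-complement distance, secondary-structure screen).
#'
#' By default `W = floor(n/2)`. For even `n` the admissible GC counts are
#' `{W}`; for odd `n` a count of exactly 50% is impossible, so both
#' `floor(n/2)` and `ceiling(n/2)` are admitted unless `gc_tolerance` is
#' given explicitly.
#'
#' @param n Word length (positive integer).
#' @param d Minimum Hamming distance, `1 <= d <= n`.
#' @param W Target GC count; default `floor(n/2)`.
#' @param gc_tolerance Integer vector of admissible GC counts; default
#'   `{W}` for even `n`, `{floor(n/2), ceiling(n/2)}` for odd `n`.
#' @param use_gc,use_nl,use_rc,use_ss Logical constraint flags. The
#'   secondary-structure screen is off by default.
#' @param max_run Maximum allowed homopolymer run length for the
#'   no-runlength constraint (default 1: no two adjacent equal symbols).
#' @param ss_min_stem Minimum stem length for the secondary-structure
#'   screen (integer >= 2).
#' @param rc_include_self Whether the reverse-complement distance is also
#'   required between a word and its own reverse complement (default TRUE).
#' @return An object of class `dna_constraints`.
#' @examples
#' dna_constraints(n = 7, d = 5)
#' @export
dna_constraints <- function(n, d, W = n %/% 2, gc_tolerance = NULL,
                            use_gc = TRUE, use_nl = TRUE, use_rc = FALSE,
                            use_ss = FALSE, max_run = 1L, ss_min_stem = 2L,
                            rc_include_self = TRUE) {
  n <- as.integer(n); d <- as.integer(d); W <- as.integer(W)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (d < 1 || d > n) stop("d must satisfy 1 <= d <= n", call. = FALSE)
  if (W < 0 || W > n) stop("W must satisfy 0 <= W <= n", call. = FALSE)
  if (ss_min_stem < 2) stop("ss_min_stem must be >= 2", call. = FALSE)
  if (max_run < 1) stop("max_run must be >= 1", call. = FALSE)
  if (is.null(gc_tolerance)) {
    gc_tolerance <- if (n %% 2 == 0) W else sort(unique(c(n %/% 2, (n + 1L) %/% 2)))
  }
  gc_tolerance <- as.integer(gc_tolerance)
  structure(list(n = n, d = d, W = W, gc_tolerance = gc_tolerance,
                 use_gc = isTRUE(use_gc), use_nl = isTRUE(use_nl),
                 use_rc = isTRUE(use_rc), use_ss = isTRUE(use_ss),
                 max_run = as.integer(max_run),
                 ss_min_stem = as.integer(ss_min_stem),
                 rc_include_self = isTRUE(rc_include_self)),
            class = "dna_constraints")
}

#' @export
print.dna_constraints <- function(x, ...) {
  flags <- c("GC"[x$use_gc], "NL"[x$use_nl], "RC"[x$use_rc], "SS"[x$use_ss])
  cat(sprintf("DNA coding constraints C^{%s}(n = %d, W = %d, d = %d)\n",
              paste(flags, collapse = ","), x$n, x$W, x$d))
  cat("  admissible GC counts:", paste(x$gc_tolerance, collapse = ", "), "\n")
  if (x$use_nl) cat("  max homopolymer run:", x$max_run, "\n")
  if (x$use_ss) cat("  min screened stem:", x$ss_min_stem, "\n")
  invisible(x)
}

#' Single-word constraint predicates
#'
#' `satisfies_gc()` tests whether the GC count of each word falls in the
#' admissible set of `constraints`; `is_run_free()` tests the no-runlength
#' constraint (no homopolymer run longer than `max_run`).
#'
#' @param x Character vector of DNA words.
#' @param constraints A [dna_constraints] object.
#' @param max_run Maximum allowed run of identical adjacent symbols.
#' @return Logical vector.
#' @examples
#' satisfies_gc("ATGTACG", dna_constraints(7, 3))  # TRUE (GC count 3)
#' is_run_free("CTGTGAC")  # TRUE
#' is_run_free("GAGATTC")  # FALSE ("TT")
#' @export
satisfies_gc <- function(x, constraints) {
  stopifnot(inherits(constraints, "dna_constraints"))
  gc_count(x) %in% constraints$gc_tolerance
}

#' @rdname satisfies_gc
#' @export
is_run_free <- function(x, max_run = 1L) {
  x <- as_dna(x)
  pat <- paste0("(.)\\1{", max_run, ",}")
  !grepl(pat, x)
}

#' Reverse-complement pair constraint
#'
#' Tests whether `hamming_dist(x, dna_revcomp(y)) >= d`, the pairwise
#' reverse-complement distance requirement. Applied over all ordered pairs
#' of a code set, including a word against its own reverse complement, it
#' suppresses cross-hybridization between codewords.
#'
#' @param x,y DNA words of equal length.
#' @param d Required minimum distance.
#' @return Logical scalar.
#' @examples
#' satisfies_rc_pair("AAAA", "AAAA", 4)  # TRUE: d("AAAA","TTTT") = 4
#' satisfies_rc_pair("AT", "AT", 1)      # FALSE: "AT" is its own revcomp
#' @export
satisfies_rc_pair <- function(x, y, d) {
  hamming_dist(x, dna_revcomp(y)) >= d
}

#' Secondary-structure stem screen
#'
#' A word can fold back on itself when two disjoint subwords are mutually
#' reverse-complementary (a stem). This screen reports whether such a stem
#' of length at least `min_stem` exists: indices `i`, `j` and a length
#' `m >= min_stem` with `|i - j| > m` (1-based starts) such that the
#' subword at `i` equals the reverse complement of the subword at `j`.
#'
#' This is a stem-existence screen, not a minimum-free-energy fold.
#'
#' @param x A single DNA word.
#' @param min_stem Minimum stem length (integer >= 2).
#' @return `TRUE` if a stem was found, else `FALSE`.
#' @examples
#' has_secondary_structure("ACGTAACGT", min_stem = 4)  # TRUE
#' has_secondary_structure("ACGT", min_stem = 2)       # FALSE
#' @export
has_secondary_structure <- function(x, min_stem = 2L) {
  x <- as_dna(x)
  if (length(x) != 1) stop("one word at a time", call. = FALSE)
  if (min_stem < 2) stop("min_stem must be >= 2", call. = FALSE)
  v <- seq_to_int(x)[1, ]
  n <- length(v)
  if (n < min_stem) return(FALSE)
  comp <- c(1L, 0L, 3L, 2L)[v + 1L]
  for (m in min_stem:(n - 1L)) {
    for (i in 1:(n - m + 1L)) {
      sub_i <- v[i:(i + m - 1L)]
      for (j in 1:(n - m + 1L)) {
        if (abs(i - j) > m &&
            identical(sub_i, rev(comp[j:(j + m - 1L)]))) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}
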