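# Code-set container, whole-set validation, rate/comparison metrics,
# and .cod / FASTA I/O.

#' DNA code-set container
#'
#' A `dna_codeset` is a set of distinct, equal-length DNA words together
#' with the constraint specification it is meant to satisfy and a
#' free-text provenance label.
#'
#' @param words Character vector of DNA words (equal length, no
#'   duplicates).
#' @param constraints Optional [dna_constraints] object.
#' @param provenance Free-text label recording how the set was obtained.
#' @return Object of class `dna_codeset`.
#' @examples
#' dna_codeset(c("ACGT", "TGCA"), dna_constraints(4, 2))
#' @export
dna_codeset <- function(words, constraints = NULL, provenance = "") {
  words <- as_dna(words, same_length = TRUE)
  if (anyDuplicated(words)) {
    stop("duplicate codewords: ",
         paste(unique(words[duplicated(words)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "dna_constraints"))
    if (nchar(words[1]) != constraints$n) {
      stop("word length ", nchar(words[1]),
           " does not match constraint n = ", constraints$n, call. = FALSE)
    }
  }
  structure(list(words = words, constraints = constraints,
                 provenance = provenance),
            class = "dna_codeset")
}

#' @export
print.dna_codeset <- function(x, ...) {
  cat(sprintf("DNA code set: %d words of length %d", length(x$words),
              nchar(x$words[1])))
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  show <- utils::head(x$words, 8)
  cat(" ", paste(show, collapse = " "),
      if (length(x$words) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
length.dna_codeset <- function(x) length(x$words)

#' Validate a code set against its constraints
#'
#' Checks every word against the single-word constraints (GC content,
#' no-runlength, secondary-structure screen) and every pair against the
#' Hamming-distance and reverse-complement requirements. Hamming distance
#' is checked over unordered pairs; the reverse-complement distance over
#' all ordered pairs, including each word against its own reverse
#' complement when `constraints$rc_include_self` is set.
#'
#' @param cs A [dna_codeset].
#' @param constraints A [dna_constraints] object; defaults to the one
#'   stored in `cs`.
#' @return Object of class `codeset_validation`: a list with data frames
#'   `word_violations` (word, rule) and `pair_violations`
#'   (word_i, word_j, rule, value) plus the flag `overall_pass`.
#' @examples
#' cs <- dna_codeset(c("ACGT", "AGCT"))
#' validate_codeset(cs, dna_constraints(4, 2))
#' @export
validate_codeset <- function(cs, constraints = NULL) {
  stopifnot(inherits(cs, "dna_codeset"))
  if (is.null(constraints)) constraints <- cs$constraints
  if (is.null(constraints)) {
    stop("no constraints stored in the set and none supplied", call. = FALSE)
  }
  w <- cs$words
  K <- length(w)
  n <- nchar(w[1])
  if (n != constraints$n) {
    stop("word length does not match constraint n", call. = FALSE)
  }
  wv <- data.frame(word = character(0), rule = character(0),
                   stringsAsFactors = FALSE)
  if (constraints$use_gc) {
    bad <- !satisfies_gc(w, constraints)
    if (any(bad)) wv <- rbind(wv, data.frame(word = w[bad], rule = "gc"))
  }
  if (constraints$use_nl) {
    bad <- !is_run_free(w, constraints$max_run)
    if (any(bad)) wv <- rbind(wv, data.frame(word = w[bad], rule = "runlength"))
  }
  if (constraints$use_ss) {
    bad <- vapply(w, has_secondary_structure, logical(1),
                  min_stem = constraints$ss_min_stem)
    if (any(bad)) wv <- rbind(wv, data.frame(word = w[bad],
                                             rule = "secondary_structure"))
  }
  pv <- data.frame(word_i = character(0), word_j = character(0),
                   rule = character(0), value = integer(0),
                   stringsAsFactors = FALSE)
  M <- seq_to_int(w)
  H <- hamming_matrix(M, M)
  d <- constraints$d
  # unordered pairs for plain Hamming distance
  if (K > 1) {
    idx <- which(upper.tri(H) & H < d, arr.ind = TRUE)
    if (nrow(idx)) {
      pv <- rbind(pv, data.frame(word_i = w[idx[, 1]], word_j = w[idx[, 2]],
                                 rule = "hamming", value = H[idx]))
    }
  }
  if (constraints$use_rc) {
    Mrc <- t(apply(M, 1, rc_int))
    if (n == 1) Mrc <- matrix(Mrc, ncol = 1)
    Hrc <- hamming_matrix(M, Mrc)  # Hrc[i, j] = d(w_i, revcomp(w_j))
    keep <- Hrc < d
    if (!constraints$rc_include_self) diag(keep) <- FALSE
    idx <- which(keep, arr.ind = TRUE)
    if (nrow(idx)) {
      pv <- rbind(pv, data.frame(word_i = w[idx[, 1]], word_j = w[idx[, 2]],
                                 rule = "reverse_complement",
                                 value = Hrc[idx]))
    }
  }
  structure(list(constraints = constraints, n_words = K,
                 word_violations = wv, pair_violations = pv,
                 overall_pass = nrow(wv) == 0 && nrow(pv) == 0),
            class = "codeset_validation")
}

# pairwise Hamming distances between rows of A and rows of B (equal ncol),
# via per-symbol indicator cross-products
hamming_matrix <- function(A, B) {
  n <- ncol(A)
  S <- matrix(0L, nrow(A), nrow(B))
  for (b in 0:3) {
    Ia <- A == b
    Ib <- B == b
    S <- S + tcrossprod(Ia, Ib)
  }
  n - S
}

#' @export
print.codeset_validation <- function(x, ...) {
  cat(sprintf("Code-set validation: %d words, %s\n", x$n_words,
              if (x$overall_pass) "PASS" else "FAIL"))
  if (nrow(x$word_violations)) {
    cat(" word violations:\n")
    print(x$word_violations, row.names = FALSE)
  }
  if (nrow(x$pair_violations)) {
    cat(sprintf(" pair violations (%d):\n", nrow(x$pair_violations)))
    print(utils::head(x$pair_violations, 10), row.names = FALSE)
    if (nrow(x$pair_violations) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Convert a validation report to JSON
#'
#' @param x A `codeset_validation` object.
#' @return A JSON string.
#' @export
validation_to_json <- function(x) {
  stopifnot(inherits(x, "codeset_validation"))
  jsonlite::toJSON(list(
    n_words = x$n_words,
    overall_pass = x$overall_pass,
    word_violations = x$word_violations,
    pair_violations = x$pair_violations
  ), auto_unbox = TRUE, digits = NA)
}

#' Coding rate of a DNA code
#'
#' The net rate of a code with `K` words of length `n` is
#' \eqn{R = \log_4(K) / n}, the number of information nucleotides per
#' transmitted nucleotide.
#'
#' @param K Number of codewords (>= 1).
#' @param n Word length (>= 1).
#' @param digits If non-`NULL`, truncate the rate toward zero at this many
#'   decimals. Published rate tables use truncation rather than rounding,
#'   so truncation is the convention for comparisons against them.
#' @return The coding rate in `(0, 1]` (0 when `K = 1`).
#' @examples
#' coding_rate(5, 2, digits = 4)    # 0.5804
#' coding_rate(190, 12, digits = 3) # 0.315
#' @export
coding_rate <- function(K, n, digits = NULL) {
  if (K < 1 || n < 1) stop("K and n must be >= 1", call. = FALSE)
  r <- log(K, base = 4) / n
  if (!is.null(digits)) r <- trunc_digits(r, digits)
  r
}

#' Percentage change between two quantities
#'
#' `100 * (new - old) / old`, optionally truncated toward zero, the
#' convention used when comparing printed lower-bound tables.
#'
#' @param new,old Numeric values; `old` must be positive.
#' @param digits If non-`NULL`, truncate toward zero at this many decimals.
#' @return Signed percentage.
#' @examples
#' percent_change(11967, 12068, digits = 2)  # -0.83
#' percent_change(248, 189, digits = 2)      # 31.21
#' @export
percent_change <- function(new, old, digits = NULL) {
  if (any(old <= 0)) stop("old value must be positive", call. = FALSE)
  p <- 100 * (new - old) / old
  if (!is.null(digits)) p <- trunc_digits(p, digits)
  p
}

#' Truncate toward zero at a fixed number of decimals
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places kept.
#' @return Truncated values.
#' @examples
#' trunc_digits(0.58048, 4)  # 0.5804
#' @export
trunc_digits <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

#' Read and write code lists
#'
#' Two plain-text formats are supported. The `.cod` dialect is one
#' uppercase codeword per line with optional `#`-prefixed comment lines;
#' a header comment of the form `# n=7 d=5 W=3 constraints=gc,nl,rc` is
#' written by `write_codes()` and, when present, restored into the
#' returned set's constraints. Standard FASTA (one codeword per record)
#' is read and written via Biostrings.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"cod"`, or `"fasta"`.
#' @param cs A [dna_codeset] to write.
#' @return `read_codes()` returns a [dna_codeset]; `write_codes()` returns
#'   `path` invisibly. Round trips preserve word order and content.
#' @export
read_codes <- function(path, format = c("auto", "cod", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "cod"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0) stop("no codewords in ", path, call. = FALSE)
    return(dna_codeset(unname(as.character(ss)),
                       provenance = basename(path)))
  }
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) stop("no codewords in ", path, call. = FALSE)
  words <- trimws(lines[keep])
  bad <- grepl("[^ACGTacgt]", words)
  if (any(bad)) {
    stop("parse error in ", path, " at line ",
         paste(keep[bad], collapse = ", "),
         ": non-ACGT symbol", call. = FALSE)
  }
  cons <- parse_cod_header(header)
  dna_codeset(words, constraints = cons, provenance = basename(path))
}

parse_cod_header <- function(header) {
  h <- grep("n=", header, value = TRUE)
  if (length(h) == 0) return(NULL)
  h <- h[1]
  get <- function(key) {
    m <- regmatches(h, regexpr(paste0(key, "=[0-9]+"), h))
    if (length(m) == 0) return(NULL)
    as.integer(sub(paste0(key, "="), "", m))
  }
  n <- get("n"); d <- get("d"); W <- get("W")
  if (is.null(n) || is.null(d)) return(NULL)
  flags <- regmatches(h, regexpr("constraints=[a-z,]+", h))
  fl <- if (length(flags)) strsplit(sub("constraints=", "", flags), ",")[[1]] else c("gc", "nl")
  dna_constraints(n = n, d = d, W = if (is.null(W)) n %/% 2 else W,
                  use_gc = "gc" %in% fl, use_nl = "nl" %in% fl,
                  use_rc = "rc" %in% fl, use_ss = "ss" %in% fl)
}

#' @rdname read_codes
#' @export
write_codes <- function(cs, path, format = c("auto", "cod", "fasta")) {
  stopifnot(inherits(cs, "dna_codeset"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "cod"
  }
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(cs$words)
    names(ss) <- sprintf("codeword_%03d", seq_along(cs$words))
    Biostrings::writeXStringSet(ss, path)
    return(invisible(path))
  }
  lines <- character(0)
  if (!is.null(cs$constraints)) {
    co <- cs$constraints
    flags <- tolower(c("gc"[co$use_gc], "nl"[co$use_nl],
                       "rc"[co$use_rc], "ss"[co$use_ss]))
    lines <- sprintf("# n=%d d=%d W=%d constraints=%s", co$n, co$d, co$W,
                     paste(flags, collapse = ","))
  }
  if (nzchar(cs$provenance)) {
    lines <- c(lines, paste("#", cs$provenance))
  }
  writeLines(c(lines, cs$words), path)
  invisible(path)
}
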