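# Binary <-> DNA payload codec: each byte maps to four quaternary digits
# (most-significant bit pair first) under the digit map A=0, T=1, C=2,
# G=3. The codec is a raw payload mapping; it enforces no coding
# constraints.

#' Encode bytes as a DNA word
#'
#' Each byte yields four bases, most-significant bit pair first, so the
#' output length is exactly four times the input length and the round
#' trip through [dna_decode_bases()] is lossless.
#'
#' @param data A raw vector (possibly empty).
#' @return A single DNA string (empty string for empty input).
#' @examples
#' dna_encode_bytes(as.raw(0x1b))  # "ATCG"
#' @export
dna_encode_bytes <- function(data) {
  if (!is.raw(data)) stop("data must be a raw vector", call. = FALSE)
  if (length(data) == 0) return("")
  b <- as.integer(data)
  digits <- rbind(b %/% 64L, (b %/% 16L) %% 4L, (b %/% 4L) %% 4L, b %% 4L)
  paste(DNA_BASES[digits + 1L], collapse = "")
}

#' Decode a DNA word back into bytes
#'
#' Exact inverse of [dna_encode_bytes()]. The word length must be a
#' multiple of four.
#'
#' @param x A single DNA string.
#' @return A raw vector.
#' @examples
#' dna_decode_bases("ATCG")  # 1b
#' @export
dna_decode_bases <- function(x) {
  if (!is.character(x) || length(x) != 1) {
    stop("x must be a single string", call. = FALSE)
  }
  if (nchar(x) == 0) return(raw(0))
  if (nchar(x) %% 4 != 0) {
    stop("framing error: length ", nchar(x), " is not a multiple of 4",
         call. = FALSE)
  }
  x <- as_dna(x)
  d <- match(strsplit(x, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
  m <- matrix(d, nrow = 4)
  as.raw(m[1, ] * 64L + m[2, ] * 16L + m[3, ] * 4L + m[4, ])
}

#' Encode or decode whole files
#'
#' `encode_file()` reads any file as bytes and writes its nucleotide
#' encoding as a single FASTA record; `decode_file()` reverses the
#' operation. The round trip is byte-exact.
#'
#' @param input,output File paths.
#' @param record_name FASTA record name for the encoded payload.
#' @return The output path, invisibly.
#' @export
encode_file <- function(input, output, record_name = NULL) {
  data <- readBin(input, "raw", n = file.size(input))
  seqs <- dna_encode_bytes(data)
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- if (is.null(record_name)) basename(input) else record_name
  Biostrings::writeXStringSet(ss, output)
  invisible(output)
}

#' @rdname encode_file
#' @export
decode_file <- function(input, output) {
  ss <- Biostrings::readDNAStringSet(input)
  if (length(ss) != 1) {
    stop("expected exactly one FASTA record, found ", length(ss),
         call. = FALSE)
  }
  data <- dna_decode_bases(as.character(ss[[1]]))
  writeBin(data, output)
  invisible(output)
}
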