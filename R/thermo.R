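# Nearest-neighbor melting-temperature model and the Tm-variance
# statistic used to compare constraint regimes.

# SantaLucia (1998) unified nearest-neighbor parameters:
# dH in kcal/mol, dS in cal/(mol K). Keys are the top-strand dinucleotide;
# a stack and its reverse complement share parameters.
NN_UNIFIED <- list(
  AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
  CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
  GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
  GG = c(-8.0, -19.9)
)
# initiation terms per terminal base pair
NN_INIT_GC <- c(0.1, -2.8)
NN_INIT_AT <- c(2.3, 4.1)

#' Thermodynamic parameters for melting-temperature calculation
#'
#' @param primer_conc Primer concentration in molar (default 200 nM).
#'   The primer-in-excess convention is used: the concentration entering
#'   the Tm formula is the primer concentration itself.
#' @param na_conc Monovalent cation concentration in molar (default
#'   50 mM).
#' @param nn_table Nearest-neighbor parameter set id; currently
#'   `"santalucia1998"`.
#' @param salt_correction Salt-correction method; currently the entropy
#'   correction `"entropy"` (`dS + 0.368 * (n - 1) * ln[Na+]`).
#' @return A list of class `thermo_params`.
#' @export
thermo_params <- function(primer_conc = 200e-9, na_conc = 0.05,
                          nn_table = "santalucia1998",
                          salt_correction = "entropy") {
  if (primer_conc <= 0 || na_conc <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  nn_table <- match.arg(nn_table, "santalucia1998")
  salt_correction <- match.arg(salt_correction, "entropy")
  structure(list(primer_conc = primer_conc, na_conc = na_conc,
                 nn_table = nn_table, salt_correction = salt_correction),
            class = "thermo_params")
}

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of each word with its perfect complement,
#' from the unified nearest-neighbor dH/dS sums with duplex-initiation
#' terms per terminal base pair, a symmetry correction for
#' self-complementary words, the entropy-based monovalent-salt
#' correction, and the primer-in-excess concentration term:
#' \deqn{T_m = \frac{1000\,\Delta H}{\Delta S + 0.368 (n-1) \ln[\mathrm{Na}^+]
#'   + R \ln C} - 273.15}
#' with `R = 1.987` cal/(mol K) and `C` the primer concentration.
#'
#' @param x Character vector of DNA words (length >= 2 each).
#' @param params A [thermo_params] object.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("ACGTATCAGA")  # about 25 C at the defaults
#' @export
melting_temperature <- function(x, params = thermo_params()) {
  stopifnot(inherits(params, "thermo_params"))
  x <- as_dna(x)
  if (any(nchar(x) < 2)) {
    stop("melting temperature needs word length >= 2", call. = FALSE)
  }
  vapply(x, function(w) tm_one(w, params), 0, USE.NAMES = FALSE)
}

tm_one <- function(w, params) {
  n <- nchar(w)
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    key <- paste0(chars[i], chars[i + 1])
    p <- NN_UNIFIED[[key]]
    if (is.null(p)) p <- NN_UNIFIED[[chartr("ACGT", "TGCA",
                                            paste0(chars[i + 1], chars[i]))]]
    dH <- dH + p[1]; dS <- dS + p[2]
  }
  for (term in chars[c(1, n)]) {
    ini <- if (term %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    dH <- dH + ini[1]; dS <- dS + ini[2]
  }
  if (w == dna_revcomp(w)) dS <- dS - 1.4  # symmetry correction
  dS <- dS + 0.368 * (n - 1) * log(params$na_conc)
  1000 * dH / (dS + 1.987 * log(params$primer_conc)) - 273.15
}

#' Melting-temperature variance of a code set
#'
#' Population variance (divisor `K`) of the per-word melting
#' temperatures. Code sets whose words share similar Tm support a more
#' uniform PCR regime, so a smaller variance indicates a more thermally
#' stable code set.
#'
#' @param cs A [dna_codeset] or character vector of at least two words.
#' @param params A [thermo_params] object.
#' @return Variance in squared degrees Celsius.
#' @export
tm_variance <- function(cs, params = thermo_params()) {
  words <- if (inherits(cs, "dna_codeset")) cs$words else as_dna(cs)
  if (length(words) < 2) {
    stop("tm_variance needs at least two words", call. = FALSE)
  }
  tms <- melting_temperature(words, params)
  mean((tms - mean(tms))^2)
}

#' Per-word Tm report for a code set
#'
#' @param cs A [dna_codeset] or character vector.
#' @param params A [thermo_params] object.
#' @return Data frame with columns `word`, `gc`, `tm_celsius`.
#' @export
tm_report <- function(cs, params = thermo_params()) {
  words <- if (inherits(cs, "dna_codeset")) cs$words else as_dna(cs)
  data.frame(word = words, gc = gc_count(words),
             tm_celsius = melting_temperature(words, params),
             stringsAsFactors = FALSE)
}
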