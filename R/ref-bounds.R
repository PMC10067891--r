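# Packaged reference lower-bound tables for code-set size comparisons.
# "mfos" columns are the published sizes obtained with this search
# approach; "prior" columns are the best previously reported sizes
# (earlier metaheuristic constructions) for the same (n, d) cell. These
# are reference data for comparison columns, not acceptance truth: the
# large-n cells are stochastic search artifacts.

#' Reference lower bounds for DNA coding sets
#'
#' Published best-found code-set sizes for the GC + no-runlength
#' constraint family (`"gc_nl"`) and for the family with the
#' reverse-complement constraint added (`"gc_nl_rc"`), with
#' `W = floor(n/2)`. Column `mfos` holds the sizes reported for the
#' moth-flame search this package implements; `prior` holds the best
#' earlier published sizes.
#'
#' @param constraint `"gc_nl"` or `"gc_nl_rc"`.
#' @return Data frame with columns `n`, `d`, `mfos`, `prior`.
#' @examples
#' head(ref_lower_bounds("gc_nl"))
#' @export
ref_lower_bounds <- function(constraint = c("gc_nl", "gc_nl_rc")) {
  constraint <- match.arg(constraint)
  if (constraint == "gc_nl") ref_gc_nl() else ref_gc_nl_rc()
}

ref_gc_nl <- function() {
  rows <- list(
    list(4, c(12), c(11)),
    list(5, c(20, 8), c(20, 8)),
    list(6, c(63, 27, 9), c(56, 24, 8)),
    list(7, c(208, 68, 23, 8), c(127, 45, 17, 7)),
    list(8, c(469, 171, 42, 18, 6), c(324, 106, 35, 14, 5)),
    list(9, c(1210, 279, 90, 37, 13, 6), c(713, 199, 65, 24, 10, 5)),
    list(10, c(3391, 829, 205, 79, 25, 10, 4),
         c(2081, 555, 159, 54, 20, 10, 4)),
    list(11, c(4703, 1967, 429, 124, 41, 8, 5, 4),
         c(4320, 1235, 284, 82, 29, 9, 4, 4)),
    list(12, c(11967, 5195, 934, 509, 73, 13, 9, 6),
         c(12068, 3326, 662, 190, 58, 22, 8, 4)),
    list(13, c(42343, 8392, 1780, 1519, 197, 51, 15, 9),
         c(41867, 7578, 1432, 1201, 123, 39, 13, 6)))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(n = r[[1]], d = seq(3, length.out = length(r[[2]])),
               mfos = r[[2]], prior = r[[3]])
  }))
}

ref_gc_nl_rc <- function() {
  rows <- list(
    list(4, c(11), c(11)),
    list(5, c(21, 8), c(24, 8)),
    list(6, c(71, 26, 7), c(58, 26, 7)),
    list(7, c(134, 63, 23, 5), c(148, 49, 19, 6)),
    list(8, c(419, 149, 51, 11, 6), c(328, 114, 35, 11, 6)),
    list(9, c(1026, 362, 113, 49, 9, 4), c(906, 281, 83, 30, 9, 4)),
    list(10, c(2249, 897, 248, 127, 27, 5, 5),
         c(2254, 721, 189, 79, 17, 5, 5)))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(n = r[[1]], d = seq(3, length.out = length(r[[2]])),
               mfos = r[[2]], prior = r[[3]])
  }))
}
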