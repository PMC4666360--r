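#' @useDynLib aluvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
#' @importFrom stats rbinom rnorm rpois runif median setNames dpois
#' @importFrom utils read.table write.table head tail
NULL

#' Reverse complement of nucleotide strings
#'
#' Vectorized over `x`; handles the `{A,C,G,T,N}` alphabet.
#'
#' @param x character vector of nucleotide strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  out <- vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    v <- rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]])
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# split a string into a character vector of single bases
#' @keywords internal
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# deterministic half-up rounding (base round() is banker's rounding)
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' @keywords internal
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}
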