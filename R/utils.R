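#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here follow
#' the half-up convention so that e.g. 89.55 prints as 89.6.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small relative epsilon so decimal halves stored just below .5 (e.g.
  # 89.55 -> 89.549999...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9 * pmax(1, abs(x) * p)) / p
}

#' Format a proportion as a percentage string
#'
#' @param p proportion in \[0, 1\].
#' @param digits decimal places (half-up); use 0 for integer display.
#' @return character, e.g. `"72.7%"`.
#' @export
format_percent <- function(p, digits = 1) {
  v <- round_half_up(100 * p, digits)
  paste0(formatC(v, format = "f", digits = digits), "%")
}

#' Wilson score 95 percent confidence interval for a binomial proportion
#'
#' @param k successes.
#' @param n trials (n >= 1).
#' @param conf confidence level.
#' @return named numeric `c(low, high)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

# Derive a child RNG seed from (seed, tag, index); stays below 2^31 so it is
# a legal R integer seed. Adding a record never perturbs another record's
# stream because each index gets its own derived seed.
derive_seed <- function(seed, tag, index = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

check_nucleotide <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad)) stop("invalid nucleotide in ", what)
  toupper(x)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @param type `"AA"` or `"DNA"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- if (type == "AA") Biostrings::readAAStringSet(path)
        else Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character vector to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  ss <- if (type == "AA") Biostrings::AAStringSet(seqs)
        else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
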