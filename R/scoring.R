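#' Alignment scoring scheme with Karlin-Altschul parameters
#'
#' Bundles a substitution matrix, affine gap penalties and the
#' Karlin-Altschul `lambda` / `K` used to convert raw local-alignment scores
#' into bit scores and E-values. The protein default is BLOSUM62 with gap
#' open 11 / extend 1 and the standard gapped parameters lambda = 0.267,
#' K = 0.041. The nucleotide default is match +2 / mismatch -3 with gap
#' 5 / 2 and lambda = 0.625, K = 0.41.
#'
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param matrix substitution matrix (numeric, dimnames = residue letters),
#'   or the name `"BLOSUM62"`.
#' @param gap_open,gap_extend positive gap penalties, `gap_extend <= gap_open`.
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @param type `"protein"` or `"nucleotide"` (used for residue coding).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, type = "protein") {
  if (is.character(matrix)) {
    name <- matrix
    matrix <- get_builtin_matrix(name)
  } else {
    name <- "custom"
  }
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  if (gap_extend > gap_open) stop("gap_extend must be <= gap_open")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(name = name, matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, type = type),
            class = "scoring_scheme")
}

#' Default nucleotide scoring scheme (+2/-3, gap 5/2)
#' @return a `scoring_scheme` for DNA.
#' @export
nucleotide_scheme <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-3, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 2
  m["N", ] <- 0; m[, "N"] <- 0
  scoring_scheme(m, gap_open = 5, gap_extend = 2,
                 lambda = 0.625, K = 0.41, type = "nucleotide")
}

get_builtin_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# Residue string -> 0-based integer codes into the scheme matrix rows.
# Unknown letters map to 'X' (protein) / 'N' (nucleotide) when present,
# otherwise error. NA_integer_ never emitted; masked positions use -1.
encode_seq <- function(x, scheme) {
  letters_m <- rownames(scheme$matrix)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  idx <- match(chars, letters_m)
  if (anyNA(idx)) {
    fb <- match(if (scheme$type == "protein") "X" else "N", letters_m)
    if (is.na(fb)) stop("sequence contains letters absent from the matrix: ",
                        paste(unique(chars[is.na(idx)]), collapse = ""))
    idx[is.na(idx)] <- fb
  }
  as.integer(idx - 1L)
}

decode_aln <- function(codes, scheme) {
  letters_m <- rownames(scheme$matrix)
  out <- rep("-", length(codes))
  out[codes >= 0] <- letters_m[codes[codes >= 0] + 1L]
  paste(out, collapse = "")
}

#' Convert a raw local-alignment score to a bit score
#'
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw_score raw alignment score.
#' @param scheme a [scoring_scheme()].
#' @return bit score (numeric).
#' @export
bit_score <- function(raw_score, scheme) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' Karlin-Altschul expectation value
#'
#' `E = m * n * 2^(-bits)`: the expected number of chance local alignments
#' scoring at least this well in an `m x n` search space.
#'
#' @param bits bit score.
#' @param m query length (>= 1).
#' @param n database length in residues (>= 1).
#' @return E-value (numeric >= 0).
#' @export
evalue <- function(bits, m, n) {
  stopifnot(m >= 1, n >= 1)
  m * n * 2^(-bits)
}
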