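#' Build a position weight model from a count matrix
#'
#' Converts a 4 x W position frequency (count) matrix into the derived
#' matrices used for scanning: a pseudocounted position probability matrix
#' (PPM), a log-odds scoring matrix (PSSM) against a background base
#' distribution, and a per-position information-content vector used as
#' position weights by the matrix-similarity score.
#'
#' The probability matrix is
#' `ppm[b, i] = (counts[b, i] + pseudocount * background[b]) /
#'              (colsum[i] + pseudocount)`,
#' the log-odds matrix is `log2(ppm / background)`, and the information
#' weight of column `i` is `2 + sum_b ppm[b, i] * log2(ppm[b, i])` bits,
#' ranging from 0 (uniform column) to 2 (single-base column).
#'
#' @param counts Numeric 4 x W matrix of non-negative base counts, rows in
#'   A, C, G, T order (row names, if present, may give any order).
#' @param name Model name used in hit and result tables.
#' @param pseudocount Total pseudocount weight per column, distributed
#'   proportionally to the background frequencies. Default 0.8.
#' @param background Length-4 background base frequencies (A, C, G, T);
#'   default uniform.
#' @return An object of class `pwm_model` with elements `name`, `width`,
#'   `counts`, `background`, `ppm`, `pssm` and `info` (bits per position).
#' @examples
#' m <- build_pwm(matrix(c(8, 0, 2, 0, 2, 4, 2, 2), nrow = 4), name = "toy")
#' m$ppm
#' consensus_word(m)
#' @export
build_pwm <- function(counts, name = "pwm", pseudocount = 0.8,
                      background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4)
    stop("'counts' must have 4 rows (A, C, G, T)", call. = FALSE)
  if (!is.null(rownames(counts))) {
    rn <- toupper(rownames(counts))
    if (!setequal(rn, DNA_BASES))
      stop("count matrix row names must be A, C, G, T", call. = FALSE)
    counts <- counts[DNA_BASES, , drop = FALSE]
  } else rownames(counts) <- DNA_BASES
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("count matrix has an all-zero column", call. = FALSE)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("'pseudocount' must be positive", call. = FALSE)
  if (length(background) != 4 || any(background <= 0))
    stop("'background' must be 4 positive frequencies", call. = FALSE)
  background <- background / sum(background)
  names(background) <- DNA_BASES
  ppm <- sweep(counts + pseudocount * background, 2, cs + pseudocount, "/")
  pssm <- log2(ppm / background)
  info <- 2 + colSums(ppm * log2(ppm))
  info <- pmin(pmax(info, 0), 2)  # guard rounding at the entropy bounds
  structure(list(name = name, width = ncol(counts), counts = counts,
                 background = background, ppm = ppm, pssm = pssm,
                 info = unname(info)),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("Position weight model '%s' (width %d)\n", x$name, x$width))
  cat(sprintf("  consensus: %s\n", consensus_word(x)))
  cat(sprintf("  information (bits/position): %s  [mean %.2f]\n",
              paste(sprintf("%.2f", x$info), collapse = " "),
              mean(x$info)))
  invisible(x)
}

#' Consensus word of a position weight model
#'
#' The word formed by each column's highest-probability base (ties broken
#' by A < C < G < T order).
#'
#' @param model A [build_pwm()] model.
#' @return A single character string of length `model$width`.
#' @export
consensus_word <- function(model) {
  stopifnot(inherits(model, "pwm_model"))
  paste(DNA_BASES[apply(model$ppm, 2, which.max)], collapse = "")
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of sequences over A, C, G, T, N (case
#'   insensitive; output is upper case).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGTN")
#' @export
reverse_complement <- function(x) {
  flipped <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(flipped, ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

# reverse-complemented model: scanning the + strand with it is equivalent
# to scanning the - strand with the original
revcomp_pwm <- function(model) {
  flip <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  out <- model
  out$counts <- flip(model$counts)
  out$ppm <- flip(model$ppm)
  out$pssm <- flip(model$pssm)
  rownames(out$counts) <- rownames(out$ppm) <- rownames(out$pssm) <- DNA_BASES
  out$info <- rev(model$info)
  out
}

encode_dna <- function(x) {
  lapply(strsplit(toupper(x), ""), function(ch) {
    code <- match(ch, DNA_BASES)  # N and anything else -> NA
    if (any(is.na(code) & ch != "N"))
      stop("sequence contains characters outside A, C, G, T, N",
           call. = FALSE)
    code
  })
}

#' Matrix-similarity score of a word under a position weight model
#'
#' Information-weighted similarity between a word and a model:
#' `sum_i c_i * ppm[word_i, i] / sum_i c_i * max_b ppm[b, i]`, with `c_i`
#' the per-position information weights. The score lies in `[0, 1]` and
#' equals 1 exactly when the word matches the per-position argmax base at
#' every position carrying positive weight. For a model whose columns are
#' all uniform the total weight is zero and the score is defined as 1.
#' An `N` in the word contributes zero to the numerator.
#'
#' @param model A [build_pwm()] model.
#' @param word Character vector of words, each of the model's width.
#' @return Numeric vector of scores in `[0, 1]`.
#' @examples
#' m <- build_pwm(matrix(c(8, 0, 2, 0, 2, 4, 2, 2), nrow = 4), name = "toy")
#' matsim_score(m, consensus_word(m))
#' @export
matsim_score <- function(model, word) {
  stopifnot(inherits(model, "pwm_model"))
  score_words(model, word, "matsim")
}

#' Log-odds score of a word under a position weight model
#'
#' The sum over positions of `log2(ppm[word_i, i] / background[word_i])`,
#' in bits. An `N` in the word contributes zero.
#'
#' @inheritParams matsim_score
#' @return Numeric vector of scores in bits.
#' @export
logodds_score <- function(model, word) {
  stopifnot(inherits(model, "pwm_model"))
  score_words(model, word, "logodds")
}

score_words <- function(model, word, method) {
  codes <- encode_dna(word)
  bad <- lengths(codes) != model$width
  if (any(bad))
    stop("word length does not match the model width", call. = FALSE)
  mat <- score_matrix(model, method)
  denom <- attr(mat, "denom")
  vapply(codes, function(cd) {
    contrib <- mat[cbind(cd, seq_len(model$width))]
    s <- sum(contrib, na.rm = TRUE)  # N -> zero contribution
    if (method == "matsim") { if (denom == 0) 1 else s / denom } else s
  }, numeric(1))
}

# per-base scoring matrix for a method; for matsim it is info-weighted ppm
# with the maximal attainable sum stored as attribute "denom"
score_matrix <- function(model, method) {
  if (method == "matsim") {
    m <- sweep(model$ppm, 2, model$info, "*")
    attr(m, "denom") <- sum(model$info * apply(model$ppm, 2, max))
  } else {
    m <- model$pssm
    attr(m, "denom") <- NA_real_
  }
  m
}
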