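#' Scan promoter sequences for motif hits
#'
#' Slides a position weight model over every promoter window and reports
#' windows scoring at or above a threshold. With `both_strands = TRUE` the
#' reverse strand is scanned as well (by scoring windows against the
#' reverse-complemented model), and reverse-strand hits are reported in
#' plus-strand coordinates of the window start. Coordinates are 0-based,
#' half-open: a hit occupies `[start, start + W)`.
#'
#' Windows containing `N` are skipped under the default `n_policy = "skip"`;
#' under `"penalize"` the `N` positions contribute zero to the score and the
#' window competes like any other. Promoters shorter than the model width
#' yield no hits.
#'
#' @param promoters Named character vector of promoter sequences
#'   (a promoter set as returned by [read_fasta()] or
#'   [simulate_promoters()]).
#' @param model A [build_pwm()] model, or a list of them to scan several
#'   motifs in one call.
#' @param method Scoring method: `"matsim"` (information-weighted matrix
#'   similarity in `[0, 1]`) or `"logodds"` (bits).
#' @param threshold Minimum reported score. Must lie in `[0, 1]` for
#'   `"matsim"`; any real for `"logodds"`.
#' @param both_strands Scan the reverse strand too? Default `TRUE`.
#' @param n_policy How windows containing `N` are handled: `"skip"`
#'   (default) or `"penalize"`.
#' @return A data.frame of hits with columns `promoter_id`, `start`, `end`,
#'   `strand`, `score`, `motif`, `method`, sorted by motif, promoter, start
#'   and strand, with attributes `both_strands` and `widths` (named motif
#'   widths) used downstream by [summarize_incidence()].
#' @examples
#' m <- build_pwm(matrix(c(9, 0, 0, 0, 0, 9, 0, 0), 4), name = "AC")
#' scan_promoters(c(p1 = "TTACGT"), m, threshold = 1)
#' @export
scan_promoters <- function(promoters, model, method = c("matsim", "logodds"),
                           threshold = 0.85, both_strands = TRUE,
                           n_policy = c("skip", "penalize")) {
  method <- match.arg(method)
  n_policy <- match.arg(n_policy)
  if (!is.character(promoters) || is.null(names(promoters)) ||
      anyDuplicated(names(promoters)))
    stop("'promoters' must be a uniquely named character vector",
         call. = FALSE)
  if (method == "matsim" &&
      (!is.numeric(threshold) || threshold < 0 || threshold > 1))
    stop("matsim 'threshold' must lie in [0, 1]", call. = FALSE)
  models <- if (inherits(model, "pwm_model")) list(model) else model
  if (!length(models) || !all(vapply(models, inherits, TRUE, "pwm_model")))
    stop("'model' must be a pwm_model or a list of them", call. = FALSE)

  codes <- encode_dna(promoters)
  lens <- lengths(codes)
  out <- lapply(models, function(mod)
    scan_one(codes, lens, names(promoters), mod, method, threshold,
             both_strands, n_policy))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, both_strands = both_strands,
            widths = setNames(vapply(models, function(m) m$width, 0),
                              vapply(models, function(m) m$name, "")))
}

# scan every promoter against one model by concatenating the integer-coded
# sequences with W-1 NA separators and scoring all windows in vector form
scan_one <- function(codes, lens, ids, model, method, threshold,
                     both_strands, n_policy) {
  W <- model$width
  empty <- data.frame(promoter_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), motif = character(),
                      method = character(), stringsAsFactors = FALSE)
  keep <- lens >= W
  if (!any(keep)) return(empty)
  sep <- rep(NA_integer_, W - 1L)
  cat_codes <- unlist(lapply(codes[keep], function(x) c(x, sep)),
                      use.names = FALSE)
  starts0 <- cumsum(c(0L, (lens[keep] + W - 1L)[-sum(keep)]))  # concat origin
  n_win <- length(cat_codes) - W + 1L
  if (n_win < 1) return(empty)

  strands <- if (both_strands) c("+", "-") else "+"
  pieces <- lapply(strands, function(strand) {
    mod <- if (strand == "-") revcomp_pwm(model) else model
    mat <- score_matrix(mod, method)
    denom <- attr(mat, "denom")
    s <- numeric(n_win)
    has_na <- logical(n_win)
    idx <- seq_len(n_win)
    for (j in seq_len(W)) {
      v <- mat[cbind(cat_codes[idx + (j - 1L)], j)]
      nas <- is.na(v)
      if (any(nas)) { has_na <- has_na | nas; v[nas] <- 0 }
      s <- s + v
    }
    if (method == "matsim") s <- if (denom == 0) rep(1, n_win) else s / denom
    ok <- s >= threshold
    if (n_policy == "skip") ok <- ok & !has_na
    # separator windows always contain NA; under "penalize" they must still
    # be discarded, as must any window crossing a promoter end
    pos <- which(ok)
    if (!length(pos)) return(NULL)
    pi <- findInterval(pos - 1L, starts0)
    local <- (pos - 1L) - starts0[pi]
    inside <- local + W <= lens[keep][pi]
    pos <- pos[inside]; pi <- pi[inside]; local <- local[inside]
    if (!length(pos)) return(NULL)
    data.frame(promoter_id = ids[keep][pi], start = local,
               end = local + W, strand = strand, score = s[pos],
               motif = model$name, method = method,
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, pieces)
  out[order(out$promoter_id, out$start, out$strand), , drop = FALSE]
}

#' Write motif hits as BED6
#'
#' One line per hit: promoter id, 0-based half-open start/end, motif name,
#' an integer score in 0-1000 (matrix-similarity scores are scaled by 1000;
#' log-odds scores in bits are scaled by 100 and clamped into the range),
#' and strand.
#'
#' @param hits A hit table from [scan_promoters()].
#' @param path Output file.
#' @param seed Seed recorded in the file header.
#' @return The path, invisibly.
#' @export
write_bed <- function(hits, path, seed = NULL) {
  scaled <- ifelse(hits$method == "matsim",
                   round(hits$score * 1000), round(hits$score * 100))
  bed <- data.frame(hits$promoter_id, hits$start, hits$end, hits$motif,
                    pmax(0L, pmin(1000L, as.integer(scaled))), hits$strand)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 motif hit file written by [write_bed()]
#'
#' @param path BED file path.
#' @return A data.frame with columns `promoter_id`, `start`, `end`,
#'   `strand`, `score` (the 0-1000 integer) and `motif`.
#' @export
read_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("expected 6 BED columns", call. = FALSE)
  data.frame(promoter_id = bed[[1]], start = bed[[2]], end = bed[[3]],
             strand = bed[[6]], score = bed[[5]], motif = bed[[4]],
             stringsAsFactors = FALSE)
}
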