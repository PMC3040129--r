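#' Read promoter sequences from FASTA
#'
#' Reads a (possibly multi-record) FASTA file into a named character vector
#' of upper-case sequences. Only A, C, G, T and N are accepted; a record
#' containing anything else is an error naming the record. Record ids are
#' the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (a promoter set).
#' @export
read_fasta <- function(path) {
  xs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ids", call. = FALSE)
  seqs <- toupper(as.character(xs))
  names(seqs) <- ids
  if (any(!nzchar(seqs)))
    stop("empty FASTA record: ", ids[!nzchar(seqs)][1], call. = FALSE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("record '", ids[bad][1],
         "' contains characters outside A, C, G, T, N", call. = FALSE)
  seqs
}

#' Write promoter sequences as FASTA
#'
#' Writes a named character vector of sequences wrapped at 60 columns.
#' Round-trips with [read_fasta()].
#'
#' @param x Named character vector of sequences.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("'x' must be uniquely named", call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 60)
  invisible(path)
}

#' Read position frequency matrices
#'
#' Two text dialects are supported. `"jaspar"`: records of the form
#' \preformatted{>MA0001.1 NAME
#' A  [ 3 21  0 ... ]
#' C  [ ... ]
#' G  [ ... ]
#' T  [ ... ]}
#' (brackets optional). `"plain"`: one matrix of four whitespace-separated
#' rows in A, C, G, T order, optionally preceded by a `>name` header;
#' several matrices may be concatenated with blank lines or headers between
#' them.
#'
#' @param path PFM file path.
#' @param dialect `"jaspar"` (default) or `"plain"`.
#' @param ... Passed to [build_pwm()] (pseudocount, background).
#' @return A list of [build_pwm()] models.
#' @export
read_pfm <- function(path, dialect = c("jaspar", "plain"), ...) {
  dialect <- match.arg(dialect)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no matrices in file", call. = FALSE)
  parse_row <- function(ln, expect_base = NULL) {
    if (!is.null(expect_base)) {
      base <- toupper(substr(ln, 1, 1))
      if (base != expect_base)
        stop("expected a row for base ", expect_base, ", got: ", ln,
             call. = FALSE)
      ln <- sub("^[ACGTacgt]", "", ln)
    }
    ln <- gsub("[][]", " ", ln)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (any(is.na(vals))) stop("malformed matrix row: ", ln, call. = FALSE)
    if (any(vals < 0)) stop("negative counts in matrix row", call. = FALSE)
    vals
  }
  finish <- function(name, rows) {
    if (length(rows) != 4)
      stop("matrix '", name, "' does not have 4 base rows", call. = FALSE)
    if (length(unique(lengths(rows))) != 1)
      stop("ragged rows in matrix '", name, "'", call. = FALSE)
    build_pwm(do.call(rbind, rows), name = name, ...)
  }
  models <- list()
  if (dialect == "jaspar") {
    hdr <- which(startsWith(lines, ">"))
    if (!length(hdr)) stop("no '>' headers in JASPAR file", call. = FALSE)
    bounds <- c(hdr, length(lines) + 1L)
    for (i in seq_along(hdr)) {
      block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
      name <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]][1]
      rows <- lapply(seq_along(block), function(j)
        parse_row(block[j], DNA_BASES[j]))
      models[[length(models) + 1L]] <- finish(name, rows)
    }
  } else {
    i <- 1L; counter <- 0L
    while (i <= length(lines)) {
      name <- if (startsWith(lines[i], ">")) {
        nm <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]][1]
        i <- i + 1L
        nm
      } else sprintf("pfm_%02d", counter + 1L)
      if (i + 3L > length(lines))
        stop("incomplete matrix block at end of file", call. = FALSE)
      rows <- lapply(lines[i:(i + 3L)], parse_row)
      models[[length(models) + 1L]] <- finish(name, rows)
      counter <- counter + 1L
      i <- i + 4L
    }
  }
  models
}

#' Write position frequency matrices in JASPAR text format
#'
#' @param models A [build_pwm()] model or list of them.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_pfm <- function(models, path) {
  if (inherits(models, "pwm_model")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(sprintf(">%s %s", m$name, m$name), con)
    for (b in DNA_BASES)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m$counts[b, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Write study call lists as TSV
#'
#' @param calls data.frame with columns `study_id`, `gene_id`, `direction`
#'   (plus any extras).
#' @param path Output file path.
#' @param seed Seed recorded in the file header.
#' @return The path, invisibly.
#' @export
write_study_calls <- function(calls, path, seed = NULL) {
  write_tsv(calls, path, output_header(seed))
}
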