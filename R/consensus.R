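#' Harmonize raw study gene calls onto canonical identifiers
#'
#' Maps each study's reported identifiers (probe ids, symbols, ...) onto a
#' canonical cluster identifier through a mapping table, the analogue of
#' keying every report's transcripts to a shared cluster id before
#' intersecting lists. Multiple source ids that collapse to the same
#' canonical id with the same direction within a study collapse to a single
#' call; a canonical id called both up and down within one study is an
#' intra-study contradiction and is excluded from that study's votes.
#' Source ids without a mapping row are dropped and counted.
#'
#' @param calls data.frame of raw records with columns `study_id`,
#'   `source_id`, `namespace` and `direction` (`"up"` or `"down"`). A
#'   `gene_id` column is accepted as an alias for `source_id`.
#' @param mapping data.frame with columns `source_id`, `namespace`,
#'   `canonical_id` and `symbol`. A source id may map to at most one
#'   canonical id within a namespace; ambiguous rows are an error.
#' @return A list of class `harmonized_calls`:
#'   \describe{
#'     \item{calls}{data.frame `study_id`, `gene_id` (canonical), `symbol`,
#'       `direction`, one row per study-level vote.}
#'     \item{report}{list with `n_records`, `n_unmapped`, `unmapped_ids`,
#'       and `contradictions` (data.frame `study_id`, `gene_id`).}
#'   }
#' @export
harmonize <- function(calls, mapping) {
  if (!all(c("study_id", "direction") %in% names(calls)))
    stop("'calls' needs study_id and direction columns", call. = FALSE)
  if (!"source_id" %in% names(calls)) {
    if (!"gene_id" %in% names(calls))
      stop("'calls' needs a source_id (or gene_id) column", call. = FALSE)
    calls$source_id <- calls$gene_id
  }
  if (!"namespace" %in% names(calls)) calls$namespace <- "default"
  if (!all(calls$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'", call. = FALSE)
  need <- c("source_id", "namespace", "canonical_id", "symbol")
  if (!all(need %in% names(mapping)))
    stop("'mapping' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- paste(mapping$namespace, mapping$source_id, sep = "\r")
  amb <- tapply(mapping$canonical_id, key, function(x) length(unique(x)))
  if (any(amb > 1))
    stop("ambiguous mapping: a source id maps to several canonical ids ",
         "within one namespace (", sub("\r", ":", names(amb)[amb > 1][1]),
         ")", call. = FALSE)
  mapping <- mapping[!duplicated(key), ]
  key <- paste(mapping$namespace, mapping$source_id, sep = "\r")

  ckey <- paste(calls$namespace, calls$source_id, sep = "\r")
  hit <- match(ckey, key)
  unmapped <- is.na(hit)
  mapped <- data.frame(study_id = calls$study_id[!unmapped],
                       gene_id = mapping$canonical_id[hit[!unmapped]],
                       symbol = mapping$symbol[hit[!unmapped]],
                       direction = calls$direction[!unmapped],
                       stringsAsFactors = FALSE)
  # collapse concordant duplicates to one vote per (study, gene, direction)
  mapped <- mapped[!duplicated(mapped[c("study_id", "gene_id", "direction")]), ]
  sg <- paste(mapped$study_id, mapped$gene_id, sep = "\r")
  contra_keys <- unique(sg[duplicated(sg)])
  contradictions <- unique(mapped[sg %in% contra_keys,
                                  c("study_id", "gene_id")])
  rownames(contradictions) <- NULL
  mapped <- mapped[!sg %in% contra_keys, ]
  rownames(mapped) <- NULL
  structure(list(
    calls = mapped,
    report = list(n_records = nrow(calls),
                  n_unmapped = sum(unmapped),
                  unmapped_ids = unique(calls$source_id[unmapped]),
                  contradictions = contradictions)),
    class = "harmonized_calls")
}

#' @export
print.harmonized_calls <- function(x, ...) {
  cat(sprintf(
    "Harmonized %d records to %d study-level calls (%d unmapped, %d intra-study contradictions)\n",
    x$report$n_records, nrow(x$calls), x$report$n_unmapped,
    nrow(x$report$contradictions)))
  invisible(x)
}

#' Build the gene-by-study direction vote table
#'
#' Arranges harmonized study calls as a gene x study matrix of direction
#' calls (`"up"`, `"down"` or absent), the substrate of the vote-counting
#' consensus filter. Studies that do not disclose their down-regulated
#' transcripts can be excluded from the down-vote electorate through
#' `down_capable`, so that thresholds are interpreted against the correct
#' number of studies able to vote in each direction.
#'
#' @param calls data.frame with columns `study_id`, `gene_id`, `direction`
#'   and optionally `symbol` (as produced by [harmonize()],
#'   [simulate_studies()] or [certl_calls()]).
#' @param studies Optional character vector of all study ids (to include
#'   studies that contributed no calls); duplicates are an error.
#' @param down_capable Character vector of study ids eligible to vote
#'   "down"; defaults to all studies. A "down" call from a study outside
#'   this set is an error.
#' @return An object of class `vote_table`: list with the character
#'   `matrix` (genes x studies, `NA` = absent), `symbols`, `studies`,
#'   `down_capable`, and the electorate sizes `n_up_capable`,
#'   `n_down_capable`.
#' @export
build_vote_table <- function(calls, studies = NULL, down_capable = NULL) {
  need <- c("study_id", "gene_id", "direction")
  if (!all(need %in% names(calls)))
    stop("'calls' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(calls) == 0 && is.null(studies))
    stop("no calls and no study list given", call. = FALSE)
  if (!all(calls$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'", call. = FALSE)
  if (is.null(studies)) studies <- unique(calls$study_id)
  if (anyDuplicated(studies))
    stop("duplicate study_id", call. = FALSE)
  if (!all(calls$study_id %in% studies))
    stop("calls reference a study not in 'studies'", call. = FALSE)
  down_capable <- down_capable %||% studies
  if (!all(down_capable %in% studies))
    stop("'down_capable' names unknown studies", call. = FALSE)
  bad <- calls$direction == "down" & !calls$study_id %in% down_capable
  if (any(bad))
    stop("down call from a study not down-capable: ",
         paste(unique(calls$study_id[bad]), collapse = ", "), call. = FALSE)
  sg <- paste(calls$study_id, calls$gene_id, sep = "\r")
  if (anyDuplicated(sg)) {
    dup <- calls[sg %in% sg[duplicated(sg)], ]
    if (any(tapply(dup$direction, paste(dup$study_id, dup$gene_id),
                   function(d) length(unique(d))) > 1))
      stop("a gene is called both up and down within one study; ",
           "run harmonize() first", call. = FALSE)
    calls <- calls[!duplicated(sg), ]
  }
  genes <- sort(unique(calls$gene_id))
  m <- matrix(NA_character_, length(genes), length(studies),
              dimnames = list(genes, studies))
  m[cbind(match(calls$gene_id, genes), match(calls$study_id, studies))] <-
    calls$direction
  symbols <- if ("symbol" %in% names(calls))
    setNames(calls$symbol, calls$gene_id)[genes] else setNames(genes, genes)
  structure(list(matrix = m, symbols = symbols, studies = studies,
                 down_capable = down_capable,
                 n_up_capable = length(studies),
                 n_down_capable = length(down_capable)),
            class = "vote_table")
}

#' @export
print.vote_table <- function(x, ...) {
  cat(sprintf("Vote table: %d genes x %d studies (%d up-capable, %d down-capable)\n",
              nrow(x$matrix), length(x$studies), x$n_up_capable,
              x$n_down_capable))
  invisible(x)
}

#' Apply the direction-aware vote-counting consensus filter
#'
#' Counts, for every gene, the studies supporting up- and down-regulation
#' and classifies the gene against direction-specific support thresholds:
#' `consensus_up` when at least `min_up` studies call it up and fewer than
#' `min_down` call it down, `consensus_down` symmetrically, `conflict` when
#' both thresholds are met (such a gene is excluded from both consensus
#' lists), and `below_threshold` otherwise. The default thresholds (4 of
#' the up-capable studies, 3 of the down-capable ones) reflect a
#' seven-study design in which one study discloses no down-regulated
#' transcripts.
#'
#' @param table A [build_vote_table()] object.
#' @param min_up,min_down Minimum supporting study counts per direction;
#'   each must be at least 1 and no larger than the corresponding
#'   electorate.
#' @return An object of class `consensus_result`: a data.frame with columns
#'   `gene_id`, `symbol`, `n_up`, `n_down`, `status`, ordered with the
#'   consensus-up block first (support descending, then symbol), then the
#'   consensus-down block, then conflicts, then below-threshold genes.
#'   Thresholds are carried in attributes `min_up` and `min_down`.
#' @seealso [consensus_genes()] to extract one direction's gene list.
#' @export
apply_consensus_filter <- function(table, min_up = 4, min_down = 3) {
  if (!inherits(table, "vote_table"))
    stop("'table' must be a vote_table", call. = FALSE)
  if (min_up < 1 || min_down < 1)
    stop("thresholds must be at least 1", call. = FALSE)
  if (min_up > table$n_up_capable)
    stop("'min_up' exceeds the number of up-capable studies", call. = FALSE)
  if (min_down > table$n_down_capable)
    stop("'min_down' exceeds the number of down-capable studies",
         call. = FALSE)
  m <- table$matrix
  n_up <- rowSums(m == "up", na.rm = TRUE)
  n_down <- rowSums(m == "down", na.rm = TRUE)
  up_ok <- n_up >= min_up
  down_ok <- n_down >= min_down
  status <- ifelse(up_ok & down_ok, "conflict",
            ifelse(up_ok, "consensus_up",
            ifelse(down_ok, "consensus_down", "below_threshold")))
  out <- data.frame(gene_id = rownames(m),
                    symbol = unname(table$symbols[rownames(m)]),
                    n_up = unname(n_up), n_down = unname(n_down),
                    status = status, stringsAsFactors = FALSE)
  rank <- match(out$status, c("consensus_up", "consensus_down", "conflict",
                              "below_threshold"))
  support <- ifelse(out$status == "consensus_down", out$n_down,
                    pmax(out$n_up, out$n_down))
  out <- out[order(rank, -support, out$symbol, out$gene_id), ]
  rownames(out) <- NULL
  structure(out, class = c("consensus_result", "data.frame"),
            min_up = min_up, min_down = min_down)
}

#' Extract a consensus gene list from a consensus result
#'
#' @param x A [apply_consensus_filter()] result.
#' @param direction `"up"` or `"down"`.
#' @return data.frame of the genes with that consensus status, ordered by
#'   support (descending) then symbol.
#' @export
consensus_genes <- function(x, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(x, "consensus_result"))
  out <- x[x$status == paste0("consensus_", direction), , drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}

#' @export
print.consensus_result <- function(x, ...) {
  tab <- table(factor(x$status, c("consensus_up", "consensus_down",
                                  "conflict", "below_threshold")))
  cat(sprintf(
    "Consensus filter (min_up = %d, min_down = %d) over %d genes:\n",
    attr(x, "min_up"), attr(x, "min_down"), nrow(x)))
  cat(sprintf("  consensus up:    %d\n  consensus down:  %d\n", tab[1], tab[2]))
  cat(sprintf("  conflict:        %d\n  below threshold: %d\n", tab[3], tab[4]))
  invisible(x)
}

#' @export
summary.consensus_result <- function(object, n = 10, ...) {
  print(object)
  up <- consensus_genes(object, "up")
  down <- consensus_genes(object, "down")
  if (nrow(up)) {
    cat("Top consensus-up genes:\n")
    print(head(up[c("symbol", "n_up", "n_down")], n), row.names = FALSE)
  }
  if (nrow(down)) {
    cat("Top consensus-down genes:\n")
    print(head(down[c("symbol", "n_up", "n_down")], n), row.names = FALSE)
  }
  invisible(object)
}

#' Packaged direction-call matrix of the consensus receptivity transcript list
#'
#' Loads the packaged transcription of the published cross-study comparison
#' tables: one row per (study, gene) differential-expression call for the 61
#' genes of the consensus endometrial receptivity transcript list, keyed by
#' UniGene cluster id, across seven window-of-implantation microarray
#' studies.
#'
#' @return data.frame with columns `study_id`, `gene_id`, `symbol`,
#'   `direction`.
#' @seealso [certl_studies()] for the study metadata, including which
#'   studies disclose down-regulated transcripts.
#' @examples
#' calls <- certl_calls()
#' meta <- certl_studies()
#' vt <- build_vote_table(calls, studies = meta$study_id,
#'                        down_capable = meta$study_id[meta$discloses_down])
#' apply_consensus_filter(vt)
#' @export
certl_calls <- function() {
  read_tsv(system.file("extdata", "certl_direction_calls.tsv",
                       package = "certl", mustWork = TRUE))
}

#' Packaged metadata of the pooled receptivity microarray studies
#'
#' @return data.frame with one row per study: `study_id`, `platform`,
#'   `fold_change_cutoff`, reported `n_up`/`n_down` transcript counts, and
#'   `discloses_down` (whether the study's down-regulated transcripts are
#'   public and the study can therefore vote on down-regulation).
#' @export
certl_studies <- function() {
  read_tsv(system.file("extdata", "certl_studies.tsv",
                       package = "certl", mustWork = TRUE))
}

#' Read study gene lists from TSV
#'
#' Expects columns `study_id`, `gene_id` (or `source_id`) and `direction`;
#' additional columns (`symbol`, `namespace`) are kept. Lines starting with
#' `#` are ignored.
#'
#' @param paths One or more file paths; files are concatenated.
#' @return data.frame of raw study call records.
#' @export
read_study_calls <- function(paths) {
  out <- do.call(rbind, lapply(paths, read_tsv))
  if (!"direction" %in% names(out))
    stop("study list lacks a 'direction' column", call. = FALSE)
  if (!all(out$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'", call. = FALSE)
  if (!any(c("gene_id", "source_id") %in% names(out)))
    stop("study list lacks a gene identifier column", call. = FALSE)
  out
}

#' Read an identifier-harmonization mapping table from TSV
#'
#' @param path File with columns `source_id`, `namespace`, `canonical_id`,
#'   `symbol`.
#' @return data.frame mapping table for [harmonize()].
#' @export
read_id_mapping <- function(path) {
  out <- read_tsv(path)
  need <- c("source_id", "namespace", "canonical_id", "symbol")
  if (!all(need %in% names(out)))
    stop("mapping needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out
}
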