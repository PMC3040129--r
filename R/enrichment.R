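#' Exact one-sided hypergeometric tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated genes in a size-`n` draw from a universe of `N`
#' genes of which `K` carry the annotation. This is the over-representation
#' statistic behind term-enrichment "p Value" columns, computed exactly
#' (no normal approximation) and identical to a one-sided Fisher exact test
#' on the implied 2x2 table.
#'
#' @param k Observed overlap count(s).
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return Numeric vector of tail probabilities in `(0, 1]`.
#' @examples
#' hypergeom_tail(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_tail <- function(k, K, n, N) {
  r <- suppressWarnings(cbind(k, K, n, N))  # recycle to common length
  k <- r[, 1]; K <- r[, 2]; n <- r[, 3]; N <- r[, 4]
  if (any(is.na(r)) || any(r < 0) || any(r != round(r)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(K > N) || any(n > N) || any(k > pmin(K, n)))
    stop("inconsistent counts: need k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  unname(phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' Order-preserving false-discovery-rate adjustment of a vector of
#' probabilities in `(0, 1]`.
#'
#' @param p Numeric vector of probabilities in `(0, 1]`.
#' @return Numeric vector of adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("probabilities must lie in (0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#' A missing description field is tolerated; duplicate members within a set
#' are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return A named list of character vectors (class
#'   `gene_set_collection`), with the per-set descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate gene-set names in GMT", call. = FALSE)
  desc <- vapply(fields, function(f) if (length(f) > 1) f[2] else "", "")
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members deduplicated in set '", f[1], "'",
              call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  structure(sets, description = setNames(desc, nm),
            class = c("gene_set_collection", "list"))
}

#' Gene-set over-representation test
#'
#' Tests every set in a collection for over-representation in a query gene
#' list against a stated universe, with the exact hypergeometric tail
#' statistic and Benjamini-Hochberg adjustment across terms. Query ids
#' outside the universe are dropped (their count is reported in attribute
#' `n_dropped`); set members outside the universe do not contribute to the
#' term size. Terms with fewer than two universe members are skipped as
#' uninformative.
#'
#' @param query Character vector of gene ids.
#' @param collection A [read_gmt()] collection, or any named list of
#'   character vectors.
#' @param universe Character vector of background gene ids.
#' @return data.frame with one row per tested term: `term`, `k` (overlap),
#'   `K` (term size in universe), `n` (query size in universe), `N`
#'   (universe size), `p`, `q`; sorted by `p` ascending with ties broken by
#'   term name.
#' @export
enrich <- function(query, collection, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!is.list(collection) || is.null(names(collection)))
    stop("'collection' must be a named list of gene-id vectors",
         call. = FALSE)
  query <- unique(query)
  n_dropped <- sum(!query %in% universe)
  query <- query[query %in% universe]
  n <- length(query)
  N <- length(universe)
  K <- vapply(collection, function(s) sum(unique(s) %in% universe), 0L)
  keep <- K >= 2
  k <- vapply(collection[keep], function(s) sum(unique(s) %in% query), 0L)
  out <- data.frame(term = names(collection)[keep], k = unname(k),
                    K = unname(K[keep]), n = n, N = N,
                    stringsAsFactors = FALSE)
  out$p <- if (nrow(out)) hypergeom_tail(out$k, out$K, out$n, out$N)
           else numeric(0)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
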