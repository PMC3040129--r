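#' Summarize motif incidence in foreground vs background promoters
#'
#' Partitions a motif's scan hits between a foreground and a background
#' promoter set and tallies the quantities the over-representation
#' statistics need: promoters with at least one site, total site counts,
#' per-promoter site counts, and the number of scanned windows
#' (`L - W + 1` per strand scanned, summed over promoters).
#'
#' @param hits Hit table from [scan_promoters()] (optionally filtered; if it
#'   contains several motifs, `motif` selects one).
#' @param foreground,background Named character vectors of promoter
#'   sequences; ids must be disjoint and jointly cover every hit.
#' @param motif Motif name to select from `hits`; default the single motif
#'   present.
#' @param width Motif width in bases; taken from the `widths` attribute of
#'   `hits` when absent.
#' @param both_strands Were both strands scanned? Taken from `hits` when
#'   absent.
#' @return An object of class `incidence_summary`: motif name, promoter and
#'   window counts, promoters-with-hit and site totals per set, and the
#'   named per-promoter site-count vectors `fg_counts`, `bg_counts`.
#' @export
summarize_incidence <- function(hits, foreground, background, motif = NULL,
                                width = NULL, both_strands = NULL) {
  ids_fg <- names(foreground)
  ids_bg <- names(background)
  if (length(intersect(ids_fg, ids_bg)))
    stop("foreground and background promoter ids overlap", call. = FALSE)
  motifs <- unique(hits$motif)
  if (is.null(motif)) {
    if (length(motifs) > 1)
      stop("several motifs in 'hits'; pick one with 'motif'", call. = FALSE)
    motif <- if (length(motifs)) motifs else NA_character_
  } else hits <- hits[hits$motif %in% motif, , drop = FALSE]
  widths <- attr(hits, "widths")
  if (is.null(width))
    width <- if (!is.null(widths) && motif %in% names(widths))
      widths[[motif]] else unique(hits$end - hits$start)
  if (length(width) != 1 || is.na(width))
    stop("motif 'width' could not be inferred; pass it explicitly",
         call. = FALSE)
  both_strands <- both_strands %||% attr(hits, "both_strands") %||% TRUE
  unknown <- setdiff(hits$promoter_id, c(ids_fg, ids_bg))
  if (length(unknown))
    stop("hits reference unknown promoters: ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  count_in <- function(set) {
    tab <- table(factor(hits$promoter_id[hits$promoter_id %in% names(set)],
                        levels = names(set)))
    setNames(as.integer(tab), names(set))
  }
  fg_counts <- count_in(foreground)
  bg_counts <- count_in(background)
  n_strands <- if (isTRUE(both_strands)) 2L else 1L
  windows <- function(set) sum(pmax(nchar(set) - width + 1L, 0L)) * n_strands
  structure(list(motif = motif, width = width,
                 n_fg = length(foreground), n_bg = length(background),
                 fg_hit_promoters = sum(fg_counts > 0),
                 bg_hit_promoters = sum(bg_counts > 0),
                 fg_sites = sum(fg_counts), bg_sites = sum(bg_counts),
                 fg_windows = windows(foreground),
                 bg_windows = windows(background),
                 fg_counts = fg_counts, bg_counts = bg_counts),
            class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("Motif '%s': fg %d/%d promoters hit (%d sites), bg %d/%d (%d sites)\n",
              x$motif, x$fg_hit_promoters, x$n_fg, x$fg_sites,
              x$bg_hit_promoters, x$n_bg, x$bg_sites))
  invisible(x)
}

#' Gene-level (promoter-count) over-representation test
#'
#' One-sided hypergeometric tail on the number of foreground promoters with
#' at least one site, drawn from the pooled promoter universe: do
#' promoters of the regulated gene set carry the motif more often than
#' expected from the pooled incidence?
#'
#' @param s An [summarize_incidence()] summary.
#' @return A tail probability in `(0, 1]`.
#' @export
gene_level_test <- function(s) {
  stopifnot(inherits(s, "incidence_summary"))
  if (s$n_fg == 0 || s$n_bg == 0)
    stop("foreground and background must both be non-empty", call. = FALSE)
  hypergeom_tail(s$fg_hit_promoters,
                 s$fg_hit_promoters + s$bg_hit_promoters,
                 s$n_fg, s$n_fg + s$n_bg)
}

#' Site-rate (per-window) over-representation test
#'
#' One-sided exact binomial tail for the total foreground site count, with
#' the number of scanned foreground windows as trials and the background
#' per-window site rate as success probability. A background with zero
#' sites gets add-one smoothing (`(bg_sites + 1) / (bg_windows + 1)`) so
#' the test never conditions on an impossible rate.
#'
#' @param s An [summarize_incidence()] summary.
#' @return A tail probability in `(0, 1]`.
#' @export
site_rate_test <- function(s) {
  stopifnot(inherits(s, "incidence_summary"))
  if (s$fg_windows == 0) stop("no scanned foreground windows", call. = FALSE)
  if (s$bg_windows == 0) stop("no scanned background windows", call. = FALSE)
  rate <- if (s$bg_sites == 0) (s$bg_sites + 1) / (s$bg_windows + 1)
          else s$bg_sites / s$bg_windows
  rate <- min(rate, 1)
  pbinom(s$fg_sites - 1, s$fg_windows, rate, lower.tail = FALSE)
}

#' Permutation test of foreground site counts
#'
#' Compares the observed total foreground site count against the
#' distribution obtained by redrawing the foreground label set uniformly at
#' random (without replacement) from the pooled promoter universe, holding
#' the per-promoter site counts fixed. The add-one estimator
#' `p = (1 + #(permuted >= observed)) / (1 + n_perm)` never returns zero.
#'
#' @param s An [summarize_incidence()] summary, from which the foreground
#'   ids and pooled per-promoter counts are taken.
#' @param n_perm Number of permutations (at least 99). Default 999.
#' @param seed Integer seed; results are seed-reproducible.
#' @return A probability in `(0, 1]`.
#' @export
permutation_test <- function(s, n_perm = 999, seed = NULL) {
  stopifnot(inherits(s, "incidence_summary"))
  if (n_perm < 99) stop("'n_perm' must be at least 99", call. = FALSE)
  counts <- c(s$fg_counts, s$bg_counts)
  n_fg <- s$n_fg
  if (n_fg > length(counts))
    stop("foreground larger than the promoter universe", call. = FALSE)
  observed <- s$fg_sites
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i)
      sum(counts[sample.int(length(counts), n_fg)]), numeric(1))
    (1 + sum(perm >= observed)) / (1 + n_perm)
  })
}

#' Ensemble motif over-representation with cross-method consensus
#'
#' Runs, for every motif in a hit table, the three over-representation
#' statistics — gene-level hypergeometric ([gene_level_test()]), site-rate
#' binomial ([site_rate_test()]) and label permutation
#' ([permutation_test()]) — adjusts each statistic across motifs by
#' Benjamini-Hochberg (per statistic, not pooled: the three are on
#' different scales), and flags a motif as a consensus call when at least
#' `min_methods` of the three reach `q <= alpha`. This formalizes the
#' practice of trusting motifs that several independent over-representation
#' tools agree on.
#'
#' @param hits Hit table from [scan_promoters()] covering one or more
#'   motifs.
#' @param foreground,background Named character vectors of promoter
#'   sequences (disjoint ids).
#' @param models Optional list of [build_pwm()] models; used for motif
#'   widths and to include motifs with zero hits (which otherwise cannot be
#'   inferred from `hits`).
#' @param alpha Per-statistic FDR level in (0, 1). Default 0.05.
#' @param min_methods Number of agreeing statistics required for the
#'   consensus flag (1-3). Default 2.
#' @param n_perm Permutations for the permutation statistic. Default 999.
#' @param seed Integer seed for the permutation statistic.
#' @return An object of class `motif_enrichment`: a data.frame with one row
#'   per motif — incidence counts, `p_gene`, `q_gene`, `p_rate`, `q_rate`,
#'   `p_perm`, `q_perm`, `methods_flagged` (comma-separated subset of
#'   gene/rate/perm), `n_methods` and logical `consensus` — sorted by
#'   number of flagged methods (descending) then smallest q.
#' @export
motif_enrichment <- function(hits, foreground, background, models = NULL,
                             alpha = 0.05, min_methods = 2, n_perm = 999,
                             seed = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1", call. = FALSE)
  if (!min_methods %in% 1:3)
    stop("'min_methods' must be 1, 2 or 3", call. = FALSE)
  motifs <- if (!is.null(models))
    vapply(models, function(m) m$name, "") else unique(hits$motif)
  if (!length(motifs)) stop("no motifs to test", call. = FALSE)
  widths <- if (!is.null(models))
    setNames(vapply(models, function(m) m$width, 0), motifs) else
    attr(hits, "widths")
  seeds <- if (is.null(seed)) rep(list(NULL), length(motifs)) else
    as.list(seed + seq_along(motifs) - 1L)
  rows <- vector("list", length(motifs))
  for (i in seq_along(motifs)) {
    mo <- motifs[i]
    s <- summarize_incidence(hits, foreground, background, motif = mo,
                             width = if (mo %in% names(widths))
                               widths[[mo]] else NULL)
    rows[[i]] <- data.frame(
      motif = mo, fg_hit_promoters = s$fg_hit_promoters,
      bg_hit_promoters = s$bg_hit_promoters, fg_sites = s$fg_sites,
      bg_sites = s$bg_sites,
      p_gene = gene_level_test(s), p_rate = site_rate_test(s),
      p_perm = permutation_test(s, n_perm = n_perm, seed = seeds[[i]]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_gene <- bh_adjust(out$p_gene)
  out$q_rate <- bh_adjust(out$p_rate)
  out$q_perm <- bh_adjust(out$p_perm)
  flagged <- cbind(gene = out$q_gene <= alpha, rate = out$q_rate <= alpha,
                   perm = out$q_perm <= alpha)
  out$methods_flagged <- apply(flagged, 1, function(f)
    paste(colnames(flagged)[f], collapse = ","))
  out$n_methods <- rowSums(flagged)
  out$consensus <- out$n_methods >= min_methods
  min_q <- pmin(out$q_gene, out$q_rate, out$q_perm)
  out <- out[order(-out$n_methods, min_q, out$motif), ]
  rownames(out) <- NULL
  structure(out, class = c("motif_enrichment", "data.frame"),
            alpha = alpha, min_methods = min_methods, n_perm = n_perm)
}

#' @export
print.motif_enrichment <- function(x, n = 10, ...) {
  cat(sprintf(
    "Motif over-representation: %d motifs, %d consensus calls (>= %d of 3 methods at FDR %.2g)\n",
    nrow(x), sum(x$consensus), attr(x, "min_methods"), attr(x, "alpha")))
  cols <- c("motif", "fg_hit_promoters", "bg_hit_promoters", "q_gene",
            "q_rate", "q_perm", "methods_flagged", "consensus")
  print(head(format_df(as.data.frame(x)[cols]), n), row.names = FALSE)
  invisible(x)
}
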