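# Independent oracles and small fixtures shared across tests.

# Brute-force recount of the vote-counting filter straight from a long
# call table, with none of the package's matrix machinery.
brute_consensus <- function(calls, min_up, min_down, studies = NULL,
                            down_capable = NULL) {
  studies <- if (is.null(studies)) unique(calls$study_id) else studies
  down_capable <- if (is.null(down_capable)) studies else down_capable
  genes <- sort(unique(calls$gene_id))
  out <- data.frame(gene_id = genes, n_up = 0L, n_down = 0L,
                    status = "", stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    n_up <- n_down <- 0L
    for (s in studies) {
      d <- unique(calls$direction[calls$study_id == s & calls$gene_id == g])
      if (length(d) == 1 && d == "up") n_up <- n_up + 1L
      if (length(d) == 1 && d == "down") n_down <- n_down + 1L
    }
    up_ok <- n_up >= min_up
    down_ok <- n_down >= min_down
    out$n_up[i] <- n_up
    out$n_down[i] <- n_down
    out$status[i] <- if (up_ok && down_ok) "conflict" else
      if (up_ok) "consensus_up" else
      if (down_ok) "consensus_down" else "below_threshold"
  }
  out
}

# Exhaustive hypergeometric tail: fraction of all size-n subsets of an
# N-universe that overlap a fixed K-subset in at least k elements.
enum_hypergeom_tail <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Direct evaluation of the information-weighted similarity formula,
# written independently of the package internals.
naive_matsim <- function(ppm, info, word) {
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  num <- sum(info * ppm[cbind(idx, seq_along(idx))])
  den <- sum(info * apply(ppm, 2, max))
  if (den == 0) 1 else num / den
}

# Hand step-up FDR, independent of stats::p.adjust.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# The worked 2-column toy matrix used throughout the scoring tests.
toy_counts <- function() {
  matrix(c(8, 0, 2, 0, 2, 4, 2, 2), nrow = 4,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

# A sharp 8-wide motif; the default dominant count gives about 1.06 bits
# of information per column, dominant = 100 about 1.73.
sharp_motif <- function(name = "planted", width = 8, seed = 42,
                        dominant = 17) {
  set.seed(seed)
  cm <- matrix(1, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  dom <- sample.int(4, width, replace = TRUE)
  cm[cbind(dom, seq_len(width))] <- dominant
  build_pwm(cm, name = name)
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

fixture_vote_table <- function() {
  meta <- certl_studies()
  build_vote_table(certl_calls(), studies = meta$study_id,
                   down_capable = meta$study_id[meta$discloses_down])
}
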