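#' Configuration for simulating multi-study differential-expression lists
#'
#' Describes a vote-counting study design: a shared gene universe, a set of
#' independent studies, and a planted "true consensus" subset of genes that
#' each study detects with probability `p_detect` in its true direction.
#' Every non-planted gene can still be called in a random direction with
#' probability `p_false` per study, emulating study-specific false positives.
#'
#' The defaults mirror the seven-microarray-study design the package's
#' consensus machinery was built for: a universe of 1000 candidate genes,
#' 7 studies, 30 truly up- and 20 truly down-regulated genes.
#'
#' @param n_universe Number of genes in the shared universe.
#' @param n_studies Number of independent studies.
#' @param n_true_up,n_true_down Number of planted consensus genes per direction.
#' @param p_detect Probability that a planted gene is called, in its true
#'   direction, by any one study.
#' @param p_false Probability that a non-planted gene is called (direction
#'   chosen uniformly) by any one study.
#' @param seed Integer seed; identical seeds give identical simulations.
#' @return An object of class `study_sim_config`.
#' @seealso [simulate_studies()]
#' @export
study_sim_config <- function(n_universe = 1000, n_studies = 7,
                             n_true_up = 30, n_true_down = 20,
                             p_detect = 0.9, p_false = 0.005, seed = NULL) {
  for (nm in c("n_universe", "n_studies", "n_true_up", "n_true_down")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop(sprintf("'%s' must be a single non-negative integer", nm),
           call. = FALSE)
  }
  if (n_studies < 1) stop("'n_studies' must be at least 1", call. = FALSE)
  if (n_true_up + n_true_down > n_universe)
    stop("planted gene counts exceed the universe size", call. = FALSE)
  stop_if_not_scalar_prob(p_detect, "p_detect")
  stop_if_not_scalar_prob(p_false, "p_false")
  structure(list(n_universe = as.integer(n_universe),
                 n_studies = as.integer(n_studies),
                 n_true_up = as.integer(n_true_up),
                 n_true_down = as.integer(n_true_down),
                 p_detect = p_detect, p_false = p_false, seed = seed),
            class = "study_sim_config")
}

#' Simulate per-study up/down gene call lists with planted consensus genes
#'
#' Draws, for each study, the planted genes it detects (each independently
#' with probability `p_detect`, always in the planted direction) and the
#' false calls among non-planted genes (probability `p_false`, direction
#' up/down with equal probability). A gene appears at most once per study.
#'
#' @param cfg A [study_sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{calls}{data.frame of `study_id`, `gene_id`, `direction`.}
#'     \item{truth}{list with `up` and `down` character vectors of planted
#'       gene ids.}
#'     \item{universe}{character vector of all gene ids.}
#'   }
#' @examples
#' sim <- simulate_studies(study_sim_config(n_universe = 100, seed = 1))
#' head(sim$calls)
#' @export
simulate_studies <- function(cfg) {
  if (!inherits(cfg, "study_sim_config"))
    stop("'cfg' must be a study_sim_config", call. = FALSE)
  with_seed(cfg$seed, {
    universe <- sprintf("g%05d", seq_len(cfg$n_universe))
    planted <- sample(universe, cfg$n_true_up + cfg$n_true_down)
    up <- sort(planted[seq_len(cfg$n_true_up)])
    down <- sort(planted[cfg$n_true_up + seq_len(cfg$n_true_down)])
    rest <- setdiff(universe, planted)
    studies <- sprintf("study_%02d", seq_len(cfg$n_studies))
    pieces <- lapply(studies, function(sid) {
      det_up <- up[runif(length(up)) < cfg$p_detect]
      det_down <- down[runif(length(down)) < cfg$p_detect]
      fp <- rest[runif(length(rest)) < cfg$p_false]
      fp_dir <- sample(c("up", "down"), length(fp), replace = TRUE)
      ids <- c(det_up, det_down, fp)
      data.frame(
        study_id = rep(sid, length(ids)),
        gene_id = ids,
        direction = c(rep("up", length(det_up)),
                      rep("down", length(det_down)), fp_dir),
        stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, pieces)
    rownames(calls) <- NULL
    list(calls = calls, truth = list(up = up, down = down),
         universe = universe)
  })
}

#' Configuration for simulating promoter sets with planted motif sites
#'
#' Foreground and background promoter sequences are drawn from a background
#' Markov model (order 0 or 1); motif instances sampled from a probability
#' matrix are then planted at Poisson-distributed per-promoter rates,
#' `lambda_fg` in the foreground and `lambda_bg` in the background, each on
#' the reverse strand with probability `p_reverse`. Planted sites never cross
#' a promoter boundary and never overlap one another within a promoter.
#'
#' Defaults emulate a motif-discovery contrast of a regulated gene cluster
#' against a larger reference promoter universe: 50 foreground vs 200
#' background promoters of 1000 bases, uniform order-0 background.
#'
#' @param planted_motif A [build_pwm()] model whose probability matrix the
#'   planted words are sampled from.
#' @param n_foreground,n_background Promoter counts.
#' @param length Bases per promoter; must be at least the motif width.
#' @param background_order Markov order of the background model, 0 or 1.
#' @param base_freqs Length-4 base frequencies (A, C, G, T) for the order-0
#'   model and the initial state of the order-1 model.
#' @param transition Optional 4x4 row-stochastic transition matrix
#'   (required when `background_order = 1`).
#' @param lambda_fg,lambda_bg Mean planted sites per foreground / background
#'   promoter (Poisson).
#' @param p_reverse Probability a planted site is written as the reverse
#'   complement of the sampled word.
#' @param seed Integer seed.
#' @return An object of class `promoter_sim_config`.
#' @seealso [simulate_promoters()]
#' @export
promoter_sim_config <- function(planted_motif, n_foreground = 50,
                                n_background = 200, length = 1000,
                                background_order = 0,
                                base_freqs = rep(0.25, 4),
                                transition = NULL,
                                lambda_fg = 2, lambda_bg = 0.1,
                                p_reverse = 0.5, seed = NULL) {
  if (!inherits(planted_motif, "pwm_model"))
    stop("'planted_motif' must be a pwm_model", call. = FALSE)
  if (length < planted_motif$width)
    stop("promoter 'length' is smaller than the motif width", call. = FALSE)
  if (n_foreground < 1 || n_background < 0)
    stop("invalid promoter counts", call. = FALSE)
  if (lambda_fg < 0 || lambda_bg < 0)
    stop("'lambda_fg' and 'lambda_bg' must be non-negative", call. = FALSE)
  stop_if_not_scalar_prob(p_reverse, "p_reverse")
  if (!background_order %in% c(0, 1))
    stop("'background_order' must be 0 or 1", call. = FALSE)
  if (length(base_freqs) != 4 || any(base_freqs < 0) || sum(base_freqs) <= 0)
    stop("'base_freqs' must be 4 non-negative frequencies", call. = FALSE)
  base_freqs <- base_freqs / sum(base_freqs)
  if (background_order == 1) {
    if (is.null(transition) || !is.matrix(transition) ||
        !all(dim(transition) == c(4, 4)) || any(transition < 0))
      stop("order-1 background needs a 4x4 non-negative 'transition' matrix",
           call. = FALSE)
    transition <- transition / rowSums(transition)
  }
  structure(list(planted_motif = planted_motif,
                 n_foreground = as.integer(n_foreground),
                 n_background = as.integer(n_background),
                 length = as.integer(length),
                 background_order = background_order,
                 base_freqs = base_freqs, transition = transition,
                 lambda_fg = lambda_fg, lambda_bg = lambda_bg,
                 p_reverse = p_reverse, seed = seed),
            class = "promoter_sim_config")
}

# sample n background sequences of given length as an integer code matrix
sample_background <- function(n, len, cfg) {
  if (cfg$background_order == 0) {
    matrix(sample.int(4L, n * len, replace = TRUE, prob = cfg$base_freqs),
           nrow = n)
  } else {
    m <- matrix(0L, n, len)
    m[, 1] <- sample.int(4L, n, replace = TRUE, prob = cfg$base_freqs)
    cum <- t(apply(cfg$transition, 1, cumsum))
    for (j in seq_len(len - 1L) + 1L) {
      u <- runif(n)
      prev <- m[, j - 1L]
      m[, j] <- 1L + (u > cum[prev, 1]) + (u > cum[prev, 2]) +
        (u > cum[prev, 3])
    }
    m
  }
}

#' Simulate foreground and background promoters with planted motif sites
#'
#' @param cfg A [promoter_sim_config()].
#' @return A list with components:
#'   \describe{
#'     \item{foreground, background}{named character vectors of promoter
#'       sequences (`fg_0001...`, `bg_0001...`).}
#'     \item{truth}{data.frame of planted sites: `promoter_id`, `offset`
#'       (0-based), `strand`, and `word` (the motif-strand word sampled from
#'       the probability matrix; reverse-strand sites are written into the
#'       sequence as its reverse complement).}
#'   }
#' @examples
#' m <- build_pwm(matrix(c(9, 0, 0, 0, 0, 9, 0, 0), 4), name = "toy")
#' sim <- simulate_promoters(promoter_sim_config(m, n_foreground = 3,
#'                                               n_background = 3,
#'                                               length = 50, seed = 1))
#' sim$truth
#' @export
simulate_promoters <- function(cfg) {
  if (!inherits(cfg, "promoter_sim_config"))
    stop("'cfg' must be a promoter_sim_config", call. = FALSE)
  model <- cfg$planted_motif
  W <- model$width
  with_seed(cfg$seed, {
    ids <- c(sprintf("fg_%04d", seq_len(cfg$n_foreground)),
             if (cfg$n_background > 0)
               sprintf("bg_%04d", seq_len(cfg$n_background)))
    n <- length(ids)
    m <- sample_background(n, cfg$length, cfg)
    lambda <- rep(c(cfg$lambda_fg, cfg$lambda_bg),
                  c(cfg$n_foreground, cfg$n_background))
    n_sites <- rpois(n, lambda)
    truth <- vector("list", n)
    max_off <- cfg$length - W  # 0-based offsets in 0..max_off
    for (i in which(n_sites > 0)) {
      offs <- integer(0)
      for (s in seq_len(n_sites[i])) {
        placed <- FALSE
        for (try in seq_len(10000L)) {
          o <- sample.int(max_off + 1L, 1L) - 1L
          if (!any(abs(o - offs) < W)) { placed <- TRUE; break }
        }
        if (!placed)
          stop("could not place a non-overlapping site; promoter too crowded",
               call. = FALSE)
        offs <- c(offs, o)
      }
      words <- vapply(seq_along(offs), function(s)
        paste(DNA_BASES[vapply(seq_len(W), function(j)
          sample.int(4L, 1L, prob = model$ppm[, j]), integer(1))],
          collapse = ""), character(1))
      strands <- ifelse(runif(length(offs)) < cfg$p_reverse, "-", "+")
      for (s in seq_along(offs)) {
        w <- if (strands[s] == "-") reverse_complement(words[s]) else words[s]
        m[i, offs[s] + seq_len(W)] <- match(strsplit(w, "")[[1]], DNA_BASES)
      }
      truth[[i]] <- data.frame(promoter_id = ids[i], offset = offs,
                               strand = strands, word = words,
                               stringsAsFactors = FALSE)
    }
    seqs <- setNames(
      vapply(seq_len(n),
             function(i) paste(DNA_BASES[m[i, ]], collapse = ""),
             character(1)),
      ids)
    truth <- if (any(n_sites > 0)) do.call(rbind, truth[n_sites > 0]) else
      data.frame(promoter_id = character(), offset = integer(),
                 strand = character(), word = character(),
                 stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(foreground = seqs[seq_len(cfg$n_foreground)],
         background = seqs[cfg$n_foreground + seq_len(cfg$n_background)],
         truth = truth)
  })
}

#' Generate random decoy position weight models
#'
#' Draws sharp random count matrices (one dominant base per column) useful as
#' negative-control motifs in over-representation analyses. A random matrix
#' can, by chance, resemble the motif it is meant to contrast with — often in
#' a shifted or reverse-complement register — and would then fire on that
#' motif's planted sites, making it a partial positive rather than a
#' negative control. When `avoid` is given, candidate decoys whose consensus
#' word aligns to the avoided model's consensus (any shift with at least
#' five overlapping positions, either strand) with 75% or more matching
#' bases are rejected and resampled.
#'
#' @param n Number of decoys.
#' @param width Motif width.
#' @param counts Total count per column.
#' @param dominance Fraction of each column's counts given to its dominant
#'   base; the rest is spread over the other three bases.
#' @param prefix Name prefix (`<prefix>_01`, ...).
#' @param avoid Optional [build_pwm()] model the decoys must not resemble.
#' @param seed Integer seed.
#' @return A list of [build_pwm()] models.
#' @export
random_decoy_motifs <- function(n, width = 8, counts = 20, dominance = 0.85,
                                prefix = "decoy", avoid = NULL,
                                seed = NULL) {
  stop_if_not_scalar_prob(dominance, "dominance")
  avoid_word <- if (!is.null(avoid)) consensus_word(avoid)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in seq_len(1000L)) {
        cm <- matrix(0, 4, width, dimnames = list(DNA_BASES, NULL))
        dom <- sample.int(4L, width, replace = TRUE)
        for (j in seq_len(width)) {
          cm[dom[j], j] <- round(counts * dominance)
          cm[-dom[j], j] <- round(counts * (1 - dominance) / 3)
        }
        word <- paste(DNA_BASES[dom], collapse = "")
        if (is.null(avoid) || !words_alike(word, avoid_word))
          return(build_pwm(cm, name = sprintf("%s_%02d", prefix, i)))
      }
      stop("could not draw a decoy dissimilar from 'avoid'", call. = FALSE)
    })
  })
}

# do two words align (any shift with >= 5 overlapping positions, either
# strand) with at least 75% identity?
words_alike <- function(a, b, min_overlap = 5, min_identity = 0.75) {
  xa <- strsplit(a, "")[[1]]
  for (bb in c(b, reverse_complement(b))) {
    xb <- strsplit(bb, "")[[1]]
    for (shift in seq(-(length(xb) - min_overlap),
                      length(xa) - min_overlap)) {
      ia <- max(1, 1 + shift):min(length(xa), length(xb) + shift)
      ib <- ia - shift
      o <- length(ia)
      if (o >= min_overlap && sum(xa[ia] == xb[ib]) >= min_identity * o)
        return(TRUE)
    }
  }
  FALSE
}
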