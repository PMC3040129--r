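# small synthetic scan setup reused across the incidence tests
incidence_fixture <- function(seed = 1, n_fg = 10, n_bg = 10, len = 60,
                              lambda_fg = 1, lambda_bg = 0.2) {
  m <- sharp_motif()
  sim <- simulate_promoters(promoter_sim_config(
    m, n_foreground = n_fg, n_background = n_bg, length = len,
    lambda_fg = lambda_fg, lambda_bg = lambda_bg, seed = seed))
  hits <- scan_promoters(c(sim$foreground, sim$background), m,
                         threshold = 0.85)
  list(model = m, sim = sim, hits = hits)
}

test_that("incidence summaries recount the hit table exactly", {
  fx <- incidence_fixture()
  s <- summarize_incidence(fx$hits, fx$sim$foreground, fx$sim$background)
  h <- fx$hits
  fg_ids <- names(fx$sim$foreground)
  expect_equal(s$fg_sites, sum(h$promoter_id %in% fg_ids))
  expect_equal(s$bg_sites, sum(!h$promoter_id %in% fg_ids))
  expect_equal(s$fg_hit_promoters,
               length(unique(h$promoter_id[h$promoter_id %in% fg_ids])))
  expect_equal(s$bg_hit_promoters,
               length(unique(h$promoter_id[!h$promoter_id %in% fg_ids])))
  # windows: (L - W + 1) per promoter and strand
  expect_equal(s$fg_windows, 10 * (60 - 8 + 1) * 2)
  expect_equal(s$bg_windows, 10 * (60 - 8 + 1) * 2)
  expect_equal(sum(s$fg_counts), s$fg_sites)
})

test_that("an empty hit table gives an all-zero summary", {
  fx <- incidence_fixture()
  none <- fx$hits[0, ]
  s <- summarize_incidence(none, fx$sim$foreground, fx$sim$background,
                           motif = "planted", width = 8)
  expect_equal(s$fg_sites + s$bg_sites, 0)
  expect_equal(s$fg_hit_promoters + s$bg_hit_promoters, 0)
})

test_that("one promoter with three hits counts one promoter, three sites", {
  hits <- data.frame(promoter_id = "fg_1", start = c(0, 10, 20),
                     end = c(8, 18, 28), strand = "+", score = 1,
                     motif = "m", method = "matsim")
  s <- summarize_incidence(hits, c(fg_1 = strrep("A", 60)),
                           c(bg_1 = strrep("A", 60)), width = 8)
  expect_equal(s$fg_hit_promoters, 1)
  expect_equal(s$fg_sites, 3)
  expect_equal(s$bg_sites, 0)
})

test_that("unknown promoters and overlapping sets are errors", {
  hits <- data.frame(promoter_id = "ghost", start = 0, end = 8,
                     strand = "+", score = 1, motif = "m",
                     method = "matsim")
  expect_error(summarize_incidence(hits, c(a = "ACGT"), c(b = "ACGT"),
                                   width = 4), "unknown promoters")
  expect_error(summarize_incidence(hits[0, ], c(a = "ACGT"),
                                   c(a = "ACGT"), width = 4), "overlap")
})

test_that("gene-level test equals closed forms and the enumeration oracle", {
  mk <- function(fg_hit, bg_hit, n_fg, n_bg) {
    structure(list(motif = "m", width = 8, n_fg = n_fg, n_bg = n_bg,
                   fg_hit_promoters = fg_hit, bg_hit_promoters = bg_hit,
                   fg_sites = fg_hit, bg_sites = bg_hit,
                   fg_windows = n_fg * 100, bg_windows = n_bg * 100,
                   fg_counts = setNames(rep(1, fg_hit), seq_len(fg_hit)),
                   bg_counts = numeric(0)),
              class = "incidence_summary")
  }
  # all 10 foreground promoters hit, none of 10 background ones
  expect_equal(gene_level_test(mk(10, 0, 10, 10)), 1 / choose(20, 10))
  # equal incidence proportions: no enrichment signal
  expect_gte(gene_level_test(mk(5, 5, 10, 10)), 0.5)
  # pooled 20-promoter universes against exhaustive enumeration
  for (case in list(c(4, 3, 8, 12), c(2, 6, 5, 15), c(7, 2, 10, 10))) {
    s <- mk(case[1], case[2], case[3], case[4])
    expect_equal(gene_level_test(s),
                 enum_hypergeom_tail(case[1], case[1] + case[2], case[3],
                                     case[3] + case[4]))
  }
})

test_that("site-rate test equals the exact binomial tail", {
  s <- structure(list(motif = "m", width = 8, n_fg = 10, n_bg = 10,
                      fg_hit_promoters = 5, bg_hit_promoters = 5,
                      fg_sites = 20, bg_sites = 10,
                      fg_windows = 10000, bg_windows = 10000,
                      fg_counts = numeric(0), bg_counts = numeric(0)),
                 class = "incidence_summary")
  # independent summation oracle for P(X >= 20), X ~ Binomial(1e4, 1e-3)
  oracle <- sum(vapply(20:10000, function(x)
    dbinom(x, 10000, 0.001), numeric(1)))
  expect_equal(site_rate_test(s), oracle, tolerance = 1e-12)

  s$fg_sites <- 10
  expect_gt(site_rate_test(s), 0.2)  # matched rates: no signal

  s$bg_sites <- 0  # add-one smoothing path
  p <- site_rate_test(s)
  expect_lt(p, 1)
  expect_equal(p, pbinom(9, 10000, 1 / 10001, lower.tail = FALSE))

  s$fg_windows <- 0
  expect_error(site_rate_test(s), "foreground windows")
})

test_that("permutation test handles its degenerate limits", {
  fx <- incidence_fixture(lambda_fg = 0, lambda_bg = 0, seed = 3)
  s <- summarize_incidence(fx$hits[fx$hits$score >= 2, ],  # no hits at all
                           fx$sim$foreground, fx$sim$background,
                           motif = "planted", width = 8)
  expect_equal(permutation_test(s, n_perm = 99, seed = 1), 1)
  # foreground equal to the whole universe: every permutation is identical
  fx2 <- incidence_fixture(n_bg = 0, seed = 4)
  s2 <- summarize_incidence(fx2$hits, fx2$sim$foreground,
                            setNames(character(0), character(0)))
  expect_equal(permutation_test(s2, n_perm = 99, seed = 1), 1)
  expect_error(permutation_test(s2, n_perm = 10), "at least 99")
})

test_that("permutation p is seed-stable and label-invariant", {
  fx <- incidence_fixture(seed = 5)
  s <- summarize_incidence(fx$hits, fx$sim$foreground, fx$sim$background)
  expect_identical(permutation_test(s, n_perm = 199, seed = 9),
                   permutation_test(s, n_perm = 199, seed = 9))
  # relabel every promoter: same counts, same p
  relabel <- function(x, prefix) setNames(x, paste0(prefix, seq_along(x)))
  hits2 <- fx$hits
  map <- setNames(c(paste0("x", seq_along(fx$sim$foreground)),
                    paste0("y", seq_along(fx$sim$background))),
                  c(names(fx$sim$foreground), names(fx$sim$background)))
  hits2$promoter_id <- unname(map[hits2$promoter_id])
  s2 <- summarize_incidence(hits2, relabel(fx$sim$foreground, "x"),
                            relabel(fx$sim$background, "y"), width = 8)
  expect_identical(permutation_test(s, n_perm = 199, seed = 9),
                   permutation_test(s2, n_perm = 199, seed = 9))
})

test_that("a strongly planted motif earns a small permutation p", {
  fx <- incidence_fixture(seed = 6, n_fg = 30, n_bg = 120, len = 300,
                          lambda_fg = 2, lambda_bg = 0.1)
  s <- summarize_incidence(fx$hits, fx$sim$foreground, fx$sim$background)
  expect_lte(permutation_test(s, n_perm = 999, seed = 10), 0.01)
})

test_that("cross-method consensus flags and nests as expected", {
  fx <- incidence_fixture(seed = 7, n_fg = 30, n_bg = 120, len = 300,
                          lambda_fg = 2, lambda_bg = 0.1)
  decoys <- random_decoy_motifs(5, seed = 70)
  models <- c(list(fx$model), decoys)
  hits <- scan_promoters(c(fx$sim$foreground, fx$sim$background), models,
                         threshold = 0.85)
  res <- motif_enrichment(hits, fx$sim$foreground, fx$sim$background,
                          models = models, seed = 11)
  planted <- res[res$motif == "planted", ]
  expect_true(planted$consensus)
  expect_equal(planted$n_methods, 3)
  # consensus sets nest as the agreement requirement relaxes
  sets <- lapply(1:3, function(k)
    motif_enrichment(hits, fx$sim$foreground, fx$sim$background,
                     models = models, min_methods = k, seed = 11))
  flagged <- lapply(sets, function(r) r$motif[r$consensus])
  expect_true(all(flagged[[3]] %in% flagged[[2]]))
  expect_true(all(flagged[[2]] %in% flagged[[1]]))
  expect_error(motif_enrichment(hits, fx$sim$foreground,
                                fx$sim$background, alpha = 1.2),
               "alpha")
})
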