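toy_mapping <- data.frame(
  source_id = c("p1", "p2", "p3", "s1", "s2"),
  namespace = c("probe", "probe", "probe", "symbol", "symbol"),
  canonical_id = c("Hs.1", "Hs.1", "Hs.2", "Hs.2", "Hs.3"),
  symbol = c("GENE1", "GENE1", "GENE2", "GENE2", "GENE3"),
  stringsAsFactors = FALSE)

test_that("harmonize collapses concordant probes and drops unmapped ids", {
  raw <- data.frame(
    study_id = "st1",
    source_id = c("p1", "p2", "p3", "nope"),
    namespace = c("probe", "probe", "probe", "probe"),
    direction = c("up", "up", "down", "up"),
    stringsAsFactors = FALSE)
  h <- harmonize(raw, toy_mapping)
  expect_equal(nrow(h$calls), 2)  # p1+p2 collapse to one Hs.1 up call
  expect_setequal(h$calls$gene_id, c("Hs.1", "Hs.2"))
  expect_equal(h$report$n_unmapped, 1)
  expect_equal(h$report$unmapped_ids, "nope")
})

test_that("five records across two namespaces harmonize to three calls", {
  raw <- data.frame(
    study_id = "st1",
    source_id = c("p1", "p2", "p3", "s1", "s2"),
    namespace = c("probe", "probe", "probe", "symbol", "symbol"),
    direction = c("up", "up", "down", "down", "up"),
    stringsAsFactors = FALSE)
  h <- harmonize(raw, toy_mapping)
  # p1/p2 -> Hs.1 up; p3 and s1 -> Hs.2 down (concordant); s2 -> Hs.3 up
  expect_equal(nrow(h$calls), 3)
  expect_equal(nrow(h$report$contradictions), 0)
})

test_that("intra-study contradictions are excluded and reported", {
  raw <- data.frame(
    study_id = "st1",
    source_id = c("p1", "p2"), namespace = "probe",
    direction = c("up", "up"), stringsAsFactors = FALSE)
  raw$direction[2] <- "down"  # p1 and p2 both map to Hs.1
  h <- harmonize(raw, toy_mapping)
  expect_equal(nrow(h$calls), 0)
  expect_equal(h$report$contradictions,
               data.frame(study_id = "st1", gene_id = "Hs.1",
                          stringsAsFactors = FALSE))
})

test_that("ambiguous mapping rows are an error", {
  bad <- rbind(toy_mapping,
               data.frame(source_id = "p1", namespace = "probe",
                          canonical_id = "Hs.99", symbol = "OTHER"))
  expect_error(harmonize(data.frame(study_id = "s", source_id = "p1",
                                    namespace = "probe", direction = "up"),
                         bad),
               "ambiguous")
})

test_that("the vote table knows its per-direction electorate", {
  calls <- data.frame(study_id = c("a", "b"), gene_id = c("g1", "g1"),
                      direction = c("up", "up"))
  vt <- build_vote_table(calls, studies = letters[1:7],
                         down_capable = letters[1:6])
  expect_equal(vt$n_up_capable, 7)
  expect_equal(vt$n_down_capable, 6)
  expect_error(build_vote_table(calls, studies = c("a", "a", "b")),
               "duplicate")
  expect_error(
    build_vote_table(data.frame(study_id = "g", gene_id = "x",
                                direction = "down"),
                     studies = c("g"), down_capable = character(0)),
    "not down-capable")
})

test_that("a single study gives every called gene support one", {
  calls <- data.frame(study_id = "only", gene_id = c("g1", "g2"),
                      direction = c("up", "down"))
  vt <- build_vote_table(calls)
  res <- apply_consensus_filter(vt, min_up = 1, min_down = 1)
  expect_equal(res$n_up[res$gene_id == "g1"], 1)
  expect_equal(res$n_down[res$gene_id == "g2"], 1)
})

test_that("vote-table cells equal brute-force set membership", {
  set.seed(9)
  calls <- do.call(rbind, lapply(c("s1", "s2", "s3"), function(sid) {
    genes <- sample(sprintf("g%02d", 1:12), 8)
    data.frame(study_id = sid, gene_id = genes,
               direction = sample(c("up", "down"), 8, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  vt <- build_vote_table(calls)
  for (g in rownames(vt$matrix)) for (s in vt$studies) {
    expected <- calls$direction[calls$gene_id == g & calls$study_id == s]
    got <- vt$matrix[g, s]
    if (length(expected)) expect_identical(got, expected)
    else expect_true(is.na(got))
  }
})

test_that("a gene meeting both thresholds is a conflict, in neither list", {
  calls <- rbind(
    data.frame(study_id = sprintf("u%d", 1:4), gene_id = "both",
               direction = "up"),
    data.frame(study_id = sprintf("d%d", 1:3), gene_id = "both",
               direction = "down"))
  vt <- build_vote_table(calls)
  res <- apply_consensus_filter(vt, min_up = 4, min_down = 3)
  expect_equal(res$status, "conflict")
  expect_equal(nrow(consensus_genes(res, "up")), 0)
  expect_equal(nrow(consensus_genes(res, "down")), 0)
})

test_that("thresholds beyond the electorate are a configuration error", {
  calls <- data.frame(study_id = c("a", "b"), gene_id = "g",
                      direction = "up")
  vt <- build_vote_table(calls)
  expect_error(apply_consensus_filter(vt, min_up = 3), "up-capable")
  expect_error(apply_consensus_filter(vt, min_up = 0), "at least 1")
})

test_that("the filter equals a brute-force recount on small universes", {
  for (seed in 1:25) {
    set.seed(seed)
    n_studies <- sample(3:7, 1)
    studies <- sprintf("s%d", seq_len(n_studies))
    calls <- do.call(rbind, lapply(studies, function(sid) {
      n <- sample(5:25, 1)
      genes <- sample(sprintf("g%02d", 1:50), n)
      data.frame(study_id = sid, gene_id = genes,
                 direction = sample(c("up", "down"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    min_up <- sample(1:3, 1); min_down <- sample(1:3, 1)
    res <- apply_consensus_filter(build_vote_table(calls, studies),
                                  min_up, min_down)
    oracle <- brute_consensus(calls, min_up, min_down, studies)
    merged <- merge(as.data.frame(res), oracle, by = "gene_id")
    expect_equal(nrow(merged), nrow(oracle))
    expect_equal(merged$n_up.x, merged$n_up.y)
    expect_equal(merged$n_down.x, merged$n_down.y)
    expect_equal(merged$status.x, merged$status.y)
  }
})

test_that("raising the up-threshold never enlarges the consensus-up list", {
  sim <- simulate_studies(study_sim_config(n_universe = 300, n_true_up = 20,
                                           n_true_down = 10, p_detect = 0.7,
                                           p_false = 0.02, seed = 31))
  vt <- build_vote_table(sim$calls,
                         studies = sprintf("study_%02d", 1:7))
  prev <- NULL
  for (thr in 1:7) {
    cur <- consensus_genes(apply_consensus_filter(vt, min_up = thr,
                                                  min_down = 3), "up")
    if (!is.null(prev)) expect_true(all(cur$gene_id %in% prev))
    prev <- cur$gene_id
  }
})

test_that("study order never changes consensus entries", {
  sim <- simulate_studies(study_sim_config(n_universe = 100, n_true_up = 10,
                                           n_true_down = 5, p_detect = 0.8,
                                           p_false = 0.05, seed = 13))
  studies <- sprintf("study_%02d", 1:7)
  res1 <- apply_consensus_filter(build_vote_table(sim$calls, studies))
  set.seed(1)
  shuffled <- sim$calls[sample(nrow(sim$calls)), ]
  res2 <- apply_consensus_filter(build_vote_table(shuffled, rev(studies)))
  expect_equal(as.data.frame(res1), as.data.frame(res2))
})

test_that("defaults recover planted genes under realistic noise", {
  # detection 0.9, false-call 0.005: recovery should be near-complete with
  # almost no false consensus genes
  recov <- false_pos <- numeric(100)
  for (seed in 1:100) {
    sim <- simulate_studies(study_sim_config(
      n_universe = 1000, n_studies = 7, n_true_up = 30, n_true_down = 20,
      p_detect = 0.9, p_false = 0.005, seed = seed))
    res <- apply_consensus_filter(
      build_vote_table(sim$calls, studies = sprintf("study_%02d", 1:7)))
    up <- consensus_genes(res, "up")$gene_id
    down <- consensus_genes(res, "down")$gene_id
    recov[seed] <- (sum(sim$truth$up %in% up) +
                      sum(sim$truth$down %in% down)) / 50
    false_pos[seed] <- sum(!up %in% sim$truth$up) +
      sum(!down %in% sim$truth$down)
  }
  expect_gte(mean(recov), 0.9)
  expect_lte(mean(false_pos), 1)
})

test_that("the packaged direction-call fixture is intact", {
  calls <- certl_calls()
  expect_setequal(names(calls),
                  c("study_id", "gene_id", "symbol", "direction"))
  expect_equal(length(unique(calls$gene_id)), 61)
  expect_equal(length(unique(calls$gene_id[calls$direction == "up"])), 40)
  expect_equal(length(unique(calls$gene_id[calls$direction == "down"])), 21)
  # the one study that discloses no down-regulated transcripts never
  # contributes a down call
  meta <- certl_studies()
  not_capable <- meta$study_id[!meta$discloses_down]
  expect_equal(length(not_capable), 1)
  expect_false(any(calls$study_id == not_capable &
                     calls$direction == "down"))
})
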