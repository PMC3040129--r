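#' Run the analysis pipeline from a configuration
#'
#' Chains the package's stages — study simulation, consensus voting,
#' gene-set annotation, promoter scanning and motif over-representation —
#' according to a single structured configuration (a YAML file or an
#' equivalent nested list). A stage runs when its block is present. All
#' referenced input files are checked before any output is written, so a
#' missing input aborts the run without partial results. Every output file
#' carries a comment header with the package version and seed, and a
#' provenance manifest (`manifest.yaml`) records the version, seed, input
#' file digests and per-stage row counts.
#'
#' Configuration blocks (all optional, all paths relative to the working
#' directory):
#' \describe{
#'   \item{`simulate_studies`}{fields of [study_sim_config()].}
#'   \item{`simulate_promoters`}{fields of [promoter_sim_config()] plus
#'     `pfm` (path of the planted motif matrix).}
#'   \item{`consensus`}{`studies` (paths of study-call TSVs, or the string
#'     `"packaged"` for the bundled receptivity tables), optional `mapping`
#'     path, optional `down_capable` study ids, `min_up`, `min_down`.}
#'   \item{`annotate`}{`gmt` path, `direction` (`"up"`/`"down"`; default
#'     up), optional `universe` path (one id per line; default: all genes
#'     in the study calls).}
#'   \item{`scan`}{`fasta`, `pfm`, `method`, `threshold`, `both_strands`.}
#'   \item{`enrich`}{`fg_fasta`, `bg_fasta`, `pfm`, `method`, `threshold`,
#'     `alpha`, `min_methods`, `n_perm`.}
#' }
#'
#' @param config Path to a YAML file, or a nested list with the same
#'   structure.
#' @param out_dir Output directory (created if needed); overrides the
#'   config's `out` field.
#' @param seed Integer seed; overrides the config's `seed` field.
#' @return Invisibly, a list with `status` (0 on success) and the
#'   `manifest` list.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    yaml::read_yaml(config)
  } else config
  out_dir <- out_dir %||% cfg$out %||% "."
  seed <- seed %||% cfg$seed
  stages <- intersect(c("simulate_studies", "simulate_promoters",
                        "consensus", "annotate", "scan", "enrich"),
                      names(cfg))
  if (!length(stages)) stop("no stages enabled in config", call. = FALSE)

  # collect and verify every referenced input before touching outputs
  inputs <- character()
  add_input <- function(p) inputs <<- c(inputs, p)
  cns <- cfg$consensus
  packaged <- !is.null(cns) && identical(cns$studies, "packaged")
  if (!is.null(cns) && !packaged) add_input(unlist(cns$studies))
  if (!is.null(cns$mapping)) add_input(cns$mapping)
  if (!is.null(cfg$annotate)) add_input(c(cfg$annotate$gmt,
                                          cfg$annotate$universe))
  if (!is.null(cfg$scan)) add_input(c(cfg$scan$fasta, cfg$scan$pfm))
  if (!is.null(cfg$enrich)) add_input(c(cfg$enrich$fg_fasta,
                                        cfg$enrich$bg_fasta,
                                        cfg$enrich$pfm))
  if (!is.null(cfg$simulate_promoters$pfm))
    add_input(cfg$simulate_promoters$pfm)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "certl",
                   version = as.character(packageVersion("certl")),
                   seed = if (is.null(seed)) NA else as.integer(seed),
                   inputs = as.list(setNames(unname(md5sum(inputs)),
                                             inputs)),
                   stages = list())
  note <- function(stage, counts) {
    manifest$stages[[stage]] <<- counts
    message(sprintf("[certl] %s: %s", stage,
                    paste(names(counts), unlist(counts), sep = "=",
                          collapse = ", ")))
  }
  hdr <- output_header(seed)
  calls <- NULL

  if ("simulate_studies" %in% stages) {
    p <- cfg$simulate_studies
    sim <- simulate_studies(study_sim_config(
      n_universe = p$n_universe %||% 1000, n_studies = p$n_studies %||% 7,
      n_true_up = p$n_true_up %||% 30, n_true_down = p$n_true_down %||% 20,
      p_detect = p$p_detect %||% 0.9, p_false = p$p_false %||% 0.005,
      seed = seed))
    write_tsv(sim$calls, file.path(out_dir, "simulated_studies.tsv"), hdr)
    truth <- data.frame(gene_id = c(sim$truth$up, sim$truth$down),
                        direction = rep(c("up", "down"),
                                        c(length(sim$truth$up),
                                          length(sim$truth$down))))
    write_tsv(truth, file.path(out_dir, "simulated_truth.tsv"), hdr)
    calls <- sim$calls
    note("simulate_studies", list(calls = nrow(sim$calls),
                                  planted = nrow(truth)))
  }

  if ("simulate_promoters" %in% stages) {
    p <- cfg$simulate_promoters
    motif <- read_pfm(p$pfm)[[1]]
    sim <- simulate_promoters(promoter_sim_config(
      motif, n_foreground = p$n_foreground %||% 50,
      n_background = p$n_background %||% 200, length = p$length %||% 1000,
      lambda_fg = p$lambda_fg %||% 2, lambda_bg = p$lambda_bg %||% 0.1,
      p_reverse = p$p_reverse %||% 0.5, seed = seed))
    write_fasta(sim$foreground, file.path(out_dir, "foreground.fa"))
    write_fasta(sim$background, file.path(out_dir, "background.fa"))
    write_tsv(sim$truth, file.path(out_dir, "planted_sites.tsv"), hdr)
    note("simulate_promoters",
         list(foreground = length(sim$foreground),
              background = length(sim$background),
              planted_sites = nrow(sim$truth)))
  }

  if ("consensus" %in% stages) {
    p <- cns
    if (packaged) {
      calls <- certl_calls()
      meta <- certl_studies()
      studies <- meta$study_id
      down_capable <- p$down_capable %||%
        meta$study_id[meta$discloses_down]
    } else {
      calls <- read_study_calls(unlist(p$studies))
      if (!is.null(p$mapping))
        calls <- harmonize(calls, read_id_mapping(p$mapping))$calls
      studies <- unique(calls$study_id)
      down_capable <- p$down_capable %||% studies
    }
    vt <- build_vote_table(calls, studies = studies,
                           down_capable = down_capable)
    res <- apply_consensus_filter(vt, min_up = p$min_up %||% 4,
                                  min_down = p$min_down %||% 3)
    write_tsv(as.data.frame(res), file.path(out_dir, "consensus.tsv"), hdr)
    tab <- table(res$status)
    n_up <- sum(res$status == "consensus_up")
    n_down <- sum(res$status == "consensus_down")
    note("consensus", list(genes = nrow(res), consensus_up = n_up,
                           consensus_down = n_down,
                           consensus_total = n_up + n_down,
                           conflict = sum(res$status == "conflict")))
    manifest$consensus <- res
  }

  if ("annotate" %in% stages) {
    p <- cfg$annotate
    if (is.null(manifest$consensus))
      stop("'annotate' needs the consensus stage", call. = FALSE)
    gmt <- read_gmt(p$gmt)
    universe <- if (!is.null(p$universe))
      readLines(p$universe, warn = FALSE) else unique(calls$gene_id)
    query <- consensus_genes(manifest$consensus,
                             p$direction %||% "up")$gene_id
    res <- enrich(query, gmt, universe)
    write_tsv(res, file.path(out_dir, "annotation.tsv"), hdr)
    note("annotate", list(terms = nrow(res),
                          significant = sum(res$q <= (p$alpha %||% 0.05))))
  }

  hits <- NULL
  if ("scan" %in% stages) {
    p <- cfg$scan
    proms <- read_fasta(p$fasta)
    models <- read_pfm(p$pfm)
    hits <- scan_promoters(proms, models,
                           method = p$method %||% "matsim",
                           threshold = p$threshold %||% 0.85,
                           both_strands = p$both_strands %||% TRUE)
    write_bed(hits, file.path(out_dir, "hits.bed"), seed)
    note("scan", list(motifs = length(models), hits = nrow(hits)))
  }

  if ("enrich" %in% stages) {
    p <- cfg$enrich
    fg <- read_fasta(p$fg_fasta)
    bg <- read_fasta(p$bg_fasta)
    models <- read_pfm(p$pfm)
    all_hits <- scan_promoters(c(fg, bg), models,
                               method = p$method %||% "matsim",
                               threshold = p$threshold %||% 0.85)
    res <- motif_enrichment(all_hits, fg, bg, models = models,
                            alpha = p$alpha %||% 0.05,
                            min_methods = p$min_methods %||% 2,
                            n_perm = p$n_perm %||% 999, seed = seed)
    write_tsv(as.data.frame(res), file.path(out_dir, "motif_enrichment.tsv"),
              hdr)
    note("enrich", list(motifs = nrow(res),
                        consensus = sum(res$consensus)))
  }

  manifest$consensus <- NULL  # objects stay out of the written manifest
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(status = 0L, manifest = manifest))
}
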