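pipeline_defaults <- function() {
  list(width = 21, pseudocount = 0.5, palindromic = TRUE, threshold = NULL,
       min_support = 2, operon_gap = 100, upstream = 300, downstream = 50,
       alpha = 0.05, min_sig = 6, n_expected = 8, cutoff = 1.0, span = 0.3,
       restarts = 10, seed = 1, out = ".")
}

#' Run a pipeline stage with a single configuration
#'
#' One programmatic entry point over the package's stages. `config` is a
#' named list or the path of a YAML file; `...` overrides win over the
#' config, which wins over the defaults. Every run writes its artifacts
#' plus a `metadata.json` record (stage, parameters, input digests,
#' package version, timestamp) into `out`.
#'
#' Stages and their expected config fields:
#' \describe{
#'   \item{simulate}{`seed`, optional [panel_config()] fields; writes the
#'     panel FASTA + annotation TSV, orthology TSV, and truth JSON.}
#'   \item{discover}{`regions` (FASTA of upstream regions); writes the
#'     motif TSV/JSON and a site table.}
#'   \item{scan}{`motif` (TSV path) and `fasta`/`annotation`; writes sites
#'     as TSV and BED6.}
#'   \item{regulon}{`motif`, `fasta`, `annotation`, `orthology`; writes the
#'     member table TSV.}
#'   \item{expression}{`spots` (TSV of spot intensities) or `means` (TSV
#'     with per-gene `gene_id`, `m`), optional `rtpcr` TSV; writes calls.}
#'   \item{geometry}{`sites` and `promoters` TSVs; writes the
#'     classification table.}
#' }
#'
#' @param stage One of `"simulate"`, `"discover"`, `"scan"`, `"regulon"`,
#'   `"expression"`, `"geometry"`.
#' @param config Named list or YAML path.
#' @param ... Individual parameter overrides.
#' @return Invisibly, a list of the stage's in-memory results.
#' @export
run_pipeline <- function(stage = c("simulate", "discover", "scan", "regulon",
                                   "expression", "geometry"),
                         config = list(), ...) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  cfg <- utils::modifyList(cfg, list(...))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  result <- switch(stage,
    simulate = stage_simulate(cfg),
    discover = stage_discover(cfg),
    scan = stage_scan(cfg),
    regulon = stage_regulon(cfg),
    expression = stage_expression(cfg),
    geometry = stage_geometry(cfg))
  inputs <- Filter(function(p) is.character(p) && length(p) == 1 && file.exists(p),
                   cfg[c("regions", "motif", "fasta", "annotation", "orthology",
                         "spots", "means", "rtpcr", "sites", "promoters")])
  meta <- list(stage = stage,
               parameters = cfg[setdiff(names(cfg), "out")],
               input_md5 = if (length(inputs) == 0) list() else
                 as.list(tools::md5sum(unname(unlist(inputs)))),
               package_version = as.character(utils::packageVersion("zurscan")),
               elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
               timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(cfg$out, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("[%s] done in %.2fs -> %s", stage, meta$elapsed_s, cfg$out))
  invisible(result)
}

stage_simulate <- function(cfg) {
  pc_args <- intersect(names(cfg), names(formals(panel_config)))
  sim <- simulate_panel(do.call(panel_config, cfg[pc_args]))
  write_panel(sim$panel, file.path(cfg$out, "panel.fasta"),
              file.path(cfg$out, "panel_genes.tsv"))
  readr::write_tsv(sim$orthology, file.path(cfg$out, "orthology.tsv"),
                   progress = FALSE)
  jsonlite::write_json(lapply(sim$truth, function(x) x),
                       file.path(cfg$out, "truth.json"),
                       dataframe = "columns", digits = NA, null = "null")
  sim
}

stage_discover <- function(cfg) {
  seqs <- Biostrings::readDNAStringSet(cfg$regions)
  regions <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  disc <- discover_motif(regions, width = cfg$width,
                         palindromic = cfg$palindromic,
                         restarts = cfg$restarts, seed = cfg$seed,
                         pseudocount = cfg$pseudocount)
  write_motif(disc$model, file.path(cfg$out, "motif.tsv"))
  readr::write_tsv(disc$sites, file.path(cfg$out, "discovered_sites.tsv"),
                   progress = FALSE)
  disc
}

load_cfg_panel <- function(cfg) read_panel(cfg$fasta, cfg$annotation)

stage_scan <- function(cfg) {
  model <- read_motif(cfg$motif)
  if (is.na(model$threshold) && is.null(cfg$threshold)) {
    model <- set_threshold_from_training(model)
  }
  panel <- load_cfg_panel(cfg)
  sites <- purrr::map_dfr(panel, function(g)
    scan_sequence(model, g, threshold = cfg$threshold))
  readr::write_tsv(sites, file.path(cfg$out, "sites.tsv"), progress = FALSE)
  write_sites_bed(sites, file.path(cfg$out, "sites.bed"), width = model$width)
  sites
}

stage_regulon <- function(cfg) {
  model <- read_motif(cfg$motif)
  if (is.na(model$threshold) && is.null(cfg$threshold)) {
    model <- set_threshold_from_training(model)
  }
  panel <- load_cfg_panel(cfg)
  ortho <- if (!is.null(cfg$orthology)) read_orthology(cfg$orthology) else NULL
  reg <- assemble_regulon(model, panel, ortho, upstream = cfg$upstream,
                          downstream = cfg$downstream,
                          operon_gap = cfg$operon_gap,
                          min_support = cfg$min_support,
                          threshold = cfg$threshold)
  readr::write_tsv(reg$members, file.path(cfg$out, "regulon_members.tsv"),
                   progress = FALSE)
  readr::write_tsv(reg$sites, file.path(cfg$out, "regulon_sites.tsv"),
                   progress = FALSE)
  reg
}

stage_expression <- function(cfg) {
  if (!is.null(cfg$means)) {
    means <- readr::read_tsv(cfg$means, show_col_types = FALSE, progress = FALSE)
    calls <- tibble::tibble(gene_id = means$gene_id, m_mean = means$m,
                            call = de_call(means$m, cutoff = cfg$cutoff))
  } else {
    spots <- readr::read_tsv(cfg$spots, show_col_types = FALSE, progress = FALSE)
    calls <- spots |>
      compute_ma() |>
      lowess_normalize(span = cfg$span) |>
      call_differential(alpha = cfg$alpha, min_sig = cfg$min_sig,
                        n_expected = cfg$n_expected, cutoff = cfg$cutoff)
  }
  if (!is.null(cfg$rtpcr)) {
    cp <- readr::read_tsv(cfg$rtpcr, show_col_types = FALSE, progress = FALSE)
    folds <- rtpcr_fold_change(cp)
    calls <- integrate_targets(calls, rtpcr = folds)
  }
  readr::write_tsv(calls, file.path(cfg$out, "expression_calls.tsv"),
                   progress = FALSE)
  calls
}

stage_geometry <- function(cfg) {
  sites <- readr::read_tsv(cfg$sites, show_col_types = FALSE, progress = FALSE)
  promoters <- readr::read_tsv(cfg$promoters, show_col_types = FALSE,
                               progress = FALSE)
  cls <- classify_site_vs_promoter(sites, promoters)
  readr::write_tsv(cls, file.path(cfg$out, "site_promoter_classes.tsv"),
                   progress = FALSE)
  cls
}
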