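#' Scan a genome for candidate binding sites
#'
#' Every width-W window on both strands is scored; windows at or above the
#' threshold are returned sorted by position. For palindromic models the
#' forward and reverse readings of one locus score identically, so each
#' locus is reported once with strand `"+"`. Windows overlapping `N` score
#' `-Inf` and are never reported.
#'
#' @param model A `pwm_model`.
#' @param genome A `genome` object or a plain DNA string.
#' @param threshold Z threshold; defaults to the model's training-derived
#'   threshold (an error if neither is available).
#' @return Tibble of candidate sites: `genome_id`, `position` (0-based
#'   leftmost on the forward strand), `strand`, `sequence` (as read on the
#'   matching strand), `z`.
#' @export
#' @examples
#' m <- set_threshold_from_training(
#'   build_motif(cgl_zur_targets()$motif[!is.na(cgl_zur_targets()$motif)]))
#' seq <- paste0(strrep("A", 20), "TAATGATAACGGTTATCATTT", strrep("A", 20))
#' scan_sequence(m, seq)
scan_sequence <- function(model, genome, threshold = NULL) {
  stopifnot(inherits(model, "pwm_model"))
  threshold <- threshold %||% model$threshold
  if (is.na(threshold)) {
    stop("no threshold: call set_threshold_from_training() or pass `threshold`",
         call. = FALSE)
  }
  if (inherits(genome, "genome")) {
    seq <- genome$sequence; genome_id <- genome$genome_id
  } else {
    seq <- check_dna(genome, allow_n = TRUE); genome_id <- NA_character_
  }
  W <- model$width
  if (nchar(seq) < W) {
    return(tibble::tibble(genome_id = character(), position = integer(),
                          strand = character(), sequence = character(),
                          z = double()))
  }
  sc <- scores_both_strands(model, seq)
  hit_f <- which(sc$fwd >= threshold)
  out_f <- tibble::tibble(position = hit_f - 1L, strand = "+", z = sc$fwd[hit_f])
  if (model$palindromic) {
    out <- out_f
  } else {
    hit_r <- which(sc$rev >= threshold)
    out_r <- tibble::tibble(position = hit_r - 1L, strand = "-", z = sc$rev[hit_r])
    out <- dplyr::bind_rows(out_f, out_r)
  }
  out$sequence <- vapply(out$position, function(p) substr(seq, p + 1L, p + W), "")
  out$sequence[out$strand == "-"] <- revcomp(out$sequence[out$strand == "-"])
  out |>
    dplyr::mutate(genome_id = genome_id, .before = 1) |>
    dplyr::arrange(.data$position, .data$strand)
}

# Upstream-window genomic interval of each gene (0-based half-open),
# truncated to linear contigs.
gene_windows <- function(genome, upstream, downstream) {
  genes <- genome$genes
  len <- nchar(genome$sequence)
  w_start <- ifelse(genes$strand == "+", genes$start - upstream, genes$end - downstream)
  w_end <- ifelse(genes$strand == "+", genes$start + downstream, genes$end + upstream)
  if (!genome$circular) {
    w_start <- pmax(w_start, 0L); w_end <- pmin(w_end, len)
  }
  dplyr::mutate(genes, w_start = w_start, w_end = w_end)
}

#' Assign candidate sites to genes by upstream-window coverage
#'
#' A site is assigned to every gene whose upstream window (in gene
#' orientation) covers the site's centre (`position + (W-1)/2`), so a single
#' site in a short intergenic region between divergently transcribed genes
#' is shared by both. Sites covering no window are dropped with a message.
#'
#' @param sites Tibble from [scan_sequence()] (one genome).
#' @param genome The matching `genome` object.
#' @param upstream,downstream Window extent relative to the translation
#'   start, as in [extract_upstream()].
#' @param width Motif width used to locate the site centre.
#' @return Tibble with one row per (site, gene): the site columns plus
#'   `gene_id` and `offset` (site centre relative to the translation start,
#'   negative upstream, in gene orientation).
#' @export
assign_sites_to_genes <- function(sites, genome, upstream = 300, downstream = 50,
                                  width = 21) {
  stopifnot(inherits(genome, "genome"))
  if (nrow(sites) == 0) {
    return(dplyr::mutate(sites, gene_id = character(0), offset = integer(0)))
  }
  wins <- gene_windows(genome, upstream, downstream)
  center <- sites$position + (width - 1L) %/% 2L
  out <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    hit <- wins[center[i] >= wins$w_start & center[i] < wins$w_end, ]
    if (nrow(hit) == 0) return(NULL)
    offset <- ifelse(hit$strand == "+", center[i] - hit$start,
                     (hit$end - 1L) - center[i])
    dplyr::bind_cols(sites[rep(i, nrow(hit)), ],
                     tibble::tibble(gene_id = hit$gene_id,
                                    offset = as.integer(offset)))
  })
  n_drop <- length(setdiff(seq_len(nrow(sites)),
                           which(vapply(seq_len(nrow(sites)), function(i)
                             any(center[i] >= wins$w_start & center[i] < wins$w_end),
                             TRUE))))
  if (n_drop > 0) {
    message(n_drop, " site(s) covered no gene window and were dropped")
  }
  if (is.null(out) || nrow(out) == 0) {
    out <- dplyr::mutate(sites[0, ], gene_id = character(0), offset = integer(0))
  }
  out
}

#' Chain co-directional genes into transcription units
#'
#' Greedy chaining: consecutive genes on the same strand whose intergenic
#' gap is at most `operon_gap` join one transcription unit; every gene lands
#' in exactly one unit. The unit is named after its lead (5'-most) gene.
#'
#' @param genome A `genome` object.
#' @param operon_gap Maximum intergenic distance in bp (default 100).
#' @return Tibble: `tu_id`, `gene_id`, `lead_gene`, `tu_order` (1 = lead,
#'   counted 5'->3'), `strand`.
#' @export
build_transcription_units <- function(genome, operon_gap = 100) {
  stopifnot(inherits(genome, "genome"))
  genes <- genome$genes
  if (nrow(genes) == 0) {
    return(tibble::tibble(tu_id = character(), gene_id = character(),
                          lead_gene = character(), tu_order = integer(),
                          strand = character()))
  }
  brk <- c(TRUE, genes$strand[-1] != genes$strand[-nrow(genes)] |
             genes$start[-1] - genes$end[-nrow(genes)] > operon_gap)
  genes$block <- cumsum(brk)
  genes |>
    dplyr::group_by(.data$block) |>
    dplyr::mutate(
      lead_gene = if (dplyr::first(.data$strand) == "+") dplyr::first(.data$gene_id)
                  else dplyr::last(.data$gene_id),
      tu_order = if (dplyr::first(.data$strand) == "+") dplyr::row_number()
                 else rev(dplyr::row_number()),
      tu_id = paste0("tu_", .data$lead_gene)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$block, .data$tu_order) |>
    dplyr::select("tu_id", "gene_id", "lead_gene", "tu_order", "strand")
}

#' Cross-genome consistency filter
#'
#' A candidate transcription unit is retained iff orthologues of at least
#' one of its genes carry candidate sites in at least `min_support` *other*
#' genomes (self-support does not count). Genes absent from the orthology
#' table contribute zero support, with a warning.
#'
#' @param members Tibble with columns `genome_id`, `tu_id`, `gene_id`,
#'   `direct_site` (logical: does the gene itself have an assigned site?).
#' @param orthology Tibble `family_id`, `genome_id`, `gene_id`.
#' @param min_support Required number of supporting other genomes (K);
#'   `K = 0` disables the filter.
#' @return The retained rows with a `consistency_support` column (number of
#'   other genomes whose orthologues carry candidate sites, maximised over
#'   the unit's genes as a union of supporting genomes).
#' @export
consistency_filter <- function(members, orthology, min_support = 2) {
  if (nrow(members) == 0) {
    return(dplyr::mutate(members, consistency_support = integer(0)))
  }
  unmapped <- dplyr::anti_join(members, orthology, by = c("genome_id", "gene_id"))
  if (nrow(unmapped) > 0) {
    warning(nrow(unmapped), " gene(s) absent from the orthology table; ",
            "treated as support 0", call. = FALSE)
  }
  # (genome, gene) pairs that directly carry a candidate site, by family
  carriers <- members |>
    dplyr::filter(.data$direct_site) |>
    dplyr::inner_join(orthology, by = c("genome_id", "gene_id")) |>
    dplyr::distinct(.data$family_id, carrier_genome = .data$genome_id)
  support <- members |>
    dplyr::inner_join(orthology, by = c("genome_id", "gene_id")) |>
    dplyr::inner_join(carriers, by = "family_id", relationship = "many-to-many") |>
    dplyr::filter(.data$carrier_genome != .data$genome_id) |>
    dplyr::distinct(.data$genome_id, .data$tu_id, .data$carrier_genome) |>
    dplyr::count(.data$genome_id, .data$tu_id, name = "consistency_support")
  out <- members |>
    dplyr::left_join(support, by = c("genome_id", "tu_id")) |>
    dplyr::mutate(consistency_support =
                    dplyr::coalesce(.data$consistency_support, 0L))
  dplyr::filter(out, .data$consistency_support >= min_support)
}

#' Assemble a predicted regulon across a genome panel
#'
#' Pipeline composition: scan each genome ([scan_sequence()]), assign sites
#' to genes ([assign_sites_to_genes()]), chain transcription units
#' ([build_transcription_units()]), apply the cross-genome consistency
#' filter ([consistency_filter()]), and expand by operon structure: every
#' gene of a site-bearing, retained unit becomes a member, with evidence
#' `direct_site` when the gene itself has an assigned site and
#' `operon_inherited` otherwise.
#'
#' @param model A `pwm_model` with a threshold (or pass `threshold`).
#' @param panel A `genome` or named list of genomes.
#' @param orthology Orthology tibble (validated against the panel); may be
#'   `NULL` when `min_support = 0`.
#' @param upstream,downstream Upstream-window extent.
#' @param operon_gap Operon chaining distance.
#' @param min_support Consistency-check K (other genomes); 0 disables.
#' @param threshold Optional explicit Z threshold.
#' @return Object of class `regulon`: list with `members` (tibble:
#'   `genome_id`, `tu_id`, `gene_id`, `tu_order`, `evidence`,
#'   `consistency_support`, `n_sites`, `best_z`), `sites` (assigned site
#'   table), and `params`. `tidy()` returns the member table.
#' @export
assemble_regulon <- function(model, panel, orthology = NULL,
                             upstream = 300, downstream = 50,
                             operon_gap = 100, min_support = 2,
                             threshold = NULL) {
  if (inherits(panel, "genome")) {
    panel <- stats::setNames(list(panel), panel$genome_id)
  }
  if (min_support > 0 && is.null(orthology)) {
    stop("min_support > 0 needs an orthology table", call. = FALSE)
  }
  if (!is.null(orthology)) validate_orthology(orthology, panel)

  per_genome <- purrr::map(panel, function(g) {
    sites <- scan_sequence(model, g, threshold = threshold)
    assigned <- suppressMessages(
      assign_sites_to_genes(sites, g, upstream = upstream,
                            downstream = downstream, width = model$width))
    tus <- build_transcription_units(g, operon_gap = operon_gap)
    site_genes <- unique(assigned$gene_id)
    candidates <- tus |>
      dplyr::group_by(.data$tu_id) |>
      dplyr::filter(any(.data$gene_id %in% site_genes)) |>
      dplyr::ungroup() |>
      dplyr::mutate(genome_id = g$genome_id,
                    direct_site = .data$gene_id %in% site_genes)
    list(candidates = candidates, sites = assigned)
  })

  members <- purrr::map_dfr(per_genome, "candidates")
  sites <- purrr::map_dfr(per_genome, "sites")
  if (nrow(members) > 0) {
    if (min_support > 0) {
      members <- consistency_filter(members, orthology, min_support = min_support)
    } else {
      members <- dplyr::mutate(members, consistency_support = NA_integer_)
    }
  } else {
    members <- dplyr::mutate(members, consistency_support = integer(0))
  }
  site_stats <- if (nrow(sites) > 0) {
    sites |>
      dplyr::group_by(.data$genome_id, .data$gene_id) |>
      dplyr::summarise(n_sites = dplyr::n(), best_z = max(.data$z), .groups = "drop")
  } else {
    tibble::tibble(genome_id = character(), gene_id = character(),
                   n_sites = integer(), best_z = double())
  }
  members <- members |>
    dplyr::mutate(evidence = ifelse(.data$direct_site, "direct_site",
                                    "operon_inherited")) |>
    dplyr::left_join(site_stats, by = c("genome_id", "gene_id")) |>
    dplyr::select("genome_id", "tu_id", "gene_id", "tu_order", "evidence",
                  "consistency_support", "n_sites", "best_z")
  structure(list(members = members,
                 sites = dplyr::semi_join(sites, members,
                                          by = c("genome_id", "gene_id")),
                 params = list(upstream = upstream, downstream = downstream,
                               operon_gap = operon_gap, min_support = min_support,
                               threshold = threshold %||% model$threshold,
                               width = model$width)),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  m <- x$members
  cat(sprintf("<regulon> %d member genes in %d transcription units across %d genome(s)\n",
              nrow(m), dplyr::n_distinct(m$genome_id, m$tu_id),
              dplyr::n_distinct(m$genome_id)))
  cat(sprintf("  threshold %.3f, K = %d, operon gap %d bp\n",
              x$params$threshold, x$params$min_support, x$params$operon_gap))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.regulon <- function(x, ...) x$members

#' @exportS3Method generics::glance
glance.regulon <- function(x, ...) {
  tibble::tibble(n_genomes = dplyr::n_distinct(x$members$genome_id),
                 n_tus = dplyr::n_distinct(paste(x$members$genome_id,
                                                 x$members$tu_id)),
                 n_members = nrow(x$members),
                 n_direct = sum(x$members$evidence == "direct_site"),
                 threshold = x$params$threshold,
                 min_support = x$params$min_support)
}

#' Site map plot for an assembled regulon
#'
#' Genes of the member transcription units drawn as arrows along the
#' contig, candidate sites as points, one facet per genome.
#'
#' @param object A `regulon` from [assemble_regulon()].
#' @param panel The genome panel the regulon was assembled from.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.regulon <- function(object, panel, ...) {
  if (inherits(panel, "genome")) panel <- stats::setNames(list(panel), panel$genome_id)
  genes <- purrr::map_dfr(panel, function(g) {
    dplyr::mutate(g$genes, genome_id = g$genome_id)
  }) |>
    dplyr::semi_join(object$members, by = c("genome_id", "gene_id"))
  ggplot2::ggplot(genes) +
    ggplot2::geom_segment(ggplot2::aes(x = ifelse(.data$strand == "+", .data$start, .data$end),
                                       xend = ifelse(.data$strand == "+", .data$end, .data$start),
                                       y = 0, yend = 0),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          linewidth = 1.2, colour = "steelblue") +
    ggplot2::geom_point(data = dplyr::distinct(object$sites, .data$genome_id,
                                               .data$position, .data$z),
                        ggplot2::aes(x = .data$position, y = 0.15, size = .data$z),
                        colour = "firebrick", shape = 18) +
    ggplot2::facet_wrap(~genome_id, scales = "free_x", ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(-0.3, 0.4), breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL, size = "Z") +
    ggplot2::theme_minimal()
}

#' Export candidate sites as BED6 / Table-style TSV
#'
#' BED6 score is `100 * z` clamped to `[0, 1000]`.
#'
#' @param sites Site tibble (from [scan_sequence()] or a `regulon`).
#' @param path Output path.
#' @param width Motif width (for the BED end coordinate).
#' @return Invisibly, `path`.
#' @export
write_sites_bed <- function(sites, path, width = 21) {
  bed <- tibble::tibble(chrom = sites$genome_id,
                        start = sites$position,
                        end = sites$position + width,
                        name = paste0("site_", seq_len(nrow(sites))),
                        score = pmin(pmax(round(100 * sites$z), 0), 1000),
                        strand = sites$strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
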