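#' Classify a candidate site against a mapped promoter
#'
#' Interval classification of a site against the deduced core promoter:
#' `overlaps_core` when the site overlaps the -10 element (with or without
#' the -35), `overlaps_minus35` when it overlaps only the -35, else
#' `distal` with the strand-aware distance `d` from the site's downstream
#' edge to the transcription start (positive upstream; a site downstream of
#' the TSS gets a negative, flagged distance). Operators overlapping the
#' core promoter are compatible with steric repression of RNA-polymerase
#' entry; distal placements are not.
#'
#' @param sites Tibble with `position` (0-based leftmost), `width`
#'   (optional, default 21), and `gene_id` linking to the promoter row.
#' @param promoters Tibble with `gene_id`, `tss` (0-based position of +1),
#'   `strand`, and optional `minus10_start`, `minus10_end`,
#'   `minus35_start`, `minus35_end` (0-based half-open).
#' @param site_strand Optional strand of the site *assignment*; must match
#'   the promoter strand when given (mismatch is an error).
#' @return Tibble: the join of site and promoter with `class` in
#'   `{overlaps_core, overlaps_minus35, distal}`, `distance` (NA unless
#'   distal), `downstream_of_tss` flag.
#' @export
classify_site_vs_promoter <- function(sites, promoters, site_strand = NULL) {
  df <- dplyr::inner_join(sites, promoters, by = "gene_id",
                          suffix = c("", ".prom"))
  if (!is.null(site_strand) && any(site_strand != df$strand)) {
    stop("site assignment strand does not match the promoter strand", call. = FALSE)
  }
  col_or <- function(name, default) {
    if (name %in% names(df)) df[[name]] else rep(default, nrow(df))
  }
  w <- col_or("width", 21L)
  s_start <- df$position; s_end <- df$position + w
  olap <- function(a1, a2, b1, b2) !is.na(b1) & a1 < b2 & b1 < a2
  hit10 <- olap(s_start, s_end, col_or("minus10_start", NA), col_or("minus10_end", NA))
  hit35 <- olap(s_start, s_end, col_or("minus35_start", NA), col_or("minus35_end", NA))
  d <- ifelse(df$strand == "+", df$tss - s_end, s_start - df$tss - 1L)
  dplyr::mutate(df,
                class = dplyr::case_when(hit10 ~ "overlaps_core",
                                         hit35 ~ "overlaps_minus35",
                                         TRUE ~ "distal"),
                distance = ifelse(.data$class == "distal", as.integer(d), NA_integer_),
                downstream_of_tss = .data$class == "distal" & d < 0,
                repression_compatible = .data$class != "distal")
}

#' Detect leaderless transcripts
#'
#' A transcript is leaderless when its mapped transcription start coincides
#' with the first base of the start codon (strand-aware: `tss == start` on
#' the plus strand, `tss == end - 1` on the minus strand).
#'
#' @param promoters Tibble with `gene_id`, `tss`, `strand`.
#' @param genes Gene tibble with `gene_id`, `start`, `end` (0-based
#'   half-open).
#' @return The joined tibble with a logical `leaderless` column.
#' @export
detect_leaderless <- function(promoters, genes) {
  dplyr::inner_join(promoters, genes, by = "gene_id", suffix = c("", ".gene")) |>
    dplyr::mutate(leaderless = ifelse(.data$strand == "+",
                                      .data$tss == .data$start,
                                      .data$tss == .data$end - 1L))
}

#' Design an EMSA probe around a candidate site
#'
#' Extracts a `probe_len`-mer with the site centred in native genomic
#' flanks (for 40/21: 10 nt left, 9 nt right). Insufficient native flank on
#' a linear contig is an error naming the deficit.
#'
#' @param genome A `genome` object.
#' @param position 0-based leftmost position of the site.
#' @param width Site width (default 21).
#' @param probe_len Probe length (default 40).
#' @return Tibble (class kept plain): `sequence`, `motif_offset` (0-based
#'   offset of the site within the probe), `start`, `end`,
#'   `mutated_positions` (list column, empty).
#' @export
design_probe <- function(genome, position, width = 21, probe_len = 40) {
  stopifnot(inherits(genome, "genome"), probe_len >= width)
  left <- ceiling((probe_len - width) / 2)
  right <- probe_len - width - left
  p_start <- position - left
  p_end <- position + width + right
  if (!genome$circular && (p_start < 0 || p_end > nchar(genome$sequence))) {
    deficit <- max(0 - p_start, p_end - nchar(genome$sequence))
    stop(sprintf("insufficient native flank: %d nt short of the contig edge",
                 deficit), call. = FALSE)
  }
  sl <- slice_sequence(genome$sequence, p_start, p_end, genome$circular)
  tibble::tibble(sequence = sl$seq, motif_offset = as.integer(left),
                 start = as.integer(p_start), end = as.integer(p_end),
                 mutated_positions = list(integer(0)))
}

#' Transition mutagenesis of an EMSA probe
#'
#' Applies transitions (A<->G, C<->T) at the selected positions, the
#' substitution class that abolishes operator binding when placed inside
#' the motif but not when confined to the flanks. Transitions are
#' involutions, so applying the same mutation twice restores the probe.
#'
#' @param probe One-row tibble from [design_probe()], with `width` of the
#'   embedded motif taken as 21 unless given.
#' @param region `"motif"` or `"flanks"`: default position set.
#' @param positions Optional explicit 1-based positions within the probe.
#' @param width Motif width.
#' @return The probe with `sequence` mutated and `mutated_positions`
#'   updated.
#' @export
mutate_probe <- function(probe, region = c("motif", "flanks"), positions = NULL,
                         width = 21) {
  region <- match.arg(region)
  plen <- nchar(probe$sequence)
  motif_pos <- seq(probe$motif_offset + 1L, probe$motif_offset + width)
  if (is.null(positions)) {
    positions <- if (region == "motif") motif_pos else setdiff(seq_len(plen), motif_pos)
  }
  if (any(positions < 1 | positions > plen)) {
    stop("mutation position outside the probe", call. = FALSE)
  }
  chars <- strsplit(probe$sequence, "", fixed = TRUE)[[1]]
  chars[positions] <- chartr("AGCT", "GATC", chars[positions])
  dplyr::mutate(probe, sequence = paste(chars, collapse = ""),
                mutated_positions = list(sort(unique(as.integer(positions)))))
}

#' Write probes as FASTA with metadata headers
#'
#' @param probes Tibble of probes (rows from [design_probe()] /
#'   [mutate_probe()]).
#' @param path Output FASTA path.
#' @param names Optional sequence names.
#' @return Invisibly, `path`.
#' @export
write_probes <- function(probes, path, names = NULL) {
  hdr <- names %||% sprintf("probe_%d offset=%d mutated=%s",
                            seq_len(nrow(probes)), probes$motif_offset,
                            vapply(probes$mutated_positions,
                                   function(p) if (length(p)) paste(p, collapse = ",") else "none",
                                   ""))
  set <- Biostrings::DNAStringSet(probes$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
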