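#' Construct a genome object
#'
#' A `genome` couples one contig's DNA sequence with its gene table. All
#' coordinates in the package are 0-based half-open on the forward strand;
#' file readers convert at the boundary (GFF3 and the TSV gene-table dialect
#' are 1-based inclusive).
#'
#' @param genome_id Identifier (used as the FASTA record / GFF seqid).
#' @param sequence DNA string over `{A,C,G,T,N}`.
#' @param genes Data frame with columns `gene_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), and optionally `product`.
#' @param circular Is the contig circular? Circular contigs wrap upstream
#'   windows instead of truncating them.
#' @return An object of class `genome`: a list with fields `genome_id`,
#'   `sequence`, `genes` (tibble sorted by `start`), `circular`.
#' @export
#' @examples
#' g <- new_genome("chr", strrep("ACGT", 250),
#'   data.frame(gene_id = "g1", start = 100, end = 400, strand = "+"))
#' g$genes
new_genome <- function(genome_id, sequence, genes, circular = FALSE) {
  sequence <- check_dna(sequence, allow_n = TRUE, what = sprintf("genome '%s'", genome_id))
  genes <- tibble::as_tibble(genes)
  if (nrow(genes) == 0) {
    genes <- tibble::tibble(gene_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            product = character())
  }
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  req <- c("gene_id", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    stop("gene table needs columns gene_id, start, end, strand", call. = FALSE)
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start >= genes$end)) stop("gene with start >= end", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("malformed strand (must be '+' or '-'): ",
         paste(unique(setdiff(genes$strand, c("+", "-"))), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids", call. = FALSE)
  if (!circular && nrow(genes) > 0 &&
      (any(genes$start < 0) || any(genes$end > nchar(sequence)))) {
    stop("gene interval outside the contig on a non-circular genome", call. = FALSE)
  }
  genes <- dplyr::arrange(genes, .data$start)
  structure(list(genome_id = genome_id, sequence = sequence,
                 genes = genes[, c("gene_id", "start", "end", "strand", "product")],
                 circular = circular),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp%s, %d genes\n", x$genome_id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) " (circular)" else "", nrow(x$genes)))
  invisible(x)
}

read_annotation <- function(annotation_path) {
  ext <- tolower(tools::file_ext(annotation_path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(annotation_path)
    df <- as.data.frame(gr)
    if ("type" %in% names(df) && any(df$type %in% c("gene", "CDS"))) {
      keep <- if (any(df$type == "gene")) "gene" else "CDS"
      df <- df[df$type == keep, , drop = FALSE]
    }
    ids <- df$ID %||% df$locus_tag %||% df$Name
    if (is.null(ids) || anyNA(ids)) {
      nid <- if (is.null(ids)) seq_len(nrow(df)) else which(is.na(ids))
      if (is.null(ids)) ids <- rep(NA_character_, nrow(df))
      ids[nid] <- sprintf("gene_%04d", nid)
    }
    tibble::tibble(seqid = as.character(df$seqnames),
                   gene_id = as.character(ids),
                   start = as.integer(df$start) - 1L,  # 1-based incl. -> 0-based half-open
                   end = as.integer(df$end),
                   strand = as.character(df$strand),
                   product = as.character(df$product %||% rep(NA_character_, nrow(df))))
  } else {
    df <- readr::read_tsv(annotation_path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
    req <- c("gene_id", "start", "end", "strand")
    if (!all(req %in% names(df))) {
      stop("TSV annotation needs columns gene_id, start, end, strand", call. = FALSE)
    }
    if (!"seqid" %in% names(df)) df$seqid <- NA_character_
    if (!"product" %in% names(df)) df$product <- NA_character_
    # TSV dialect is 1-based inclusive (flagged in the writer's header)
    tibble::tibble(seqid = as.character(df$seqid), gene_id = as.character(df$gene_id),
                   start = as.integer(df$start) - 1L, end = as.integer(df$end),
                   strand = as.character(df$strand), product = df$product)
  }
}

#' Read a genome panel from FASTA plus annotation
#'
#' `read_panel()` reads every FASTA record into one [new_genome()] object;
#' `read_genome()` is the single-contig convenience form. Annotation may be
#' GFF3 (1-based inclusive, converted at the boundary) or a TSV with header
#' columns `gene_id`, `start`, `end`, `strand` and optional `seqid`,
#' `product` (also 1-based inclusive).
#'
#' @param fasta_path FASTA file with >= 1 record.
#' @param annotation_path GFF3 or TSV gene table.
#' @param circular Logical, recycled over records.
#' @return `read_panel()`: named list of `genome` objects; `read_genome()`:
#'   a single `genome`.
#' @export
read_panel <- function(fasta_path, annotation_path, circular = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) < 1) stop("FASTA has no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- read_annotation(annotation_path)
  if (nrow(ann) == 0) warning("annotation has no gene records", call. = FALSE)
  if (all(is.na(ann$seqid))) {
    if (length(seqs) > 1) stop("multi-record FASTA needs a seqid column", call. = FALSE)
    ann$seqid <- ids[1]
  }
  missing <- setdiff(unique(ann$seqid), ids)
  if (length(missing) > 0) {
    stop("annotation references records absent from the FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  circular <- rep_len(circular, length(seqs))
  panel <- purrr::map2(ids, seq_along(ids), function(id, i) {
    new_genome(id, as.character(seqs[[i]]),
               ann[ann$seqid == id, setdiff(names(ann), "seqid")],
               circular = circular[i])
  })
  stats::setNames(panel, ids)
}

#' @rdname read_panel
#' @export
read_genome <- function(fasta_path, annotation_path, circular = FALSE) {
  panel <- read_panel(fasta_path, annotation_path, circular = circular)
  if (length(panel) > 1) stop("FASTA has several records; use read_panel()", call. = FALSE)
  panel[[1]]
}

#' Write a genome (or panel) back to FASTA + TSV annotation
#'
#' The TSV gene table is written 1-based inclusive (header comment flags the
#' convention), so a write/read round trip reproduces coordinates exactly.
#'
#' @param panel A `genome` or list of genomes.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the input.
#' @export
write_panel <- function(panel, fasta_path, annotation_path) {
  if (inherits(panel, "genome")) panel <- list(panel)
  seqs <- Biostrings::DNAStringSet(purrr::map_chr(panel, "sequence"))
  names(seqs) <- purrr::map_chr(panel, "genome_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- purrr::map_dfr(panel, function(g) {
    dplyr::mutate(g$genes, seqid = g$genome_id, start = .data$start + 1L,
                  .before = 1)
  })
  header <- "# coordinates: 1-based inclusive"
  writeLines(c(header, paste(names(ann), collapse = "\t")), annotation_path)
  readr::write_tsv(ann, annotation_path, append = TRUE, col_names = FALSE)
  invisible(panel)
}

#' Read and validate an orthology table
#'
#' Three-column TSV (`family_id`, `genome_id`, `gene_id`) mapping genes into
#' orthologous families, the substrate of the cross-genome consistency
#' check. Duplicate rows are collapsed; a gene assigned to two families is a
#' hard error.
#'
#' @param tsv_path Path to the TSV (with header).
#' @return Tibble with columns `family_id`, `genome_id`, `gene_id`.
#' @export
read_orthology <- function(tsv_path) {
  df <- readr::read_tsv(tsv_path, show_col_types = FALSE, progress = FALSE)
  req <- c("family_id", "genome_id", "gene_id")
  if (!all(req %in% names(df))) {
    stop("orthology TSV needs columns family_id, genome_id, gene_id", call. = FALSE)
  }
  df <- dplyr::distinct(tibble::as_tibble(df[req]))
  dup <- df |>
    dplyr::distinct(.data$genome_id, .data$gene_id, .data$family_id) |>
    dplyr::count(.data$genome_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("gene assigned to more than one family: ",
         paste(dup$gene_id, collapse = ", "), call. = FALSE)
  }
  df
}

#' Validate an orthology table against a genome panel
#'
#' @param orthology Tibble from [read_orthology()].
#' @param panel Named list of `genome` objects.
#' @return The orthology tibble, invisibly, after validation.
#' @export
validate_orthology <- function(orthology, panel) {
  if (inherits(panel, "genome")) panel <- list(panel) |> stats::setNames(panel$genome_id)
  bad_genome <- setdiff(unique(orthology$genome_id), names(panel))
  if (length(bad_genome) > 0) {
    stop("orthology references unknown genomes: ",
         paste(bad_genome, collapse = ", "), call. = FALSE)
  }
  for (gid in names(panel)) {
    want <- orthology$gene_id[orthology$genome_id == gid]
    bad <- setdiff(want, panel[[gid]]$genes$gene_id)
    if (length(bad) > 0) {
      stop(sprintf("orthology references genes absent from genome '%s': %s",
                   gid, paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  invisible(orthology)
}

#' Extract strand-aware upstream regions
#'
#' Collects, for each requested gene, the window `(-upstream, +downstream)`
#' around its translation start (position 0 = first base of the start
#' codon), oriented 5'->3' in the sense of the gene (minus-strand regions
#' are reverse-complemented). Windows are truncated at contig edges for
#' linear genomes and wrapped for circular ones; a window fully off the
#' contig yields an empty, flagged region rather than an error.
#'
#' @param genome A `genome` object.
#' @param gene_ids Genes to extract; default all genes.
#' @param upstream,downstream Window extent in nt (defaults -300..+50).
#' @return Tibble: `genome_id`, `gene_id`, `start`, `end` (0-based half-open
#'   on the forward strand), `strand`, `seq` (oriented), `truncated`,
#'   `off_contig`.
#' @export
extract_upstream <- function(genome, gene_ids = NULL, upstream = 300, downstream = 50) {
  stopifnot(inherits(genome, "genome"), upstream >= 0, downstream >= 0)
  genes <- genome$genes
  if (!is.null(gene_ids)) {
    bad <- setdiff(gene_ids, genes$gene_id)
    if (length(bad) > 0) stop("unknown gene(s): ", paste(bad, collapse = ", "), call. = FALSE)
    genes <- genes[match(gene_ids, genes$gene_id), ]
  }
  purrr::pmap_dfr(genes[c("gene_id", "start", "end", "strand")],
    function(gene_id, start, end, strand) {
      if (strand == "+") {
        w_start <- start - upstream; w_end <- start + downstream
      } else {
        w_start <- end - downstream; w_end <- end + upstream
      }
      sl <- slice_sequence(genome$sequence, w_start, w_end, genome$circular)
      seq <- if (strand == "-" && nzchar(sl$seq)) revcomp(sl$seq) else sl$seq
      tibble::tibble(genome_id = genome$genome_id, gene_id = gene_id,
                     start = max(w_start, if (genome$circular) w_start else 0L),
                     end = min(w_end, if (genome$circular) w_end else nchar(genome$sequence)),
                     strand = strand, seq = seq, truncated = sl$truncated,
                     off_contig = !nzchar(seq))
    })
}
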