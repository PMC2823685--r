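#' Configuration for the synthetic genome-panel generator
#'
#' Defaults emulate the study conditions of a small actinobacterial panel:
#' 10 genomes, 80% of which carry the zinc-uptake regulon; order-1 Markov
#' background at 54% GC (high-GC, C. glutamicum-like); the regulon laid out
#' as in the C. glutamicum genome ("table1_layout": a three-gene operon in
#' divergence with a singleton across a 29-bp gap sharing one site, a
#' second three-gene operon with one upstream site, and a divergent
#' head-to-head pair with two sites in a 118-bp gap); one site per
#' transcription unit, sampled from the motif model conditional on scoring
#' at or above its threshold; regulon genes carry a true expression fold of
#' 4.
#'
#' @param n_genomes Number of genomes in the panel.
#' @param regulon_fraction Fraction of genomes carrying the regulon.
#' @param n_background_genes Background (non-regulon) genes per genome.
#' @param gene_length,intergenic Background gene length and spacing in bp.
#' @param gc Background GC content (order-1 Markov stationary composition).
#' @param motif Planting motif model; default [cgl_zur_motif()].
#' @param template Regulon layout template: `"table1_layout"`,
#'   `"operon3"`, `"divergent_pair"`, `"head_to_head"`, or `"singleton"`.
#' @param regulon_fold True expression fold of regulon genes.
#' @param n_decoy_sites Motif-sampled decoy sites planted upstream of
#'   randomly chosen background genes (one genome each); these are the
#'   false positives the consistency check is meant to remove.
#' @param seed Mandatory integer seed.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_genomes = 10, regulon_fraction = 0.8,
                         n_background_genes = 30, gene_length = 900,
                         intergenic = 150, gc = 0.54, motif = NULL,
                         template = "table1_layout", regulon_fold = 4,
                         n_decoy_sites = 0, seed) {
  if (missing(seed)) stop("panel_config() requires a seed", call. = FALSE)
  stopifnot(regulon_fraction >= 0, regulon_fraction <= 1, gc > 0, gc < 1)
  structure(list(n_genomes = n_genomes, regulon_fraction = regulon_fraction,
                 n_background_genes = n_background_genes,
                 gene_length = gene_length, intergenic = intergenic, gc = gc,
                 motif = motif %||% cgl_zur_motif(), template = template,
                 regulon_fold = regulon_fold, n_decoy_sites = n_decoy_sites,
                 seed = as.integer(seed)),
            class = "panel_config")
}

# Order-1 Markov background with stationary composition set by GC.
markov_sequence <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  # iid draws form a valid order-1 chain with rows equal to the stationary
  # distribution; kept as the default background
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# Draw one site from the model's pseudocounted column frequencies,
# rejecting draws below the model threshold (observed sites are by
# construction detectable at the study threshold).
sample_site <- function(model, max_tries = 1000) {
  f <- column_freqs(model)
  for (i in seq_len(max_tries)) {
    s <- paste(vapply(seq_len(model$width),
                      function(k) sample(DNA_BASES, 1, prob = f[, k]), ""),
               collapse = "")
    if (is.na(model$threshold) || score_sites(model, s)$z >= model$threshold) {
      return(s)
    }
  }
  stop("could not sample a site above the model threshold", call. = FALSE)
}

splice_in <- function(sequence, position, insert) {
  # overwrite (not insert) so downstream coordinates stay fixed
  paste0(substr(sequence, 1, position), insert,
         substr(sequence, position + nchar(insert) + 1, nchar(sequence)))
}

# One regulon cassette: returns gene rows (coordinates relative to the
# cassette start), site placements, and the cassette length. Gene ids are
# the canonical C. glutamicum-style names so truth tables are readable.
regulon_cassette <- function(template, gene_length, motif_width = 21) {
  L <- gene_length; cur <- 0
  genes <- list(); sites <- integer()
  add_gene <- function(id, len, strand) {
    genes[[length(genes) + 1]] <<- tibble::tibble(
      gene_id = id, start = cur, end = cur + len, strand = strand)
    cur <<- cur + len
  }
  gap <- function(n) cur <<- cur + n
  site_at <- function(offset_in_gap, gap_len) {
    sites <<- c(sites, cur + offset_in_gap)
    gap(gap_len)
  }
  if (template %in% c("table1_layout", "operon3")) {
    if (template == "table1_layout") {
      # three-gene operon on the minus strand read right-to-left, then a
      # 29-bp gap with one shared site, then the divergent singleton
      add_gene("zA", L, "-"); gap(20)
      add_gene("zB", L, "-"); gap(20)
      add_gene("zC", L, "-")
      site_at(4, 29)                       # 21-mer centred in the 29-bp gap
      add_gene("zD", L, "+")
      gap(400)
    }
    # co-directional operon, one site ~40 bp upstream of the lead gene
    site_at(0, 40 + motif_width)
    add_gene("zE", L, "+"); gap(20)
    add_gene("zF", L, "+"); gap(20)
    add_gene("zG", L, "+")
    if (template == "table1_layout") {
      gap(400)
      # head-to-head divergent pair, two sites in a 118-bp gap
      add_gene("zH", L, "-")
      sites <- c(sites, cur + 15, cur + 82)
      gap(118)
      add_gene("zI", L, "+")
    }
  } else if (template == "divergent_pair") {
    add_gene("zC", L, "-"); site_at(4, 29); add_gene("zD", L, "+")
  } else if (template == "head_to_head") {
    add_gene("zH", L, "-")
    sites <- c(sites, cur + 15, cur + 82); gap(118)
    add_gene("zI", L, "+")
  } else if (template == "singleton") {
    site_at(0, 40 + motif_width); add_gene("zE", L, "+")
  } else {
    stop("unknown template: ", template, call. = FALSE)
  }
  list(genes = dplyr::bind_rows(genes), site_offsets = sites, length = cur)
}

#' Simulate a ground-truthed genome panel
#'
#' Generates `n_genomes` genomes of Markov background sequence with
#' orthologous background genes, plants the regulon cassette (genes plus
#' motif-sampled sites) in the configured fraction of genomes, optionally
#' sprinkles decoy sites upstream of random background genes, and returns
#' the matching orthology table and ground truth.
#'
#' @param config A [panel_config()].
#' @return List of class `synthetic_panel`: `panel` (named list of
#'   `genome`s), `orthology` (tibble), `truth` (list with `sites` tibble
#'   `genome_id`, `position`, `strand`, `sequence`, `decoy`; `members`
#'   tibble `genome_id`, `tu`, `gene_id`; `expression` tibble `gene_id`,
#'   `fold` for the first regulon-bearing genome), and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  withr::with_seed(config$seed, simulate_panel_impl(config))
}

simulate_panel_impl <- function(config) {
  model <- config$motif
  W <- model$width
  n_reg <- round(config$regulon_fraction * config$n_genomes)
  carries <- seq_len(config$n_genomes) <= n_reg
  cassette <- regulon_cassette(config$template, config$gene_length, W)
  tu_of <- c(zA = "zC", zB = "zC", zC = "zC", zD = "zD",
             zE = "zE", zF = "zE", zG = "zE", zH = "zH", zI = "zI")

  panel <- list(); truth_sites <- list(); truth_members <- list(); ortho <- list()
  for (g in seq_len(config$n_genomes)) {
    gid <- sprintf("genome_%02d", g)
    half <- config$n_background_genes %/% 2
    unit <- config$gene_length + config$intergenic
    pre_len <- half * unit + config$intergenic
    post_n <- config$n_background_genes - half
    cass_len <- if (carries[g]) cassette$length + config$intergenic else 0
    total <- pre_len + cass_len + post_n * unit + config$intergenic
    seqs <- markov_sequence(total, config$gc)

    bg_start <- c(seq_len(half) - 1, half + seq_len(post_n) - 1) * unit +
      config$intergenic
    bg_start[(half + 1):(half + post_n)] <- bg_start[(half + 1):(half + post_n)] + cass_len
    bg <- tibble::tibble(gene_id = sprintf("%s_bg%03d", gid, seq_len(config$n_background_genes)),
                         start = as.integer(bg_start),
                         end = as.integer(bg_start + config$gene_length),
                         strand = "+",  # co-directional: each intergenic gap lies in exactly one upstream window
                         family = sprintf("fam_bg%03d", seq_len(config$n_background_genes)))
    genes <- bg
    if (carries[g]) {
      cg <- cassette$genes |>
        dplyr::mutate(family = paste0("fam_", .data$gene_id),
                      tu = tu_of[.data$gene_id],
                      gene_id = paste0(gid, "_", .data$gene_id),
                      start = .data$start + pre_len,
                      end = .data$end + pre_len)
      for (off in cassette$site_offsets) {
        s <- sample_site(model)
        pos <- off + pre_len
        seqs <- splice_in(seqs, pos, s)
        truth_sites[[length(truth_sites) + 1]] <- tibble::tibble(
          genome_id = gid, position = as.integer(pos), strand = "+",
          sequence = s, decoy = FALSE)
      }
      truth_members[[length(truth_members) + 1]] <- tibble::tibble(
        genome_id = gid, tu = paste0(gid, "_", cg$tu),
        gene_id = cg$gene_id)
      genes <- dplyr::bind_rows(bg, dplyr::select(cg, -"tu"))
    }
    ortho[[g]] <- tibble::tibble(family_id = genes$family, genome_id = gid,
                                 gene_id = genes$gene_id)
    panel[[gid]] <- new_genome(gid, seqs, dplyr::select(genes, -"family"))
  }

  # decoys: one site upstream of a random background '+' gene, one genome each
  if (config$n_decoy_sites > 0) {
    if (config$n_decoy_sites > config$n_background_genes) {
      stop("n_decoy_sites cannot exceed n_background_genes", call. = FALSE)
    }
    # decoys are uncorrelated false positives: one per background family,
    # each in a single random genome (recurrent orthologous hits would be
    # indistinguishable from real conserved regulation)
    pick <- tibble::tibble(g = sample.int(config$n_genomes, config$n_decoy_sites,
                                          replace = TRUE),
                           b = sample.int(config$n_background_genes,
                                          config$n_decoy_sites))
    for (i in seq_len(nrow(pick))) {
      gid <- sprintf("genome_%02d", pick$g[i])
      gobj <- panel[[gid]]
      gene <- gobj$genes[gobj$genes$gene_id == sprintf("%s_bg%03d", gid, pick$b[i]), ]
      pos <- gene$start - 40 - W
      if (pos < 0) next
      s <- sample_site(model)
      gobj$sequence <- splice_in(gobj$sequence, pos, s)
      panel[[gid]] <- gobj
      truth_sites[[length(truth_sites) + 1]] <- tibble::tibble(
        genome_id = gid, position = as.integer(pos), strand = "+",
        sequence = s, decoy = TRUE)
    }
  }

  members <- dplyr::bind_rows(truth_members)
  first_reg <- if (n_reg > 0) sprintf("genome_%02d", 1) else NA_character_
  expression <- if (n_reg > 0) {
    g1 <- panel[[first_reg]]$genes$gene_id
    tibble::tibble(gene_id = g1,
                   fold = ifelse(g1 %in% members$gene_id[members$genome_id == first_reg],
                                 config$regulon_fold, 1))
  } else NULL
  structure(list(panel = panel,
                 orthology = dplyr::bind_rows(ortho),
                 truth = list(sites = dplyr::bind_rows(truth_sites),
                              members = members, expression = expression),
                 config = config),
            class = "synthetic_panel")
}

#' Simulate dye-swap two-colour microarray spot intensities
#'
#' Per gene, `n_spots` spots on each of `n_arrays` arrays (dye orientations
#' alternating, emulating label swapping). Reference intensities are
#' lognormal; test intensities multiply in the true fold; both channels
#' receive multiplicative lognormal noise (`noise_sd` on the log2 scale,
#' per channel), and an optional intensity-dependent dye bias `dye_bias(a)`
#' is added to m in the direction of the dye carrying the test sample.
#'
#' @param expression Tibble `gene_id`, `fold` (true fold changes, > 0).
#' @param n_spots Spots per gene per array.
#' @param n_arrays Number of arrays (dye orientation alternates).
#' @param noise_sd Per-channel lognormal noise sd (log2 scale).
#' @param dye_bias Optional function of `a` returning the m-scale bias.
#' @param base_log2 Mean log2 reference intensity.
#' @param seed Integer seed.
#' @return Spot tibble: `gene_id`, `array_id`, `spot`, `dye_orientation`
#'   (`"test_cy5"`/`"test_cy3"`), `intensity_test`, `intensity_ref`.
#' @export
simulate_microarray <- function(expression, n_spots = 4, n_arrays = 2,
                                noise_sd = 0.25, dye_bias = NULL,
                                base_log2 = 11, seed) {
  stopifnot(all(expression$fold > 0))
  if (missing(seed)) stop("simulate_microarray() requires a seed", call. = FALSE)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(gene_id = expression$gene_id,
                               array_id = seq_len(n_arrays),
                               spot = seq_len(n_spots)) |>
      dplyr::left_join(expression, by = "gene_id") |>
      dplyr::mutate(dye_orientation = ifelse(.data$array_id %% 2 == 1,
                                             "test_cy5", "test_cy3"))
    n <- nrow(grid)
    ref <- 2^(base_log2 + stats::rnorm(n, 0, 1) + stats::rnorm(n, 0, noise_sd))
    test <- ref * grid$fold * 2^(stats::rnorm(n, 0, noise_sd) -
                                   stats::rnorm(n, 0, noise_sd))
    if (!is.null(dye_bias)) {
      a <- 0.5 * log2(test * ref)
      dir <- ifelse(grid$dye_orientation == "test_cy5", 1, -1)
      test <- test * 2^(dir * dye_bias(a) / 2)
      ref <- ref * 2^(-dir * dye_bias(a) / 2)
    }
    dplyr::mutate(grid, intensity_test = test, intensity_ref = ref,
                  fold = NULL)
  })
}

#' Simulate qPCR crossing points
#'
#' `CP_test = CP_control - log2(fold) + noise`: each doubling of transcript
#' advances the crossing point by one cycle.
#'
#' @param expression Tibble `gene_id`, `fold` (> 0).
#' @param replicates Replicates per condition.
#' @param cp_noise_sd Additive CP noise sd (cycles).
#' @param base_cp Mean control crossing point.
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `condition`, `replicate`, `cp`, ready for
#'   [rtpcr_fold_change()].
#' @export
simulate_rtpcr <- function(expression, replicates = 4, cp_noise_sd = 0.2,
                           base_cp = 20, seed) {
  stopifnot(all(expression$fold > 0))
  if (missing(seed)) stop("simulate_rtpcr() requires a seed", call. = FALSE)
  withr::with_seed(seed, {
    tidyr::expand_grid(gene_id = expression$gene_id,
                       condition = c("control", "test"),
                       replicate = seq_len(replicates)) |>
      dplyr::left_join(expression, by = "gene_id") |>
      dplyr::mutate(cp = base_cp -
                      ifelse(.data$condition == "test", log2(.data$fold), 0) +
                      stats::rnorm(dplyr::n(), 0, cp_noise_sd),
                    fold = NULL)
  })
}

#' The C. glutamicum regulon-layout fixture genome
#'
#' A single synthetic genome reproducing the regulatory geometry of the
#' *C. glutamicum* Zur regulon with the five published 21-mers planted at
#' their canonical placements: the `cg0042` operon in divergence with
#' `cg0043` across a 29-bp gap sharing one site, the `cg2911` operon with
#' one upstream site, and the `cg0794`/`cg0795` head-to-head pair with two
#' sites in a 118-bp gap. Gene ids use the canonical locus tags.
#'
#' @param seed Seed for the background sequence.
#' @param gene_length,gc As in [panel_config()].
#' @return A `genome` object with attribute `"truth"` (tibble of planted
#'   site positions and sequences).
#' @export
cgl_fixture_genome <- function(seed = 1, gene_length = 900, gc = 0.54) {
  cassette <- regulon_cassette("table1_layout", gene_length)
  rename <- c(zA = "cg0040", zB = "cg0041", zC = "cg0042", zD = "cg0043",
              zE = "cg2911", zF = "cg2912", zG = "cg2913",
              zH = "cg0794", zI = "cg0795")
  planted <- c("TAATGATAACGGTTATCATTT",  # shared cg0042/cg0043 site
               "TGTTGACATCCTTTTTCAATA",  # cg2911
               "TATTGAAAATGATTCCCAAAA",  # cg0794
               "TAATGGAAATTGTTTTCAATA")  # cg0795
  withr::with_seed(seed, {
    pad <- 300
    seqs <- markov_sequence(cassette$length + 2 * pad, gc)
    for (i in seq_along(cassette$site_offsets)) {
      seqs <- splice_in(seqs, cassette$site_offsets[i] + pad, planted[i])
    }
    genes <- cassette$genes |>
      dplyr::mutate(gene_id = rename[.data$gene_id],
                    start = .data$start + pad, end = .data$end + pad)
    g <- new_genome("cgl_fixture", seqs, genes)
    attr(g, "truth") <- tibble::tibble(position = cassette$site_offsets + pad,
                                       sequence = planted)
    g
  })
}
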