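test_that("a planted published site is found exactly once at its position", {
  m <- cgl_zur_motif()
  seq <- paste0(strrep("A", 20), "TAATGATAACGGTTATCATTT", strrep("A", 20))
  hits <- scan_sequence(m, seq)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 20L)
  expect_equal(hits$strand, "+")
  expect_identical(hits$sequence, "TAATGATAACGGTTATCATTT")
  # all-N sequence yields nothing
  expect_equal(nrow(scan_sequence(m, strrep("N", 100))), 0)
})

test_that("scan output equals brute-force window enumeration on random sequences", {
  m <- cgl_zur_motif()
  wts <- brute_weights(published_sites())
  # permissive threshold so both implementations report many windows
  thr <- 10
  set.seed(1234)
  for (i in 1:20) {
    seq <- random_dna(2000)
    fast <- scan_sequence(m, seq, threshold = thr)
    slow <- brute_scan(wts, seq, threshold = thr)
    expect_equal(fast$position, slow$position)
    expect_equal(fast$z, slow$z, tolerance = 1e-9)
  }
})

test_that("scanning the reverse complement of a genome mirrors the site list", {
  m <- cgl_zur_motif()
  g <- cgl_fixture_genome(seed = 2)
  fwd <- scan_sequence(m, g$sequence)
  rev <- scan_sequence(m, rc_chr(g$sequence))
  L <- nchar(g$sequence)
  expect_equal(sort(L - 21 - rev$position), sort(fwd$position))
  expect_equal(sort(rev$z), sort(fwd$z), tolerance = 1e-12)
})

test_that("raising the threshold never adds sites", {
  m <- cgl_zur_motif()
  g <- cgl_fixture_genome(seed = 3)
  lo <- scan_sequence(m, g, threshold = m$threshold - 5)
  hi <- scan_sequence(m, g, threshold = m$threshold + 1)
  expect_true(all(hi$position %in% lo$position))
  expect_gte(nrow(lo), nrow(hi))
})

test_that("site assignment covers divergent sharing and drops distal sites", {
  # divergent pair separated by a 29-bp gap with one centred site
  gap_start <- 500L
  genes <- data.frame(gene_id = c("left", "right"),
                      start = c(200L, gap_start + 29L),
                      end = c(gap_start, gap_start + 329L),
                      strand = c("-", "+"))
  set.seed(6)
  g <- toy_genome(random_dna(900), genes)
  site <- tibble::tibble(genome_id = "toy", position = gap_start + 4L,
                         strand = "+", sequence = strrep("A", 21), z = 30)
  asg <- assign_sites_to_genes(site, g)
  expect_setequal(asg$gene_id, c("left", "right"))
  # offsets measured to each gene's translation start, negative upstream
  expect_equal(asg$offset[asg$gene_id == "left"], (gap_start - 1L) - (gap_start + 14L))
  expect_equal(asg$offset[asg$gene_id == "right"], (gap_start + 14L) - (gap_start + 29L))

  # a site 500 bp upstream of the only gene is dropped
  far <- tibble::tibble(genome_id = "toy", position = 0L, strand = "+",
                        sequence = strrep("A", 21), z = 30)
  g2 <- toy_genome(random_dna(900),
                   data.frame(gene_id = "only", start = 520L, end = 800L, strand = "+"))
  expect_message(dropped <- assign_sites_to_genes(far, g2), "dropped")
  expect_equal(nrow(dropped), 0)

  # head-to-head pair, 118-bp gap, two sites: both covered by both windows
  g3 <- toy_genome(random_dna(1200),
                   data.frame(gene_id = c("h1", "h2"),
                              start = c(100L, 618L), end = c(500L, 1000L),
                              strand = c("-", "+")))
  sites3 <- tibble::tibble(genome_id = "toy", position = c(515L, 582L),
                           strand = "+", sequence = strrep("A", 21), z = 30)
  asg3 <- assign_sites_to_genes(sites3, g3)
  expect_equal(nrow(asg3), 4)
  expect_equal(sort(table(asg3$gene_id)), sort(c(h1 = 2L, h2 = 2L)), ignore_attr = TRUE)
})

test_that("operon chaining follows gaps and strand breaks", {
  mk <- function(starts, ends, strands) {
    toy_genome(strrep("A", max(ends) + 10),
               data.frame(gene_id = sprintf("g%d", seq_along(starts)),
                          start = starts, end = ends, strand = strands))
  }
  # gaps 10 and 20 at operon_gap 100: one unit of three genes
  tu <- build_transcription_units(mk(c(0, 110, 230), c(100, 210, 330), rep("+", 3)), 100)
  expect_equal(dplyr::n_distinct(tu$tu_id), 1)
  expect_equal(tu$lead_gene, rep("g1", 3))
  expect_equal(tu$tu_order, 1:3)
  # gaps 10 and 150: units of sizes 2 and 1
  tu2 <- build_transcription_units(mk(c(0, 110, 360), c(100, 210, 460), rep("+", 3)), 100)
  expect_equal(sort(as.vector(table(tu2$tu_id))), c(1L, 2L))
  # convergent genes never chain
  tu3 <- build_transcription_units(mk(c(0, 110), c(100, 210), c("+", "-")), 100)
  expect_equal(dplyr::n_distinct(tu3$tu_id), 2)
  # minus-strand unit is led by its 5'-most (rightmost) gene
  tu4 <- build_transcription_units(mk(c(0, 110, 230), c(100, 210, 330), rep("-", 3)), 100)
  expect_equal(unique(tu4$lead_gene), "g3")
  expect_equal(tu4$gene_id[tu4$tu_order == 1], "g3")
})

test_that("consistency support counts other genomes only (toy-panel regression)", {
  members <- tibble::tibble(
    genome_id = c("g1", "g2", "g3"),
    tu_id = "tu_x", gene_id = c("a1", "a2", "a3"),
    direct_site = c(TRUE, TRUE, FALSE))
  ortho <- tibble::tibble(family_id = "F", genome_id = c("g1", "g2", "g3"),
                          gene_id = c("a1", "a2", "a3"))
  # K = 0: identity
  k0 <- consistency_filter(members, ortho, min_support = 0)
  expect_equal(nrow(k0), 3)
  # K = 1: the two site-carrying genomes support each other; g3 has no site
  # and its row records support 2 but that row is a candidate anyway
  k1 <- consistency_filter(members, ortho, min_support = 1)
  expect_true(all(c("g1", "g2") %in% k1$genome_id))
  expect_equal(k1$consistency_support[k1$genome_id == "g1"], 1L)
  # K = 2: each site-carrier is supported by only ONE other genome -> removed
  k2 <- consistency_filter(members, ortho, min_support = 2)
  expect_false(any(c("g1", "g2") %in% k2$genome_id))
  # unknown gene warns and yields support 0
  expect_warning(
    out <- consistency_filter(
      dplyr::mutate(members, gene_id = c("zz", "a2", "a3")), ortho, 0),
    "absent from the orthology")
  expect_equal(out$consistency_support[out$gene_id == "zz"], 0L)
})

test_that("raising K never adds members; every member traces to a site via its unit", {
  sim <- simulate_panel(panel_config(seed = 5, n_genomes = 6,
                                     n_background_genes = 12, n_decoy_sites = 6))
  m <- cgl_zur_motif()
  regs <- lapply(c(0, 1, 2, 4), function(k) {
    suppressWarnings(tidy(assemble_regulon(m, sim$panel, sim$orthology,
                                           min_support = k)))
  })
  for (i in 2:4) {
    expect_true(nrow(regs[[i]]) <= nrow(regs[[i - 1]]))
    expect_equal(nrow(dplyr::anti_join(regs[[i]], regs[[i - 1]],
                                       by = c("genome_id", "gene_id"))), 0)
  }
  # conservation: every unit with members has at least one direct-site gene
  per_tu <- regs[[3]] |>
    dplyr::group_by(genome_id, tu_id) |>
    dplyr::summarise(ok = any(evidence == "direct_site"), .groups = "drop")
  expect_true(all(per_tu$ok))
})

test_that("the regulon-layout fixture yields five units covering nine genes", {
  g <- cgl_fixture_genome(seed = 1)
  reg <- assemble_regulon(cgl_zur_motif(), g, min_support = 0)
  members <- tidy(reg)
  expect_equal(nrow(members), 9)
  expect_equal(dplyr::n_distinct(members$tu_id), 5)
  expect_setequal(members$gene_id,
                  c("cg0040", "cg0041", "cg0042", "cg0043", "cg0794",
                    "cg0795", "cg2911", "cg2912", "cg2913"))
  # the shared divergent site serves both cg0042 and cg0043
  shared <- reg$sites |> dplyr::filter(gene_id %in% c("cg0042", "cg0043"))
  expect_equal(dplyr::n_distinct(shared$position), 1)
  # an impossible threshold empties the table
  empty <- assemble_regulon(cgl_zur_motif(), g, min_support = 0, threshold = 1e6)
  expect_equal(nrow(tidy(empty)), 0)
})

test_that("BED6 export clamps scores and keeps coordinates half-open", {
  sites <- tibble::tibble(genome_id = "g", position = c(0L, 50L), strand = "+",
                          sequence = strrep("A", 21), z = c(-2, 35))
  path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  expect_equal(bed$X2, c(0, 50))
  expect_equal(bed$X3, c(21, 71))
  expect_equal(bed$X5, c(0, 1000))
})
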