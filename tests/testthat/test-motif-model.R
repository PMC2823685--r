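test_that("weights are centred log counts; hand-computed single-column case", {
  # two identical 1-bp 'sites' with pseudocount 0.5: column counts A=4
  # after palindromic symmetrisation are awkward at width 1, so use a
  # non-palindromic model where counts are forced: four sites 'A'
  m <- build_motif(c("AG", "AG", "AG", "AG"), palindromic = FALSE, pseudocount = 0.5)
  expect_equal(unname(m$counts["A", 1]), 4)
  expected_wA <- log(4.5) - mean(log(c(4.5, 0.5, 0.5, 0.5)))
  expected_wC <- log(0.5) - mean(log(c(4.5, 0.5, 0.5, 0.5)))
  expect_equal(unname(m$weights["A", 1]), expected_wA, tolerance = 1e-12)
  expect_equal(unname(m$weights["C", 1]), expected_wC, tolerance = 1e-12)
  expect_equal(unname(m$weights["G", 1]), unname(m$weights["C", 1]))
})

test_that("every column of the published-site model sums to zero and matches the brute-force oracle", {
  m <- build_motif(published_sites(), palindromic = TRUE, pseudocount = 0.5)
  expect_equal(max(abs(colSums(m$weights))), 0, tolerance = 1e-9)
  expect_equal(m$width, 21)
  # value computed by the independent brute-force scorer, frozen
  z <- score_sites(m, "TGTTGACATCCTTTTTCAATA")$z
  expect_equal(z, 27.8347125611, tolerance = 1e-9)
  # full oracle agreement on all five training sites
  wts <- brute_weights(published_sites())
  for (s in published_sites()) {
    expect_equal(score_sites(m, s)$z, brute_score(wts, s), tolerance = 1e-9)
  }
})

test_that("palindromic scoring is exactly strand-symmetric", {
  m <- build_motif(published_sites(), palindromic = TRUE)
  # the two divergently-shared published sites are reverse complements
  expect_identical(rc_chr("TAATGATAACGGTTATCATTT"), "AAATGATAACCGTTATCATTA")
  expect_identical(score_sites(m, "TAATGATAACGGTTATCATTT")$z,
                   score_sites(m, "AAATGATAACCGTTATCATTA")$z)
  # weight matrix satisfies the dyad constraint w(b,k) = w(comp(b), W-1-k)
  expect_equal(m$weights, m$weights[4:1, 21:1], ignore_attr = TRUE)
  # property: 1000 random 21-mers score identically to their reverse complements
  set.seed(17)
  for (i in 1:1000) {
    s <- random_dna(21)
    expect_identical(score_sites(m, s)$z, score_sites(m, rc_chr(s))$z)
  }
})

test_that("ambiguity codes score -Inf; degenerate two-site model peaks at its site", {
  m <- build_motif(published_sites())
  expect_identical(score_sites(m, "NGTTGACATCCTTTTTCAATA")$z, -Inf)
  m2 <- build_motif(c("ACGTA", "ACGTA"), palindromic = FALSE, pseudocount = 0.5)
  expect_identical(as.character(consensus(m2)), "ACGTA")
  # its own site is the per-column argmax, hence the global maximum
  set.seed(4)
  others <- vapply(1:200, function(i) random_dna(5), "")
  expect_true(all(score_sites(m2, "ACGTA")$z >= score_sites(m2, others)$z))
})

test_that("training-derived threshold never rejects a training site and is monotone", {
  m <- set_threshold_from_training(build_motif(published_sites()))
  z <- score_sites(m, published_sites())$z
  expect_true(all(z >= m$threshold))
  expect_equal(min(z), m$threshold)
  # single-site threshold equals that site's score (non-palindromic, 2 copies)
  m1 <- set_threshold_from_training(
    build_motif(c("ACGTT", "ACGTT"), palindromic = FALSE))
  expect_equal(m1$threshold, score_sites(m1, "ACGTT")$z)
  # adding a weaker site to the training set cannot raise the threshold
  weak <- "AAAAAAAAAAAAAAAAAAAAA"
  m_plus <- set_threshold_from_training(
    build_motif(c(published_sites(), weak)))
  expect_lt(m_plus$threshold, m$threshold)
})

test_that("build_motif rejects malformed training input", {
  expect_error(build_motif(c("ACGT", "ACGTA"), palindromic = FALSE), "lengths")
  expect_error(build_motif(c("ACNTA", "ACGTA"), palindromic = FALSE), "training site")
  expect_error(build_motif("ACGTA"), "length")
})

test_that("information content: uniform 0 bits, pure 2 bits, palindromic mirror symmetry", {
  mu <- build_motif(c("A", "C", "G", "T"), palindromic = FALSE, pseudocount = 0.5)
  expect_equal(information_content(mu), 0, tolerance = 1e-12)
  mp <- build_motif(c("A", "A"), palindromic = FALSE)
  expect_equal(information_content(mp, pseudocount = 0), 2, tolerance = 1e-12)
  m <- build_motif(published_sites())
  ic <- information_content(m)
  expect_equal(ic, rev(ic), tolerance = 1e-12)
  lt <- logo_table(m)
  sums <- tapply(lt$freq, lt$position, sum)
  expect_equal(as.vector(sums), rep(1, 21), tolerance = 1e-12)
})

test_that("ranking of candidate sequences is invariant to the pseudocount at large counts", {
  set.seed(8)
  training <- vapply(1:200, function(i) {
    paste0(ifelse(runif(11) < 0.85, strsplit("TAATGATAACG", "")[[1]],
                  sample(c("A", "C", "G", "T"), 11, TRUE)), collapse = "")
  }, "")
  cands <- vapply(1:50, function(i) random_dna(11), "")
  zs <- sapply(c(0.25, 0.5, 1.0), function(pc) {
    m <- build_motif(training, palindromic = FALSE, pseudocount = pc)
    score_sites(m, cands)$z
  })
  # the ordering is stable up to near-ties: weight perturbations scale as
  # 1/N(b,k), so with 200 training sites only candidates separated by less
  # than ~1e-2 can swap
  rho <- cor(zs, method = "spearman")
  expect_true(all(rho > 0.998))
  expect_equal(which.max(zs[, 1]), which.max(zs[, 2]))
  expect_equal(which.max(zs[, 2]), which.max(zs[, 3]))
})

test_that("motif serialization round-trips and MEME minimal import converts at effective n", {
  dir <- withr::local_tempdir()
  m <- set_threshold_from_training(build_motif(published_sites()))
  write_motif(m, file.path(dir, "motif.tsv"))
  back <- read_motif(file.path(dir, "motif.tsv"))
  expect_equal(back$counts, m$counts, ignore_attr = TRUE)
  expect_equal(back$weights, m$weights, ignore_attr = TRUE)
  expect_equal(back$threshold, m$threshold)
  expect_identical(back$training_sites, m$training_sites)

  meme <- file.path(dir, "m.meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF test", "letter-probability matrix: alength= 4 w= 3 nsites= 10",
               " 0.5 0.2 0.2 0.1", " 0.1 0.1 0.1 0.7", " 0.25 0.25 0.25 0.25"),
             meme)
  mm <- read_meme_motif(meme)
  expect_equal(mm$width, 3L)
  expect_equal(unname(mm$counts["A", 1]), 5)
  expect_equal(unname(mm$counts["T", 2]), 7)
  expect_equal(max(abs(colSums(mm$weights))), 0, tolerance = 1e-9)
})

test_that("tidy/glance/autoplot provide the standard views of a motif model", {
  m <- set_threshold_from_training(build_motif(published_sites()))
  td <- tidy(m)
  expect_equal(nrow(td), 4 * 21)
  expect_named(td, c("position", "base", "count", "weight", "freq"))
  gl <- glance(m)
  expect_equal(gl$width, 21)
  expect_equal(gl$threshold, m$threshold)
  expect_s3_class(autoplot(m), "ggplot")
})
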