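test_that("m/a arithmetic and dye-swap symmetry", {
  spot <- tibble::tibble(gene_id = "g", array_id = 1,
                         intensity_test = 800, intensity_ref = 200)
  ma <- compute_ma(spot)
  expect_equal(ma$m, 2)
  expect_equal(ma$a, 0.5 * log2(160000))
  # equal intensities: m = 0
  expect_equal(compute_ma(dplyr::mutate(spot, intensity_ref = 800))$m, 0)
  # the dye-swapped replicate carries the same labelled intensities, so m
  # is unchanged after orientation resolution
  swapped <- dplyr::mutate(spot, dye_orientation = "test_cy3")
  expect_equal(compute_ma(swapped)$m, ma$m)
  # non-positive intensities are excluded with a message
  expect_message(out <- compute_ma(dplyr::mutate(spot, intensity_ref = 0)),
                 "excluded")
  expect_equal(nrow(out), 0)
})

test_that("LOWESS normalization removes intensity-dependent and constant bias", {
  withr::with_seed(7, {
    n <- 5000
    a <- runif(n, 7, 13)
    bias <- 0.5 * sin(a)
    spots <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n)), array_id = 1,
                            a = a, m = bias + rnorm(n, 0, 0.25))
    norm <- lowess_normalize(spots)
    # residual bias: what the smoother failed to remove
    expect_lt(median(abs((spots$m - bias) - norm$m)), 0.05)
    expect_identical(norm$a, spots$a)

    # bias-free data are left essentially untouched
    clean <- dplyr::mutate(spots, m = rnorm(n, 0, 0.25))
    norm2 <- lowess_normalize(clean)
    expect_lt(median(abs(norm2$m - clean$m)), 0.05)

    # a constant offset is absorbed entirely
    const <- dplyr::mutate(spots, m = 1)
    expect_equal(median(lowess_normalize(const)$m), 0, tolerance = 1e-6)
  })
  # too few spots: skipped with a warning, m unchanged
  small <- tibble::tibble(gene_id = "x", array_id = 1, a = 1:5, m = rep(2, 5))
  expect_warning(out <- lowess_normalize(small), "skipped")
  expect_equal(out$m, rep(2, 5))
})

test_that("replicate-significance filtering gates the fold-change call", {
  # 200 null genes set the array-wide spread; clear signal passes 8/8
  withr::with_seed(12, {
    null_spots <- tidyr::expand_grid(gene_id = sprintf("n%03d", 1:200), spot = 1:8) |>
      dplyr::mutate(array_id = ifelse(spot <= 4, 1, 2), m = rnorm(1600, 0, 0.3))
  })
  up_gene <- tibble::tibble(gene_id = "upg", spot = 1:8,
                            array_id = rep(1:2, each = 4), m = rep(2, 8))
  # mean m = 3 but only 5 of 8 spots individually significant -> filtered
  mixed <- tibble::tibble(gene_id = "mix", spot = 1:8,
                          array_id = rep(1:2, each = 4),
                          m = c(4.78, 4.78, 4.78, 4.78, 4.8, 0.01, -0.01, 0.01))
  calls <- call_differential(dplyr::bind_rows(null_spots, up_gene, mixed))
  expect_equal(calls$call[calls$gene_id == "upg"], "up")
  expect_equal(calls$n_significant[calls$gene_id == "upg"], 8)
  expect_equal(calls$n_significant[calls$gene_id == "mix"], 5)
  expect_equal(calls$call[calls$gene_id == "mix"], "filtered")
  expect_gt(calls$m_mean[calls$gene_id == "mix"], 1)
  # too few spots -> filtered
  tiny <- tibble::tibble(gene_id = "t", spot = 1:3, array_id = 1, m = 3)
  expect_equal(call_differential(dplyr::bind_rows(null_spots, tiny)) |>
                 dplyr::filter(gene_id == "t") |> dplyr::pull(call), "filtered")
  # calls are invariant to row permutation
  withr::with_seed(3, perm <- sample(nrow(null_spots)))
  c1 <- call_differential(dplyr::bind_rows(null_spots, up_gene))
  c2 <- call_differential(dplyr::bind_rows(null_spots[perm, ], up_gene))
  expect_equal(dplyr::arrange(c1, gene_id), dplyr::arrange(c2, gene_id))
})

test_that("published per-gene m values reproduce the reported regulation counts", {
  t1 <- cgl_zur_targets()
  t2 <- cgl_zur_other_de()
  pooled <- c(t1$m_array, t2$m_array)
  expect_equal(sum(de_call(pooled) == "up"), 23)
  expect_equal(sum(de_call(pooled) == "down"), 3)
  expect_setequal(t2$cds[de_call(t2$m_array) == "down"],
                  c("cg0045", "cg2261", "cg2925"))
  expect_equal(sum(de_call(t2$m_array) == "up"), 14)
  # inclusive cut-off: the m = 1.0 gene counts as up
  expect_equal(de_call(1.0), "up")
  # RT-PCR-confirmed secondary genes number 9
  expect_equal(sum(!is.na(t2$fold_rtpcr)), 9)
  # union of direct targets and confirmed secondary genes: 18 distinct genes
  union_genes <- union(t1$cds, t2$cds[!is.na(t2$fold_rtpcr)])
  expect_equal(length(union_genes), 18)
})

test_that("crossing-point fold changes follow 2^-dCP and compose multiplicatively", {
  mk <- function(d) tibble::tibble(gene_id = "g",
                                   condition = rep(c("test", "control"), each = 2),
                                   cp = c(20 + d, 20 + d, 20, 20))
  expect_equal(rtpcr_fold_change(mk(0))$fold_change, 1)
  expect_equal(rtpcr_fold_change(mk(-3))$fold_change, 8)
  expect_equal(rtpcr_fold_change(mk(1))$delta_cp, 1)
  # fold(a->c) = fold(a->b) * fold(b->c)
  ab <- rtpcr_fold_change(mk(-1.2))$fold_change
  bc <- rtpcr_fold_change(mk(-0.8))$fold_change
  ac <- rtpcr_fold_change(mk(-2.0))$fold_change
  expect_equal(ab * bc, ac, tolerance = 1e-12)
})

test_that("simulated crossing points recover a planted fold within noise bounds", {
  truth <- tibble::tibble(gene_id = "g1", fold = 50)
  ok <- vapply(1:200, function(i) {
    cp <- simulate_rtpcr(truth, replicates = 4, cp_noise_sd = 0.2, seed = 1000 + i)
    est <- rtpcr_fold_change(cp)$fold_change
    abs(est - 50) / 50 <= 0.25
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("target integration separates direct, indirect and the site-without-support case", {
  calls <- tibble::tibble(
    gene_id = c("cg0042", "cg2911", "cg1447", "cg0045", "adhA", "cg9999"),
    call = c("up", "up", "up", "down", "unchanged", "unchanged"))
  members <- tibble::tibble(gene_id = c("cg0042", "cg2911", "adhA"))
  rt <- tibble::tibble(gene_id = c("cg1447", "cg0042"), fold_change = c(25.8, 331))
  out <- integrate_targets(calls, members, rt)
  expect_equal(out$status[out$gene_id == "cg0042"], "direct")
  expect_equal(out$status[out$gene_id == "cg1447"], "indirect")
  expect_equal(out$status[out$gene_id == "cg0045"], "down")
  expect_equal(out$status[out$gene_id == "adhA"], "site_without_expression_support")
  expect_equal(out$status[out$gene_id == "cg9999"], "unchanged")
  expect_true(out$rtpcr_confirmed[out$gene_id == "cg1447"])
  expect_false(out$rtpcr_confirmed[out$gene_id == "cg2911"])

  # the published tables integrate to 9 direct targets in 5 units
  t1 <- cgl_zur_targets()
  direct <- integrate_targets(
    tibble::tibble(gene_id = t1$cds, call = de_call(t1$m_array)),
    tibble::tibble(gene_id = t1$cds))
  expect_equal(sum(direct$status == "direct"), 9)
  expect_equal(dplyr::n_distinct(t1$tu), 5)
})
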