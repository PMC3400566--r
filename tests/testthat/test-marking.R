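gene_row <- function(start_0based, end_0based, id = "g1", chrom = "chr1") {
  tibble::tibble(gene_id = id, chrom = chrom,
                 start = start_0based + 1L, end = end_0based,
                 strand = "+", length = end_0based - start_0based)
}

test_that("central segment arithmetic matches the 40% rule", {
  g <- gene_row(1000L, 2000L)   # [1000, 2000) half-open
  cs <- central_segment(g, marking_criterion(0.4))
  # expected central segment [1300, 1700) half-open = (1301, 1700) 1-based
  expect_equal(cs$start, 1301L)
  expect_equal(cs$end, 1700L)

  cs_full <- central_segment(g, marking_criterion(1))
  expect_equal(cs_full$start, g$start)
  expect_equal(cs_full$end, g$end)

  tiny <- gene_row(100L, 110L)  # 10 bp gene
  cs_tiny <- central_segment(tiny, marking_criterion(0.4))
  expect_gte(cs_tiny$end - cs_tiny$start + 1L, 4L)
})

test_that("marking follows central-segment overlap", {
  g <- gene_row(1000L, 2000L)
  dom_in <- tibble::tibble(chrom = "chr1", start = 1601L, end = 1900L)
  expect_true(call_marked_genes(g, dom_in)$marked)
  expect_equal(call_marked_genes(g, dom_in)$overlap_bp, 100L)

  dom_out <- tibble::tibble(chrom = "chr1", start = 1751L, end = 1900L)
  expect_false(call_marked_genes(g, dom_out)$marked)

  dom_all <- tibble::tibble(chrom = "chr1", start = 1L, end = 100000L)
  genes <- dplyr::bind_rows(lapply(1:5, function(i) {
    gene_row(i * 3000L, i * 3000L + 1500L, id = paste0("g", i))
  }))
  expect_true(all(call_marked_genes(genes, dom_all)$marked))
})

test_that("marking agrees with a per-base brute-force oracle", {
  set.seed(77)
  crit <- marking_criterion(0.4, 1L, 0)
  for (trial in 1:200) {
    gs <- sample(50:500, 1)
    ge <- gs + sample(20:400, 1)
    gene <- gene_row(gs, ge)
    n_dom <- sample(0:4, 1)
    doms <- tibble::tibble(
      chrom = "chr1",
      start = sample(1:600, n_dom, replace = TRUE))
    doms$end <- doms$start + sample(5:200, n_dom, replace = TRUE)
    got <- call_marked_genes(gene, doms, crit)$marked
    want <- brute_force_marked(gene, doms, crit)
    expect_equal(got, want,
                 info = sprintf("trial %d gene [%d,%d)", trial, gs, ge))
  }
})

test_that("marking is invariant to domain fragmentation", {
  set.seed(78)
  genes <- dplyr::bind_rows(lapply(1:20, function(i) {
    gene_row(i * 2000L, i * 2000L + 900L, id = paste0("g", i))
  }))
  dom <- tibble::tibble(chrom = "chr1", start = 4500L, end = 21000L)
  # split into abutting pieces
  cuts <- sort(sample(4600:20900, 15))
  pieces <- tibble::tibble(chrom = "chr1",
                           start = c(4500L, cuts + 1L),
                           end = c(cuts, 21000L))
  expect_equal(call_marked_genes(genes, dom)$marked,
               call_marked_genes(genes, pieces)$marked)
})

test_that("covered-fraction variant tightens the criterion", {
  g <- gene_row(1000L, 2000L)
  dom <- tibble::tibble(chrom = "chr1", start = 1601L, end = 1700L)  # 100 bp
  expect_true(call_marked_genes(g, dom)$marked)
  strict <- marking_criterion(0.4, 1L, min_covered_fraction = 0.5)
  expect_false(call_marked_genes(g, dom, strict)$marked)
})

test_that("venn partition enumerates all membership classes", {
  mm <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       A = c(TRUE, TRUE, FALSE),
                       B = c(FALSE, TRUE, FALSE),
                       C = c(FALSE, TRUE, TRUE))
  vp <- venn_partitions(mm, c("A", "B", "C"))
  expect_equal(nrow(vp), 7)
  expect_equal(vp$n[vp$class == "A"], 1)
  expect_equal(vp$n[vp$class == "A&B&C"], 1)
  expect_equal(vp$n[vp$class == "C"], 1)
  expect_equal(sum(vp$n), 3)
  expect_setequal(vp$gene_ids[vp$class == "A&B&C"][[1]], "g2")

  # identical sets: only the all-conditions class is nonempty
  mm2 <- tibble::tibble(gene_id = c("g1", "g2"), A = TRUE, B = TRUE)
  vp2 <- venn_partitions(mm2, c("A", "B"))
  expect_equal(vp2$n[vp2$class == "A&B"], 2)
  expect_equal(sum(vp2$n), 2)

  # disjoint sets: only singleton classes nonempty
  mm3 <- tibble::tibble(gene_id = c("g1", "g2"),
                        A = c(TRUE, FALSE), B = c(FALSE, TRUE))
  vp3 <- venn_partitions(mm3, c("A", "B"))
  expect_equal(vp3$n[vp3$class == "A&B"], 0)
  expect_equal(vp3$n[vp3$class == "A"], 1)
})

test_that("differential domains combine with marking into subtypes", {
  genes <- dplyr::bind_rows(
    gene_row(1000L, 2000L, "g1"),
    gene_row(5000L, 6000L, "g2"),
    gene_row(9000L, 9800L, "g3"))
  mm <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       D = c(FALSE, TRUE, TRUE),
                       `1h` = c(TRUE, TRUE, FALSE))
  dd <- tibble::tibble(
    chrom = "chr1",
    start = c(1301L, 5301L, 9200L), end = c(1700L, 5700L, 9500L),
    comparison = "1h_vs_D",
    direction = c("gain", "gain", "loss"))
  out <- combine_differential_with_marking(dd, genes, mm, "1h_vs_D")
  expect_equal(out$subtype[out$gene_id == "g1"], "de_novo")
  expect_equal(out$subtype[out$gene_id == "g2"], "increased")
  expect_equal(out$subtype[out$gene_id == "g3"], "complete_loss")

  # partition property: de_novo and increased are disjoint and cover gains
  gains <- out[out$direction == "gain", ]
  expect_setequal(gains$subtype, c("de_novo", "increased"))
  expect_equal(anyDuplicated(gains$gene_id), 0)

  empty <- combine_differential_with_marking(dd[0, ], genes, mm, "1h_vs_D")
  expect_equal(nrow(empty), 0)
  expect_error(
    combine_differential_with_marking(dd, genes, mm, "badlabel"),
    "unknown comparison")
})

test_that("length quantiles separate extremes and balance mid bins", {
  genes <- tibble::tibble(gene_id = paste0("g", 1:4),
                          length = c(500, 1500, 2500, 5000))
  lq <- length_quantiles(genes, 4, c(1000, 4000))
  expect_equal(lq$bin, c(1L, 2L, 3L, 4L))

  short <- tibble::tibble(gene_id = paste0("g", 1:5), length = 100:104)
  expect_true(all(length_quantiles(short, 8, c(1000, 3000))$bin == 1L))

  set.seed(5)
  many <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                         length = sample(1000:3000, 200, replace = TRUE))
  lq8 <- length_quantiles(many, 8, c(999, 3001))
  sizes <- table(lq8$bin)
  expect_lte(diff(range(sizes)), 1)
  expect_error(length_quantiles(many, 8, c(3000, 1000)), "lower <= upper")
})
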