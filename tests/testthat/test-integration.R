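test_that("gene mean levels average the overlapping tiles", {
  tiles <- tibble::tibble(tile_id = 1:6, chrom = "chr1",
                          start = c(100L, 300L, 500L, 2000L, 2200L, 5000L),
                          end = c(160L, 360L, 560L, 2060L, 2260L, 5060L))
  genes <- tibble::tibble(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                          start = c(90L, 1990L, 8000L),
                          end = c(600L, 2300L, 8500L),
                          strand = "+", length = c(511L, 311L, 501L))
  track <- tibble::tibble(tile_id = 1:6, score = c(1, 2, 3, 4, 6, 9))
  lv <- gene_mean_levels(list(D = track), genes, tiles)
  expect_equal(lv$level_D[lv$gene_id == "gA"], 2)
  expect_equal(lv$level_D[lv$gene_id == "gB"], 5)
  expect_false("gC" %in% lv$gene_id)  # no tiles -> excluded
  # identical tracks for two conditions give delta 0
  lv2 <- gene_mean_levels(list(D = track, `6h` = track), genes, tiles)
  expect_true(all(lv2$level_D == lv2$`level_6h`))
})

test_that("crosstab restricts the denominator before counting", {
  mm <- tibble::tibble(gene_id = sprintf("g%02d", 1:12),
                       `6h` = c(rep(TRUE, 8), rep(FALSE, 4)))
  response <- list(up_6h = sprintf("g%02d", 1:10))
  have_expr <- sprintf("g%02d", 1:12)
  ct <- crosstab_mark_by_response(
    response, gain_set = sprintf("g%02d", c(1:4, 11)),
    loss_set = character(0), mark_matrix = mm,
    marked_at = c(up_6h = "6h"), expression_universe = have_expr)
  gain_row <- ct[ct$class == "up_6h" & ct$category == "gain", ]
  # eligible = marked at 6h among the 10 up genes = 8; 4 of them gain
  expect_equal(gain_row$n_eligible, 8)
  expect_equal(gain_row$percent, 50)
  loss_row <- ct[ct$category == "loss", ]
  expect_equal(loss_row$percent, 0)
})

test_that("rank comparisons reproduce exact and degenerate cases", {
  rc <- rank_compare(list(x = c(1, 2, 3), y = c(4, 5, 6)))
  expect_equal(rc$p, 0.1)
  rc_same <- rank_compare(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(rc_same$p, 1)
  expect_error(rank_compare(list(x = 1:2, y = 1:5)), "n >= 3")
  # shift alternative: p decreases with shift
  set.seed(71)
  base <- rnorm(30)
  ps <- sapply(c(0.5, 1.5, 3), function(shift) {
    rank_compare(list(a = base, b = base + shift))$p
  })
  expect_true(all(diff(ps) < 0))
})

test_that("metagene recovers a planted central bump and normalizes to 1", {
  cfg <- tiny_cfg(noise_sd = 0.1, snr = 3, seed = 81, frac_marked = 1,
                  frac_gain_1h = 0, frac_gain_6h = 0, frac_loss_6h = 0)
  gen <- simulate_genome(cfg)
  tiles <- simulate_tiles(gen$genes, cfg)
  chip <- simulate_chip_signal(tiles, gen$genes, gen$truth, cfg)
  track <- combine_replicates(chip, "D")
  prof <- metagene(list(marked = gen$genes$gene_id), gen$genes, track,
                   tiles)
  expect_equal(max(prof$value_norm), 1)
  body <- prof[prof$bin >= 1 & prof$bin <= 100, ]
  peak_bin <- body$bin[which.max(body$value)]
  expect_gte(peak_bin, 35)
  expect_lte(peak_bin, 65)
  flank <- prof[prof$bin < 1 | prof$bin > 100, ]
  expect_lt(max(flank$value_norm), 0.25)
})

test_that("metagene flips antisense genes onto the 5'-to-3' axis", {
  # one gene, signal concentrated at the genomic left = 5' only on +
  tiles <- tibble::tibble(tile_id = 1:20, chrom = "chr1",
                          start = seq(1000L, by = 100L, length.out = 20))
  tiles$end <- tiles$start + 59L
  gene_plus <- tibble::tibble(gene_id = "gp", chrom = "chr1",
                              start = 1000L, end = 2999L, strand = "+",
                              length = 2000L)
  gene_minus <- gene_plus
  gene_minus$strand <- "-"
  track <- tibble::tibble(tile_id = 1:20,
                          score = c(rep(2, 5), rep(0, 15)))
  pp <- metagene(list(s = "gp"), gene_plus, track, tiles, flank_bp = 0)
  pm <- metagene(list(s = "gp"), gene_minus, track, tiles, flank_bp = 0)
  # + strand: signal in early body bins; - strand: late bins
  expect_lt(min(pp$bin[pp$value > 1]), 30)
  expect_gt(max(pm$bin[pm$value > 1]), 70)
})

test_that("delta scatter computes quadrant correlations and LOWESS", {
  set.seed(91)
  n <- 400
  dh <- rnorm(n)
  summary <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    delta_h2bub = dh,
    delta_expr = dh,                      # perfect correlation
    de_flag = ifelse(dh > 0, "up", "down"))
  ds <- delta_scatter(summary)
  pop <- ds$quadrants[!is.na(ds$quadrants$r), ]
  expect_true(all(abs(pop$r - 1) < 1e-9))
  expect_equal(nrow(ds$lowess), n)

  # independent deltas: small overall |r|
  rs <- sapply(1:10, function(s) {
    set.seed(s)
    sm <- tibble::tibble(gene_id = sprintf("g%04d", 1:2000),
                         delta_h2bub = rnorm(2000),
                         delta_expr = rnorm(2000),
                         de_flag = sample(c("up", "down", "ns"), 2000,
                                          replace = TRUE))
    abs(delta_scatter(sm)$overall$r[3])
  })
  expect_gte(mean(rs < 0.05), 0.9)
})

test_that("marked fractions per expression bin count correctly", {
  mm <- tibble::tibble(gene_id = paste0("g", 1:6),
                       D = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  bins <- tibble::tibble(gene_id = paste0("g", 1:6),
                         bin = c(1, 1, 1, 2, 2, 2))
  mf <- marked_fraction_by_expression(mm, bins, "D")
  expect_equal(mf$fraction[mf$bin == 1], 2 / 3)
  expect_equal(mf$fraction[mf$bin == 2], 1 / 3)
  all_marked <- mm
  all_marked$D <- TRUE
  expect_true(all(
    marked_fraction_by_expression(all_marked, bins, "D")$fraction == 1))
})

test_that("hypergeometric enrichment matches closed forms", {
  uni <- sprintf("g%02d", 1:20)
  se <- set_enrichment(uni[1:5], list(hit = uni[1:5]), uni)
  expect_equal(se$observed, 5)
  expect_equal(se$p_over, 1 / choose(20, 5))
  # target = set = universe: observed = expected, p = 1
  se2 <- set_enrichment(uni, list(all = uni), uni)
  expect_equal(se2$observed, se2$expected)
  expect_equal(se2$p_over, 1)
  expect_equal(se2$ratio, 1)
  expect_error(set_enrichment(uni[1:2], list(a = uni), character(0)),
               "non-empty")
  expect_error(set_enrichment(c("zz"), list(a = uni), uni), "subset")
})

test_that("candidate selection intersects the three criteria", {
  gain <- tibble::tibble(gene_id = c("g2", "g3", "g4"),
                         comparison = "6h_vs_D", direction = "gain",
                         subtype = c("de_novo", "increased", "de_novo"))
  cand <- select_candidates(c("g1", "g2", "g3"), gain, c("g3", "g4"))
  expect_equal(cand$gene_id, "g3")
  expect_equal(cand$subtypes, "increased")
  expect_equal(nrow(select_candidates(character(0), gain, c("g3"))), 0)
  # de-duplication across time points
  gain2 <- dplyr::bind_rows(gain, within(gain, comparison <- "1h_vs_D"))
  cand2 <- select_candidates(c("g3"), gain2, c("g3"))
  expect_equal(nrow(cand2), 1)
  expect_equal(cand2$comparisons, "1h_vs_D,6h_vs_D")
  # input order invariance
  cand3 <- select_candidates(c("g3", "g2", "g1"),
                             gain2[sample(nrow(gain2)), ], c("g4", "g3"))
  expect_identical(cand2$gene_id, cand3$gene_id)
})

test_that("marking recovery on synthetic data is sensitive and specific", {
  hits <- misses <- fps <- total_marked <- total_unmarked <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_genes = 150, n_chromosomes = 1,
                      chrom_length_bp = 8e5, snr = 3, noise_sd = 0.5,
                      seed = 200 + s)
    sim <- simulate_dataset(cfg)
    tracks <- combine_all_conditions(sim$chip)
    domains <- lapply(tracks, function(tr) {
      call_domains(tr, suppressWarnings(fit_hmm(tr)))
    })
    mm <- build_mark_matrix(sim$genes, domains)
    for (cond in cfg$conditions) {
      planted <- sim$truth[[paste0("marked_", cond)]]
      called <- mm[[cond]][match(sim$truth$gene_id, mm$gene_id)]
      hits <- hits + sum(called & planted)
      total_marked <- total_marked + sum(planted)
      fps <- fps + sum(called & !planted)
      total_unmarked <- total_unmarked + sum(!planted)
    }
  }
  expect_gte(hits / total_marked, 0.9)
  expect_lte(fps / total_unmarked, 0.05)
})
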