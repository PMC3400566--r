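test_that("empty and deterministic genome simulation", {
  cfg0 <- sim_config(n_genes = 0)
  gen0 <- simulate_genome(cfg0)
  expect_equal(nrow(gen0$genes), 0)
  expect_equal(nrow(gen0$truth), 0)

  cfg <- sim_config(n_genes = 100, chrom_length_bp = 1e6, seed = 42)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
})

test_that("genes are non-overlapping with >= 1 kb intergenic flanks", {
  cfg <- sim_config(n_genes = 200, seed = 11)
  gen <- simulate_genome(cfg)
  for (chrom in unique(gen$genes$chrom)) {
    g <- dplyr::arrange(gen$genes[gen$genes$chrom == chrom, ], start)
    expect_true(all(g$end <= cfg$chrom_length_bp))
    if (nrow(g) > 1) {
      gaps <- g$start[-1] - g$end[-nrow(g)] - 1
      expect_true(all(gaps >= 1000))
    }
  }
  expect_true(all(gen$genes$end > gen$genes$start))
})

test_that("overfull genome placement fails loudly", {
  cfg <- sim_config(n_genes = 500, n_chromosomes = 1,
                    chrom_length_bp = 1e5)
  expect_error(simulate_genome(cfg), "cannot place")
})

test_that("planted gain-1h frequency falls in its binomial 99% interval", {
  cfg <- sim_config(n_genes = 1000, n_chromosomes = 4,
                    chrom_length_bp = 2e6, frac_gain_1h = 0.1, seed = 5)
  gen <- simulate_genome(cfg)
  n_gain <- sum(gen$truth$category == "gain_1h")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(n_gain, ci[1])
  expect_lte(n_gain, ci[2])
})

test_that("transition categories obey the marking logic", {
  cfg <- sim_config(n_genes = 500, seed = 3)
  tt <- simulate_genome(cfg)$truth
  g1 <- tt[tt$category == "gain_1h", ]
  expect_true(all(!g1$marked_D & g1$`marked_1h` & g1$`marked_6h`))
  l6 <- tt[tt$category == "loss_6h", ]
  expect_true(all(l6$marked_D & l6$`marked_1h` & !l6$`marked_6h`))
  g6 <- tt[tt$category == "gain_6h", ]
  expect_true(all(!g6$marked_D & !g6$`marked_1h` & g6$`marked_6h`))
})

test_that("tile layout is sorted, non-overlapping, at the target density", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 11000, seed = 9)
  gen <- simulate_genome(sim_config(n_chromosomes = 1,
                                    chrom_length_bp = 11000, n_genes = 0))
  tiles <- simulate_tiles(gen$genes, cfg)
  # expectation ~ length / spacing = 100
  expect_gt(nrow(tiles), 80)
  expect_lt(nrow(tiles), 120)
  expect_true(all(diff(tiles$start) > 0))
  expect_true(all(tiles$start[-1] > tiles$end[-nrow(tiles)]))
  w <- tiles$end - tiles$start + 1
  expect_true(all(w >= cfg$tile_length_range[1] &
                    w <= cfg$tile_length_range[2]))
  expect_identical(tiles, simulate_tiles(gen$genes, cfg))
})

test_that("every gene >= 500 bp is overlapped by >= 3 tiles", {
  cfg <- sim_config(n_genes = 150, seed = 21)
  gen <- simulate_genome(cfg)
  tiles <- simulate_tiles(gen$genes, cfg)
  gr <- GenomicRanges::GRanges(gen$genes$chrom,
                               IRanges::IRanges(gen$genes$start,
                                                gen$genes$end))
  tg <- GenomicRanges::GRanges(tiles$chrom,
                               IRanges::IRanges(tiles$start, tiles$end))
  counts <- GenomicRanges::countOverlaps(gr, tg)
  expect_true(all(counts[gen$genes$length >= 500] >= 3))
})

test_that("noiseless chip signal reproduces the planted shape exactly", {
  cfg <- tiny_cfg(noise_sd = 0, snr = 2, seed = 7)
  gen <- simulate_genome(cfg)
  tiles <- simulate_tiles(gen$genes, cfg)
  chip <- simulate_chip_signal(tiles, gen$genes, gen$truth, cfg)
  r1 <- chip[chip$replicate == 1 & chip$condition == "D", ]
  r2 <- chip[chip$replicate == 2 & chip$condition == "D", ]
  expect_equal(r1$score, r2$score)  # dye-swap partner, noiseless

  marked <- gen$truth[gen$truth$marked_D, ]
  marked <- marked[order(-gen$genes$length[match(marked$gene_id,
                                                 gen$genes$gene_id)]), ]
  gene <- gen$genes[gen$genes$gene_id == marked$gene_id[1], ]
  sel <- r1[r1$chrom == gene$chrom & r1$start >= gene$start &
              r1$end <= gene$end, ]
  mid <- (sel$start + sel$end) / 2
  p <- (mid - gene$start) / gene$length
  # mid-gene tiles outscore 5' end tiles; max at peak
  expect_gt(sel$score[which.min(abs(p - 0.5))],
            sel$score[which.min(p)])
  expect_lte(max(sel$score), cfg$snr + 1e-12)
})

test_that("snr scales the planted marked-vs-unmarked signal difference", {
  cfg <- tiny_cfg(noise_sd = 0.3, snr = 2, seed = 13)
  gen <- simulate_genome(cfg)
  tiles <- simulate_tiles(gen$genes, cfg)
  chip <- simulate_chip_signal(tiles, gen$genes, gen$truth, cfg)
  gain1 <- gen$truth[gen$truth$category == "gain_1h", ]
  expect_gt(nrow(gain1), 0)
  gene <- gen$genes[gen$genes$gene_id == gain1$gene_id[1], ]
  per_cond <- function(cond) {
    sub <- chip[chip$condition == cond & chip$chrom == gene$chrom &
                  chip$start >= gene$start & chip$end <= gene$end, ]
    mean(sub$score)
  }
  # unmarked in D, marked at 1h: difference reflects planted enrichment
  expect_gt(per_cond("1h") - per_cond("D"), 0.5)
})

test_that("expression ratios carry the planted effects", {
  cfg <- tiny_cfg(expr_noise_sd = 0, seed = 17)
  gen <- simulate_genome(cfg)
  expr <- simulate_expression(gen$truth, cfg)
  up1 <- gen$truth$gene_id[gen$truth$expr_class == "up_1h"]
  expect_gt(length(up1), 0)
  m <- expr[expr$gene_id == up1[1] & expr$comparison == "wt_1h_vs_D", ]
  expect_equal(mean(m$log2_ratio), cfg$de_effect_log2)
  none <- gen$truth$gene_id[gen$truth$expr_class == "none"][1]
  m0 <- expr[expr$gene_id == none & expr$comparison == "wt_1h_vs_D", ]
  expect_equal(mean(m0$log2_ratio), 0)
})

test_that("full coupling puts every planted-up gene in the gain pool", {
  cfg <- sim_config(n_genes = 400, rho_gain_up = 1, frac_gain_1h = 0.15,
                    frac_gain_6h = 0.15, seed = 23)
  tt <- simulate_genome(cfg)$truth
  up <- tt[tt$expr_class %in% c("up_1h", "up_6h", "up_and_down"), ]
  expect_true(all(up$category %in% c("gain_1h", "gain_6h")))
})

test_that("up_and_down genes are planted transient", {
  cfg <- tiny_cfg(expr_noise_sd = 0, seed = 29, frac_up_and_down = 0.2)
  gen <- simulate_genome(cfg)
  expr <- simulate_expression(gen$truth, cfg)
  ud <- gen$truth$gene_id[gen$truth$expr_class == "up_and_down"]
  expect_gt(length(ud), 0)
  m1 <- mean(expr$log2_ratio[expr$gene_id == ud[1] &
                               expr$comparison == "wt_1h_vs_D"])
  m6 <- mean(expr$log2_ratio[expr$gene_id == ud[1] &
                               expr$comparison == "wt_6h_vs_D"])
  expect_equal(m1, cfg$de_effect_log2)
  expect_lt(m6 - m1, 0)
})
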