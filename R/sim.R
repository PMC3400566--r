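#' Simulation configuration for a synthetic de-etiolation study
#'
#' Builds the configuration object consumed by [simulate_genome()],
#' [simulate_tiles()], [simulate_chip_signal()] and [simulate_expression()]
#' (or the [simulate_dataset()] wrapper). Defaults emulate the study design:
#' NimbleGen-style tiles of 50-75 nt at ~110 nt average start-to-start
#' spacing, three conditions (dark, 1 h and 6 h of light), two dye-swap
#' replicate pairs per ChIP comparison, and CATMA-style per-gene log2
#' expression ratios for five comparisons (wt 1h/D, wt 6h/D, hub 1h/D,
#' hub 6h/D, hub-dark/wt-dark).
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length_bp length of each chromosome (bp)
#' @param n_genes number of genes placed over the genome
#' @param gene_length_median,gene_length_sigma log-normal transcribed-region
#'   length distribution (median in bp, sigma on the log scale)
#' @param tile_length_range integer range of tile lengths in bp
#' @param tile_spacing_mean mean start-to-start tile spacing in bp
#' @param conditions ordered condition labels (>= 2)
#' @param n_replicates ChIP replicates per condition (dye-swap pairs,
#'   simulated post-correction)
#' @param snr planted enrichment: peak mean minus background mean, log2 units
#' @param noise_sd per-tile Gaussian noise sd (log2 units) per replicate
#' @param frac_marked probability a gene is stably marked in all conditions
#' @param frac_gain_1h,frac_gain_6h,frac_loss_6h planted transition
#'   probabilities between conditions (gain at 1 h means unmarked in D and
#'   marked at 1 h and 6 h; loss at 6 h means marked in D and 1 h only)
#' @param domain_fraction central fraction of the transcribed region covered
#'   by a planted domain (default 0.8 so the central-40% marking rule falls
#'   strictly inside it)
#' @param shape_sd sd of the Gaussian positional profile of planted signal,
#'   in units of fractional gene position (peak at mid-gene)
#' @param de_effect_log2 planted differential-expression effect size
#' @param expr_noise_sd per-array sd of log2 expression ratios
#' @param frac_up_1h,frac_up_6h,frac_down_1h,frac_down_6h,frac_up_and_down
#'   planted light-response class probabilities (wild type)
#' @param rho_gain_up probability that a planted light-induced gene is drawn
#'   from the planted H2Bub-gain pool (chromatin/expression coupling)
#' @param frac_hub_defect probability a planted light-responsive gene has a
#'   damped response in the hub1-3 mutant
#' @param hub_defect_factor multiplier applied to the planted effect in the
#'   mutant for defective genes
#' @param frac_hub_dark_mimic probability a planted light-responsive gene is
#'   already shifted in the same direction in the mutant in darkness
#' @param seed RNG seed (integer)
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length_bp = 2e6,
                       n_genes = 1000,
                       gene_length_median = 1800,
                       gene_length_sigma = 0.6,
                       tile_length_range = c(50, 75),
                       tile_spacing_mean = 110,
                       conditions = c("D", "1h", "6h"),
                       n_replicates = 2,
                       snr = 3,
                       noise_sd = 0.5,
                       frac_marked = 0.30,
                       frac_gain_1h = 0.08,
                       frac_gain_6h = 0.10,
                       frac_loss_6h = 0.04,
                       domain_fraction = 0.8,
                       shape_sd = 0.2,
                       de_effect_log2 = 1,
                       expr_noise_sd = 0.25,
                       frac_up_1h = 0.05,
                       frac_up_6h = 0.05,
                       frac_down_1h = 0.02,
                       frac_down_6h = 0.05,
                       frac_up_and_down = 0.03,
                       rho_gain_up = 0.8,
                       frac_hub_defect = 0.5,
                       hub_defect_factor = 0.3,
                       frac_hub_dark_mimic = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_genes = as.integer(n_genes),
    gene_length_median = gene_length_median,
    gene_length_sigma = gene_length_sigma,
    tile_length_range = as.integer(tile_length_range),
    tile_spacing_mean = tile_spacing_mean,
    conditions = conditions,
    n_replicates = as.integer(n_replicates),
    snr = snr,
    noise_sd = noise_sd,
    frac_marked = frac_marked,
    frac_gain_1h = frac_gain_1h,
    frac_gain_6h = frac_gain_6h,
    frac_loss_6h = frac_loss_6h,
    domain_fraction = domain_fraction,
    shape_sd = shape_sd,
    de_effect_log2 = de_effect_log2,
    expr_noise_sd = expr_noise_sd,
    frac_up_1h = frac_up_1h,
    frac_up_6h = frac_up_6h,
    frac_down_1h = frac_down_1h,
    frac_down_6h = frac_down_6h,
    frac_up_and_down = frac_up_and_down,
    rho_gain_up = rho_gain_up,
    frac_hub_defect = frac_hub_defect,
    hub_defect_factor = hub_defect_factor,
    frac_hub_dark_mimic = frac_hub_dark_mimic,
    seed = as.integer(seed)
  )
  probs <- unlist(cfg[c("frac_marked", "frac_gain_1h", "frac_gain_6h",
                        "frac_loss_6h", "frac_up_1h", "frac_up_6h",
                        "frac_down_1h", "frac_down_6h", "frac_up_and_down",
                        "rho_gain_up", "frac_hub_defect",
                        "frac_hub_dark_mimic")])
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  cat_sum <- cfg$frac_marked + cfg$frac_gain_1h + cfg$frac_gain_6h +
    cfg$frac_loss_6h
  if (cat_sum > 1) stop("chromatin category probabilities sum to > 1")
  if (sum(unlist(cfg[c("frac_up_1h", "frac_up_6h", "frac_down_1h",
                       "frac_down_6h", "frac_up_and_down")])) > 1) {
    stop("expression class probabilities sum to > 1")
  }
  if (length(cfg$conditions) < 2) stop("need at least 2 conditions")
  if (length(cfg$tile_length_range) != 2 ||
      cfg$tile_length_range[1] > cfg$tile_length_range[2]) {
    stop("tile_length_range must be [min, max]")
  }
  if (cfg$domain_fraction <= 0 || cfg$domain_fraction > 1) {
    stop("domain_fraction must be in (0, 1]")
  }
  structure(cfg, class = "sim_config")
}

sim_chroms <- function(cfg) paste0("chr", seq_len(cfg$n_chromosomes))

#' Simulate a toy gene annotation with planted chromatin/expression truth
#'
#' Places non-overlapping genes (>= 1 kb intergenic flanks) on the
#' configured chromosomes, draws transcribed-region lengths from the
#' log-normal in `cfg`, and assigns every gene a planted chromatin category
#' (stable / gain-1h / gain-6h / loss-6h / unmarked), a planted
#' light-response expression class, a mutant-defect flag and a
#' mutant-dark-shift direction. Light-induced genes are drawn preferentially
#' from the planted-gain pool with probability `rho_gain_up`, leaving the
#' marginal category frequencies untouched.
#'
#' @param cfg a [sim_config()]
#' @return list with `genes` (tibble: gene_id, chrom, start, end, strand,
#'   length; 1-based closed coordinates) and `truth` (tibble with per-gene
#'   planted state, including `marked_<condition>` columns and the planted
#'   domain interval)
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  flank <- 1000L
  empty_genes <- tibble(gene_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), length = integer())
  if (cfg$n_genes == 0) {
    return(list(genes = empty_genes, truth = empty_truth(cfg)))
  }
  lens <- pmax(200L, as.integer(round(stats::rlnorm(
    cfg$n_genes, meanlog = log(cfg$gene_length_median),
    sdlog = cfg$gene_length_sigma))))
  chrom_of <- rep(seq_len(cfg$n_chromosomes), length.out = cfg$n_genes)
  genes <- vector("list", cfg$n_chromosomes)
  for (ci in seq_len(cfg$n_chromosomes)) {
    idx <- which(chrom_of == ci)
    if (length(idx) == 0) next
    k <- length(idx)
    slack <- cfg$chrom_length_bp - sum(lens[idx]) - (k + 1L) * flank
    if (slack < 0) {
      stop("cannot place ", k, " genes of total length ", sum(lens[idx]),
           " bp on a ", cfg$chrom_length_bp, " bp chromosome with 1 kb flanks")
    }
    u <- stats::runif(k + 1)
    extra <- floor(slack * u / sum(u))
    gaps <- flank + extra[seq_len(k)]
    starts <- cumsum(gaps) + cumsum(c(0L, lens[idx][-k])) + 1L
    genes[[ci]] <- tibble(
      gene_id = sprintf("g%05d", idx),
      chrom = sim_chroms(cfg)[ci],
      start = as.integer(starts),
      end = as.integer(starts + lens[idx] - 1L),
      strand = sample(c("+", "-"), k, replace = TRUE),
      length = lens[idx]
    )
  }
  genes <- bind_rows(genes) %>% arrange(.data$gene_id)
  truth <- assign_truth(genes, cfg)
  list(genes = genes, truth = truth)
}

empty_truth <- function(cfg) {
  tt <- tibble(gene_id = character(), category = character(),
               expr_class = character(), hub_defective = logical(),
               hub_dark_direction = integer(),
               domain_start = integer(), domain_end = integer())
  for (cond in cfg$conditions) tt[[paste0("marked_", cond)]] <- logical()
  tt
}

# chromatin category -> marked status per condition (D, 1h, 6h)
category_marking <- function(category, conditions) {
  marked <- matrix(FALSE, nrow = length(category), ncol = length(conditions),
                   dimnames = list(NULL, conditions))
  marked[category == "stable", ] <- TRUE
  if (all(c("D", "1h", "6h") %in% conditions)) {
    marked[category == "gain_1h", c("1h", "6h")] <- TRUE
    marked[category == "gain_6h", "6h"] <- TRUE
    marked[category == "loss_6h", c("D", "1h")] <- TRUE
  }
  marked
}

assign_truth <- function(genes, cfg) {
  n <- nrow(genes)
  cat_probs <- c(stable = cfg$frac_marked, gain_1h = cfg$frac_gain_1h,
                 gain_6h = cfg$frac_gain_6h, loss_6h = cfg$frac_loss_6h)
  cat_probs <- c(cat_probs, unmarked = 1 - sum(cat_probs))
  category <- sample(names(cat_probs), n, replace = TRUE, prob = cat_probs)

  cls_probs <- c(up_1h = cfg$frac_up_1h, up_6h = cfg$frac_up_6h,
                 down_1h = cfg$frac_down_1h, down_6h = cfg$frac_down_6h,
                 up_and_down = cfg$frac_up_and_down)
  cls_draw <- sample(c(names(cls_probs), "none"), n, replace = TRUE,
                     prob = c(cls_probs, 1 - sum(cls_probs)))
  n_cls <- table(factor(cls_draw, levels = c(names(cls_probs), "none")))

  # place up classes preferentially on matching gain genes (rho_gain_up),
  # preserving both marginal frequencies
  expr_class <- rep("none", n)
  assigned <- rep(FALSE, n)
  pref_pool <- list(up_1h = "gain_1h", up_and_down = "gain_1h",
                    up_6h = "gain_6h")
  for (cls in c("up_1h", "up_and_down", "up_6h")) {
    k <- n_cls[[cls]]
    if (k == 0) next
    pool <- which(!assigned & category == pref_pool[[cls]])
    n_pref <- min(round(cfg$rho_gain_up * k), length(pool))
    take <- if (n_pref > 0) sample(pool, n_pref) else integer(0)
    rest_pool <- which(!assigned & !(category %in% "gain_1h") &
                         !(category %in% "gain_6h"))
    rest_pool <- setdiff(rest_pool, take)
    n_rest <- k - n_pref
    if (n_rest > length(rest_pool)) {
      rest_pool <- setdiff(which(!assigned), take)
    }
    rest <- if (n_rest > 0) sample(rest_pool, n_rest) else integer(0)
    sel <- c(take, rest)
    expr_class[sel] <- cls
    assigned[sel] <- TRUE
  }
  for (cls in c("down_1h", "down_6h")) {
    k <- n_cls[[cls]]
    if (k == 0) next
    pool <- which(!assigned)
    sel <- sample(pool, min(k, length(pool)))
    expr_class[sel] <- cls
    assigned[sel] <- TRUE
  }

  responsive <- expr_class != "none"
  hub_defective <- responsive &
    stats::runif(n) < cfg$frac_hub_defect
  light_dir <- ifelse(expr_class %in% c("up_1h", "up_6h", "up_and_down"), 1L,
                      ifelse(expr_class %in% c("down_1h", "down_6h"), -1L, 0L))
  hub_dark_direction <- ifelse(
    responsive & stats::runif(n) < cfg$frac_hub_dark_mimic, light_dir, 0L)

  # planted domain footprint: central domain_fraction of the transcribed
  # region (0-based arithmetic on offsets, stored 1-based closed)
  L <- genes$length
  lo <- floor(L * (0.5 - cfg$domain_fraction / 2))
  hi <- ceiling(L * (0.5 + cfg$domain_fraction / 2))
  truth <- tibble(
    gene_id = genes$gene_id,
    category = category,
    expr_class = expr_class,
    hub_defective = hub_defective,
    hub_dark_direction = as.integer(hub_dark_direction),
    domain_start = as.integer(genes$start + lo),
    domain_end = as.integer(genes$start - 1L + hi)
  )
  marked <- category_marking(category, cfg$conditions)
  for (cond in cfg$conditions) {
    truth[[paste0("marked_", cond)]] <- marked[, cond]
  }
  truth
}

#' Simulate a NimbleGen-style tile layout
#'
#' Walks each chromosome placing non-overlapping tiles with lengths drawn
#' uniformly from `cfg$tile_length_range` and start-to-start spacing
#' averaging `cfg$tile_spacing_mean`. Every gene of length >= 500 bp is
#' overlapped by at least 3 tiles at the default geometry.
#'
#' @param genes gene annotation tibble (used only to know the chromosomes;
#'   may be empty)
#' @param cfg a [sim_config()]
#' @return tibble: tile_id, chrom, start, end (1-based closed), sorted with
#'   strictly increasing starts per chromosome
#' @export
simulate_tiles <- function(genes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  len_rng <- cfg$tile_length_range
  gap_mean <- cfg$tile_spacing_mean - mean(len_rng)
  if (gap_mean < 0) gap_mean <- 0
  gap_lo <- max(0L, as.integer(round(gap_mean - 25)))
  # symmetric around gap_mean so the average spacing stays on target
  gap_hi <- as.integer(round(2 * gap_mean - gap_lo))
  out <- vector("list", cfg$n_chromosomes)
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- sim_chroms(cfg)[ci]
    n_est <- ceiling(cfg$chrom_length_bp /
                       (len_rng[1] + max(gap_lo, 1))) + 10L
    lens <- sample(seq(len_rng[1], len_rng[2]), n_est, replace = TRUE)
    gaps <- sample(seq(gap_lo, gap_hi), n_est, replace = TRUE)
    starts <- cumsum(c(1L + gaps[1], (lens + gaps)[-n_est]))
    ends <- starts + lens - 1L
    keep <- ends <= cfg$chrom_length_bp
    out[[ci]] <- tibble(chrom = chrom, start = as.integer(starts[keep]),
                        end = as.integer(ends[keep]))
  }
  tiles <- bind_rows(out)
  tiles$tile_id <- seq_len(nrow(tiles))
  tiles[, c("tile_id", "chrom", "start", "end")]
}

gaussian_shape <- function(p, shape_sd) {
  exp(-(p - 0.5)^2 / (2 * shape_sd^2))
}

#' Simulate ChIP tiling-array signal with planted H2Bub domains
#'
#' For every (gene, condition) pair marked in the ground truth, tiles whose
#' midpoint falls inside the planted domain receive a mean of
#' `snr * gaussian_shape(position within gene)` (peak at mid-gene, low over
#' promoters and intergenic space); all other tiles have mean 0. Additive
#' Gaussian noise of sd `noise_sd` is drawn independently per tile per
#' replicate; the dye-swap partner replicate is simulated post-correction
#' (same expectation, independent noise).
#'
#' @param tiles tile layout from [simulate_tiles()]
#' @param genes,truth from [simulate_genome()]
#' @param cfg a [sim_config()]
#' @return long tibble: tile_id, chrom, start, end, condition, replicate,
#'   score (log2 IP/input)
#' @export
simulate_chip_signal <- function(tiles, genes, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n_tiles <- nrow(tiles)
  mid <- (tiles$start + tiles$end) / 2
  mid_gr <- GenomicRanges::GRanges(tiles$chrom,
                                   IRanges::IRanges(floor(mid), floor(mid)))
  out <- vector("list", length(cfg$conditions) * cfg$n_replicates)
  k <- 1L
  for (cond in cfg$conditions) {
    mu <- numeric(n_tiles)
    marked <- truth[[paste0("marked_", cond)]]
    if (any(marked)) {
      dom <- truth[marked, ]
      gm <- genes[match(dom$gene_id, genes$gene_id), ]
      dom_gr <- GenomicRanges::GRanges(
        gm$chrom, IRanges::IRanges(dom$domain_start, dom$domain_end))
      hits <- GenomicRanges::findOverlaps(mid_gr, dom_gr)
      ti <- S4Vectors::queryHits(hits)
      gi <- S4Vectors::subjectHits(hits)
      p <- (mid[ti] - gm$start[gi]) / gm$length[gi]
      mu[ti] <- cfg$snr * gaussian_shape(p, cfg$shape_sd)
    }
    for (rep_i in seq_len(cfg$n_replicates)) {
      noise <- if (cfg$noise_sd > 0) {
        stats::rnorm(n_tiles, 0, cfg$noise_sd)
      } else {
        numeric(n_tiles)
      }
      out[[k]] <- tibble(tile_id = tiles$tile_id, chrom = tiles$chrom,
                         start = tiles$start, end = tiles$end,
                         condition = cond, replicate = rep_i,
                         score = mu + noise)
      k <- k + 1L
    }
  }
  bind_rows(out)
}

#' Comparison labels of the five-array transcriptome design
#' @return character vector of comparison labels
#' @export
expression_comparisons <- function() {
  c("wt_1h_vs_D", "wt_6h_vs_D", "hub_1h_vs_D", "hub_6h_vs_D", "hub_D_vs_wt_D")
}

planted_expression_effects <- function(truth, cfg) {
  e <- cfg$de_effect_log2
  wt1 <- ifelse(truth$expr_class %in% c("up_1h", "up_and_down"), e,
                ifelse(truth$expr_class == "down_1h", -e, 0))
  wt6 <- ifelse(truth$expr_class == "up_6h", e,
                ifelse(truth$expr_class == "down_6h", -e, 0))
  damp <- ifelse(truth$hub_defective, cfg$hub_defect_factor, 1)
  tibble(
    gene_id = truth$gene_id,
    wt_1h_vs_D = wt1,
    wt_6h_vs_D = wt6,
    hub_1h_vs_D = wt1 * damp,
    hub_6h_vs_D = wt6 * damp,
    hub_D_vs_wt_D = truth$hub_dark_direction * e
  )
}

#' Simulate CATMA-style per-gene expression log ratios
#'
#' Per gene and comparison, draws `n_replicates * 2` (dye-swap pairs)
#' independent log2 ratios around the planted effect. Up&Down genes carry
#' the full effect in the 1h-vs-dark comparisons and none at 6 h, so that
#' the derived 6h-vs-1h contrast is negative.
#'
#' @param truth ground truth from [simulate_genome()]
#' @param cfg a [sim_config()]
#' @return long tibble: gene_id, comparison, array, log2_ratio
#' @export
simulate_expression <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  eff <- planted_expression_effects(truth, cfg)
  n_arrays <- cfg$n_replicates * 2L
  out <- vector("list", length(expression_comparisons()))
  for (i in seq_along(expression_comparisons())) {
    comp <- expression_comparisons()[i]
    mu <- rep(eff[[comp]], each = n_arrays)
    noise <- if (cfg$expr_noise_sd > 0) {
      stats::rnorm(length(mu), 0, cfg$expr_noise_sd)
    } else {
      numeric(length(mu))
    }
    out[[i]] <- tibble(
      gene_id = rep(truth$gene_id, each = n_arrays),
      comparison = comp,
      array = rep(seq_len(n_arrays), times = nrow(truth)),
      log2_ratio = mu + noise
    )
  }
  bind_rows(out)
}

#' Simulate a complete synthetic study dataset
#'
#' @param cfg a [sim_config()]
#' @return list: genes, truth, tiles, chip (long tile scores), expr (long
#'   log2 ratios), cfg
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  gen <- simulate_genome(cfg)
  tiles <- simulate_tiles(gen$genes, cfg)
  chip <- simulate_chip_signal(tiles, gen$genes, gen$truth, cfg)
  expr <- simulate_expression(gen$truth, cfg)
  list(genes = gen$genes, truth = gen$truth, tiles = tiles, chip = chip,
       expr = expr, cfg = cfg)
}

#' Genes planted to satisfy all three candidate criteria
#'
#' Convenience accessor: light-induced, H2Bub gain, and defective
#' upregulation in the mutant.
#'
#' @param truth ground truth tibble
#' @return character vector of gene ids
#' @export
planted_candidates <- function(truth) {
  truth$gene_id[truth$expr_class %in% c("up_1h", "up_6h", "up_and_down") &
                  truth$category %in% c("gain_1h", "gain_6h") &
                  truth$hub_defective]
}
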