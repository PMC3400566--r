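#' Per-gene mean H2Bub levels across conditions
#'
#' A tile is assigned to a gene when it overlaps the transcribed region
#' (any overlap, strand-agnostic); the gene-level value is the mean
#' combined score over its tiles, per condition. Genes with no tile are
#' excluded.
#'
#' @param tracks named list of standardized tracks (condition -> tibble
#'   with tile_id, score), as from [combine_all_conditions()]
#' @param genes gene tibble
#' @param tiles tile layout tibble
#' @return tibble: gene_id, n_tiles, one `level_<condition>` column per
#'   condition
#' @export
gene_mean_levels <- function(tracks, genes, tiles) {
  gr <- genes_to_granges(genes)
  tile_gr <- intervals_to_granges(tiles)
  hits <- GenomicRanges::findOverlaps(tile_gr, gr, ignore.strand = TRUE)
  ti <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  if (length(ti) == 0) {
    out <- tibble(gene_id = character(), n_tiles = integer())
    for (cond in names(tracks)) out[[paste0("level_", cond)]] <- numeric()
    return(out)
  }
  gene_ids <- genes$gene_id[gi]
  out <- tibble(gene_id = sort(unique(gene_ids)))
  out$n_tiles <- as.integer(table(gene_ids)[out$gene_id])
  for (cond in names(tracks)) {
    tr <- tracks[[cond]]
    sc <- tr$score[match(tiles$tile_id[ti], tr$tile_id)]
    agg <- tapply(sc, gene_ids, mean, na.rm = TRUE)
    out[[paste0("level_", cond)]] <- as.numeric(agg[out$gene_id])
  }
  out
}

#' Per-gene chromatin/expression change summary for one comparison
#'
#' @param levels output of [gene_mean_levels()]
#' @param de DE table from [call_de()]
#' @param comparison expression comparison (e.g. `"wt_6h_vs_D"`)
#' @param cond_from,cond_to chromatin conditions differenced as
#'   `level_<cond_to> - level_<cond_from>`
#' @return tibble: gene_id, delta_h2bub, delta_expr, de_flag (genes present
#'   in both datasets)
#' @export
delta_summary <- function(levels, de, comparison, cond_from = "D",
                          cond_to = "6h") {
  dd <- de[de$comparison == comparison, ]
  common <- intersect(levels$gene_id, dd$gene_id)
  li <- match(common, levels$gene_id)
  di <- match(common, dd$gene_id)
  tibble(
    gene_id = common,
    delta_h2bub = levels[[paste0("level_", cond_to)]][li] -
      levels[[paste0("level_", cond_from)]][li],
    delta_expr = dd$mean_log2[di],
    de_flag = dd$de_flag[di])
}

#' Cross-tabulate mark gain/loss by light-response class
#'
#' For each response class, the percentage of its eligible genes falling in
#' the gain and in the loss category. Eligibility restricts the denominator
#' to genes present in both datasets and marked at the stated condition for
#' that class.
#'
#' @param response_sets named list: class -> gene ids
#' @param gain_set,loss_set gene ids in the mark gain / loss categories
#' @param mark_matrix marking matrix (for the eligibility filter)
#' @param marked_at named character: class -> condition at which eligible
#'   genes must be marked (entries may be NA to skip the marking filter)
#' @param expression_universe genes with expression data (eligibility also
#'   requires membership here)
#' @return tibble: class, category, n_eligible, n_in_category, percent
#' @export
crosstab_mark_by_response <- function(response_sets, gain_set, loss_set,
                                      mark_matrix, marked_at,
                                      expression_universe) {
  out <- list()
  for (cls in names(response_sets)) {
    eligible <- intersect(response_sets[[cls]], expression_universe)
    cond <- marked_at[[cls]]
    if (!is.null(cond) && !is.na(cond)) {
      marked_genes <- mark_matrix$gene_id[mark_matrix[[cond]]]
      eligible <- intersect(eligible, marked_genes)
    }
    for (cat in c("gain", "loss")) {
      set <- if (cat == "gain") gain_set else loss_set
      n_in <- length(intersect(eligible, set))
      out[[paste(cls, cat)]] <- tibble(
        class = cls, category = cat,
        n_eligible = length(eligible), n_in_category = n_in,
        percent = if (length(eligible) == 0) NA_real_ else
          100 * n_in / length(eligible))
    }
  }
  bind_rows(out)
}

#' Pairwise two-sided Wilcoxon rank-sum comparisons of level sets
#'
#' Exact enumeration for small samples without ties, normal approximation
#' with tie correction otherwise (the standard [stats::wilcox.test()]
#' switch). All-identical pooled values give p = 1.
#'
#' @param level_sets named list of numeric vectors (each n >= 3)
#' @return tibble: set1, set2, n1, n2, statistic, p
#' @export
rank_compare <- function(level_sets) {
  nm <- names(level_sets)
  out <- list()
  for (i in seq_along(level_sets)) {
    for (j in seq_along(level_sets)) {
      if (j <= i) next
    x <- level_sets[[i]]; y <- level_sets[[j]]
      if (length(x) < 3 || length(y) < 3) {
        stop("each level set needs n >= 3")
      }
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided"))
      out[[paste(i, j)]] <- tibble(
        set1 = nm[i], set2 = nm[j], n1 = length(x), n2 = length(y),
        statistic = unname(wt$statistic), p = wt$p.value)
    }
  }
  bind_rows(out)
}

#' Metagene profile over a scaled gene body with fixed-width flanks
#'
#' Each tile contributes its level to the body bin its midpoint falls in
#' after mapping position to percent of the transcribed region (antisense
#' genes are flipped so bin 1 is always the 5' end); flanks are binned at a
#' fixed `flank_bin_bp`. Values are per-bin means over genes (gene-level
#' bin means first, then averaged across genes). When several gene sets
#' are profiled together, they are jointly normalized so the global
#' maximum bin value is 1.
#'
#' @param gene_sets named list: set label -> gene ids
#' @param genes gene tibble
#' @param track standardized signal track
#' @param tiles tile layout
#' @param n_body_bins number of body bins (default 100: percent positions)
#' @param flank_bp flank length (bp) profiled on each side
#' @param flank_bin_bp width of each flank bin (bp)
#' @return tibble: set, bin (-k..-1 = 5' flank, 1..n_body_bins = body,
#'   n_body_bins+1.. = 3' flank), value, value_norm
#' @export
metagene <- function(gene_sets, genes, track, tiles, n_body_bins = 100L,
                     flank_bp = 1000L, flank_bin_bp = 100L) {
  n_flank_bins <- as.integer(flank_bp / flank_bin_bp)
  mid <- floor((tiles$start + tiles$end) / 2)
  score <- track$score[match(tiles$tile_id, track$tile_id)]
  profile_set <- function(ids) {
    gg <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (nrow(gg) == 0) return(NULL)
    ext_gr <- GenomicRanges::GRanges(
      gg$chrom,
      IRanges::IRanges(pmax(gg$start - flank_bp, 1), gg$end + flank_bp))
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(tiles$chrom, IRanges::IRanges(mid, mid)),
      ext_gr)
    ti <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    if (length(ti) == 0) return(NULL)
    gs <- gg$start[gi]; ge <- gg$end[gi]
    L <- ge - gs + 1L
    minus <- gg$strand[gi] == "-"
    pos <- mid[ti]
    # signed distance from the 5' end, in bp (negative = upstream flank)
    d5 <- ifelse(minus, ge - pos, pos - gs)
    rel <- d5 / L
    bin <- integer(length(ti))
    body <- d5 >= 0 & d5 < L
    bin[body] <- pmin(pmax(ceiling(rel[body] * n_body_bins), 1L),
                      n_body_bins)
    upstream <- d5 < 0
    bin[upstream] <- -pmin(ceiling(-d5[upstream] / flank_bin_bp),
                           n_flank_bins)
    downstream <- d5 >= L
    bin[downstream] <- n_body_bins +
      pmin(ceiling((d5[downstream] - L[downstream] + 1) / flank_bin_bp),
           n_flank_bins)
    df <- data.frame(gene = gg$gene_id[gi], bin = bin, score = score[ti])
    per_gene <- stats::aggregate(score ~ gene + bin, data = df, FUN = mean)
    agg <- stats::aggregate(score ~ bin, data = per_gene, FUN = mean)
    tibble(bin = agg$bin, value = agg$score)
  }
  out <- list()
  for (set in names(gene_sets)) {
    prof <- profile_set(gene_sets[[set]])
    if (!is.null(prof)) out[[set]] <- mutate(prof, set = set)
  }
  if (length(out) == 0) {
    return(tibble(set = character(), bin = integer(), value = numeric(),
                  value_norm = numeric()))
  }
  res <- bind_rows(out)
  res$value_norm <- res$value / max(res$value)
  res[, c("set", "bin", "value", "value_norm")]
}

#' Quadrant correlations and LOWESS trend of expression vs H2Bub change
#'
#' Quadrants use the DE flag for the expression axis and the sign of the
#' H2Bub change for the chromatin axis (genes with exactly zero H2Bub
#' change are excluded from quadrants): I = down/gain, II = up/gain,
#' III = down/loss, IV = up/loss. Pearson r (with p) is reported per
#' quadrant (NA when n < 3) and overall for the up and down subsets. The
#' LOWESS trend uses span 2/3 with 3 robustifying iterations.
#'
#' @param summary tibble from [delta_summary()]
#' @return list: `quadrants` (tibble quadrant, n, r, p), `overall` (tibble
#'   subset, n, r, p), `lowess` (tibble x, fitted)
#' @export
delta_scatter <- function(summary) {
  dh <- summary$delta_h2bub
  dx <- summary$delta_expr
  flag <- summary$de_flag
  quadrant_def <- list(
    I = flag == "down" & dh > 0,
    II = flag == "up" & dh > 0,
    III = flag == "down" & dh < 0,
    IV = flag == "up" & dh < 0)
  cor_row <- function(sel) {
    n <- sum(sel, na.rm = TRUE)
    if (n < 3) return(c(n = n, r = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(dx[sel], dh[sel]))
    c(n = n, r = unname(ct$estimate), p = ct$p.value)
  }
  quad <- bind_rows(lapply(quadrant_def, function(sel) {
    as_tibble(as.list(cor_row(sel & !is.na(dh))))
  }))
  quad$quadrant <- names(quadrant_def)
  overall <- bind_rows(lapply(
    list(up = flag == "up", down = flag == "down", all = rep(TRUE,
                                                             length(flag))),
    function(sel) as_tibble(as.list(cor_row(sel)))))
  overall$subset <- c("up", "down", "all")
  lw <- stats::lowess(dx, dh, f = 2 / 3, iter = 3)
  list(quadrants = quad[, c("quadrant", "n", "r", "p")],
       overall = overall[, c("subset", "n", "r", "p")],
       lowess = tibble(x = lw$x, fitted = lw$y))
}

#' Marked-gene fraction per expression bin
#'
#' @param mark_matrix marking matrix
#' @param expression_bins tibble: gene_id, bin (a partition of the genes)
#' @param conditions condition columns of the mark matrix to report
#' @return tibble: condition, bin, n, n_marked, fraction (NA on empty bins)
#' @export
marked_fraction_by_expression <- function(mark_matrix, expression_bins,
                                          conditions = NULL) {
  conditions <- conditions %||%
    setdiff(names(mark_matrix), "gene_id")
  out <- list()
  for (cond in conditions) {
    for (b in sort(unique(expression_bins$bin))) {
      ids <- expression_bins$gene_id[expression_bins$bin == b]
      idx <- match(ids, mark_matrix$gene_id)
      idx <- idx[!is.na(idx)]
      n <- length(idx)
      nm <- sum(mark_matrix[[cond]][idx])
      out[[paste(cond, b)]] <- tibble(
        condition = cond, bin = b, n = n, n_marked = nm,
        fraction = if (n == 0) NA_real_ else nm / n)
    }
  }
  bind_rows(out)
}

#' Hypergeometric over/under-representation of annotation sets
#'
#' For each annotation set, the observed overlap with the target set, the
#' expected overlap under independence, the hypergeometric tail
#' probabilities for over- and under-representation, and BH-adjusted
#' over-representation p-values across sets.
#'
#' @param target_set target gene ids (subset of the universe)
#' @param annotation_sets named list of gene-id vectors (subsets of the
#'   universe)
#' @param universe all gene ids
#' @return tibble: set, n_set, n_target, observed, expected, ratio,
#'   p_over, p_under, p_adj
#' @export
set_enrichment <- function(target_set, annotation_sets, universe) {
  if (length(universe) == 0) stop("universe must be non-empty")
  if (!all(target_set %in% universe)) {
    stop("target_set must be a subset of the universe")
  }
  N <- length(unique(universe))
  target <- unique(target_set)
  out <- list()
  for (nm in names(annotation_sets)) {
    set <- unique(intersect(annotation_sets[[nm]], universe))
    k <- length(intersect(target, set))
    m <- length(set)
    expected <- length(target) * m / N
    p_over <- stats::phyper(k - 1, m, N - m, length(target),
                            lower.tail = FALSE)
    p_under <- stats::phyper(k, m, N - m, length(target), lower.tail = TRUE)
    out[[nm]] <- tibble(
      set = nm, n_set = m, n_target = length(target), observed = k,
      expected = expected,
      ratio = if (expected == 0) NA_real_ else k / expected,
      p_over = p_over, p_under = p_under)
  }
  res <- bind_rows(out)
  res$p_adj <- stats::p.adjust(res$p_over, method = "BH")
  res
}

#' Select candidate genes for selective H2Bub-dependent regulation
#'
#' Candidates satisfy all three criteria: (1) induced by light (member of
#' the up classes), (2) concomitant H2Bub gain (de novo marking or
#' increased enrichment in any light-vs-dark comparison), and (3) defective
#' upregulation in the mutant (membership in the identified SOM
#' partition(s)). The list is de-duplicated and each candidate annotated
#' with the gain subtype(s) and comparison(s) that satisfied criterion (2).
#'
#' @param up_genes gene ids induced by light
#' @param gain_table tibble from [combine_differential_with_marking()]
#'   rows with `direction == "gain"` (any light-vs-dark comparison)
#' @param defective_up_genes gene ids with defective upregulation in the
#'   mutant
#' @return tibble: gene_id, subtypes, comparisons (sorted by gene_id)
#' @export
select_candidates <- function(up_genes, gain_table, defective_up_genes) {
  gains <- gain_table[gain_table$direction == "gain", , drop = FALSE]
  ids <- sort(Reduce(intersect, list(unique(up_genes),
                                     unique(gains$gene_id),
                                     unique(defective_up_genes))))
  if (length(ids) == 0) {
    return(tibble(gene_id = character(), subtypes = character(),
                  comparisons = character()))
  }
  ann <- gains %>%
    filter(.data$gene_id %in% ids) %>%
    group_by(.data$gene_id) %>%
    summarise(
      subtypes = paste(sort(unique(.data$subtype)), collapse = ","),
      comparisons = paste(sort(unique(.data$comparison)), collapse = ","),
      .groups = "drop")
  ann[match(ids, ann$gene_id), ]
}
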