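#' Call differentially expressed genes per comparison
#'
#' One-sample moderated t-test of the per-array log2 ratios against 0,
#' separately per comparison, using empirical-Bayes variance moderation
#' (limma), followed by multiple-testing correction within each comparison.
#' Genes with fewer than 2 finite ratios are flagged `ns` with NA p-values.
#'
#' @param expr long tibble: gene_id, comparison, array, log2_ratio
#' @param alpha significance level on the adjusted p-value
#' @param correction `"bonferroni"` (default), `"BH"` or `"none"`
#' @return tibble: gene_id, comparison, n_arrays, mean_log2, p_raw, p_adj,
#'   de_flag (`up`, `down` or `ns`)
#' @export
call_de <- function(expr, alpha = 0.05,
                    correction = c("bonferroni", "BH", "none")) {
  correction <- match.arg(correction)
  out <- list()
  for (comp in unique(expr$comparison)) {
    sub <- expr[expr$comparison == comp, ]
    mat <- tapply(sub$log2_ratio, list(sub$gene_id, sub$array), identity)
    mat <- matrix(as.numeric(mat), nrow = nrow(mat),
                  dimnames = dimnames(mat))
    n_finite <- rowSums(is.finite(mat))
    mean_log2 <- rowMeans(mat, na.rm = TRUE)
    p_raw <- rep(NA_real_, nrow(mat))
    ok <- n_finite >= 2
    if (any(ok)) {
      p_raw[ok] <- moderated_onesample_p(mat[ok, , drop = FALSE])
    }
    p_adj <- stats::p.adjust(p_raw, method = correction)
    de_flag <- ifelse(!ok | is.na(p_adj) | p_adj >= alpha, "ns",
                      ifelse(mean_log2 > 0, "up", "down"))
    out[[comp]] <- tibble(
      gene_id = rownames(mat), comparison = comp,
      n_arrays = unname(as.integer(n_finite)),
      mean_log2 = unname(mean_log2),
      p_raw = unname(p_raw), p_adj = unname(p_adj),
      de_flag = unname(de_flag))
  }
  bind_rows(out)
}

# Empirical-Bayes moderated one-sample t p-values (limma); falls back to a
# point-mass test when the whole matrix is noiseless (all residual
# variances zero), where the moderated t is undefined.
moderated_onesample_p <- function(mat) {
  sds <- apply(mat, 1, stats::sd, na.rm = TRUE)
  if (all(sds < 1e-12, na.rm = TRUE)) {
    means <- rowMeans(mat, na.rm = TRUE)
    return(ifelse(abs(means) < 1e-12, 1, 0))
  }
  fit <- limma::lmFit(mat, design = matrix(1, ncol(mat), 1))
  fit <- limma::eBayes(fit)
  as.numeric(fit$p.value[, 1])
}

#' Classify light-response kinetics from the wild-type DE tables
#'
#' A gene is `up_1h` / `up_6h` when flagged up and at least
#' `fold_threshold`-fold induced at that time point (`down_*` symmetric).
#' `up_and_down` genes are transiently induced: at least
#' `fold_threshold`-fold up at 1 h (with DE support), a negative 6h-vs-1h
#' contrast (derived as `mean_log2(6h) - mean_log2(1h)`; no direct 6h-vs-1h
#' hybridization exists in the design), and no longer meeting the up
#' threshold at 6 h. A gene may be in `up_1h` and `up_6h` simultaneously.
#'
#' @param de DE table from [call_de()] containing comparisons
#'   `wt_1h_vs_D` and `wt_6h_vs_D`
#' @param fold_threshold fold-change threshold (default 2)
#' @return tibble: gene_id, logical class columns, contrast_6h_vs_1h, and a
#'   `class` summary label
#' @export
classify_light_response <- function(de, fold_threshold = 2) {
  need <- c("wt_1h_vs_D", "wt_6h_vs_D")
  if (!all(need %in% unique(de$comparison))) {
    stop("missing comparison(s): ",
         paste(setdiff(need, unique(de$comparison)), collapse = ", "))
  }
  thr <- log2(fold_threshold)
  t1 <- de[de$comparison == "wt_1h_vs_D", ]
  t6 <- de[de$comparison == "wt_6h_vs_D", ]
  genes <- union(t1$gene_id, t6$gene_id)
  i1 <- match(genes, t1$gene_id)
  i6 <- match(genes, t6$gene_id)
  m1 <- t1$mean_log2[i1]; f1 <- t1$de_flag[i1]
  m6 <- t6$mean_log2[i6]; f6 <- t6$de_flag[i6]
  f1[is.na(f1)] <- "ns"; f6[is.na(f6)] <- "ns"
  up_1h <- f1 == "up" & !is.na(m1) & m1 >= thr
  up_6h <- f6 == "up" & !is.na(m6) & m6 >= thr
  down_1h <- f1 == "down" & !is.na(m1) & m1 <= -thr
  down_6h <- f6 == "down" & !is.na(m6) & m6 <= -thr
  contrast <- ifelse(is.na(m6) | is.na(m1), NA_real_, m6 - m1)
  up_and_down <- up_1h & !is.na(contrast) & contrast < 0 &
    !(!is.na(m6) & m6 >= thr)
  class <- rep("none", length(genes))
  class[up_1h | up_6h] <- "up"
  class[down_1h | down_6h] <- "down"
  class[up_and_down] <- "up_and_down"
  tibble(gene_id = genes, up_1h = up_1h, up_6h = up_6h,
         down_1h = down_1h, down_6h = down_6h,
         up_and_down = up_and_down, contrast_6h_vs_1h = contrast,
         class = class)
}

#' Overlap of wild-type light-response classes with mutant-dark DE
#'
#' For each wild-type light-response class, the fraction of its genes that
#' are differentially expressed in the mutant-vs-wild-type dark comparison
#' in the direction mimicking the light response (down for light-down
#' classes, up for light-up classes).
#'
#' @param classes output of [classify_light_response()]
#' @param de DE table containing comparison `hub_D_vs_wt_D`
#' @return tibble: class, n_class, n_mimic, fraction
#' @export
overlap_with_mutant <- function(classes, de) {
  hub <- de[de$comparison == "hub_D_vs_wt_D", ]
  if (nrow(hub) == 0) stop("comparison 'hub_D_vs_wt_D' absent")
  class_cols <- c(up_1h = "up", up_6h = "up",
                  down_1h = "down", down_6h = "down")
  out <- list()
  for (cls in names(class_cols)) {
    members <- classes$gene_id[classes[[cls]]]
    dirn <- class_cols[[cls]]
    mimic <- hub$gene_id[hub$de_flag == dirn]
    out[[cls]] <- tibble(
      class = cls, direction = dirn,
      n_class = length(members),
      n_mimic = length(intersect(members, mimic)),
      fraction = if (length(members) == 0) NA_real_ else
        length(intersect(members, mimic)) / length(members))
  }
  bind_rows(out)
}
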