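#' Self-organizing-map partitioning of expression profiles
#'
#' Online SOM on a rectangular grid with a Gaussian neighborhood whose
#' radius decays linearly from `max(grid_rows, grid_cols) / 2` to 0.5 over
#' the iterations, and a learning rate decaying linearly between
#' `alpha[1]` and `alpha[2]`. Prototypes are initialized from randomly
#' sampled input rows. After training, every gene is assigned to its
#' best-matching unit, so the partitions are disjoint and exhaustive.
#' Partitions are numbered row-major from 1.
#'
#' @param expr_matrix numeric matrix, genes x comparisons, rownames = gene
#'   ids
#' @param grid_rows,grid_cols SOM grid dimensions
#' @param seed RNG seed
#' @param iterations number of online updates (each picks one random gene)
#' @param alpha c(start, end) learning rate
#' @param standardize_rows center/scale each gene profile before training
#' @return list of class `som_partition`: `assignment` (tibble gene_id,
#'   partition), `profiles` (tibble partition, comparison, mean, var, n),
#'   `codes` (unit prototype matrix), grid dimensions
#' @export
som_cluster <- function(expr_matrix, grid_rows = 2L, grid_cols = 2L,
                        seed = 1L, iterations = 2000L,
                        alpha = c(0.05, 0.01), standardize_rows = FALSE) {
  if (is.null(dim(expr_matrix)) || nrow(expr_matrix) == 0) {
    stop("expr_matrix must be a non-empty matrix")
  }
  x <- as.matrix(expr_matrix)
  if (standardize_rows) {
    x <- t(scale(t(x)))
    x[!is.finite(x)] <- 0
  }
  n_units <- grid_rows * grid_cols
  set.seed(seed)
  # grid coordinates, row-major unit numbering
  coords <- cbind(row = rep(seq_len(grid_rows), each = grid_cols),
                  col = rep(seq_len(grid_cols), times = grid_rows))
  grid_d2 <- as.matrix(stats::dist(coords))^2
  codes <- x[sample(nrow(x), n_units, replace = nrow(x) < n_units), ,
             drop = FALSE]
  codes <- codes + stats::rnorm(length(codes), 0, 1e-4)  # break exact ties
  sigma0 <- max(grid_rows, grid_cols) / 2
  pick <- sample(nrow(x), iterations, replace = TRUE)
  for (it in seq_len(iterations)) {
    frac <- (it - 1) / max(iterations - 1, 1)
    sigma <- sigma0 + frac * (0.5 - sigma0)
    lr <- alpha[1] + frac * (alpha[2] - alpha[1])
    xi <- x[pick[it], ]
    d2 <- rowSums(sweep(codes, 2, xi)^2)
    bmu <- which.min(d2)
    h <- lr * exp(-grid_d2[bmu, ] / (2 * sigma^2))
    codes <- codes - h * sweep(codes, 2, xi, `-`)
  }
  # final assignment: best-matching unit per gene
  d2 <- outer(rowSums(x^2), rep(1, n_units)) -
    2 * x %*% t(codes) + outer(rep(1, nrow(x)), rowSums(codes^2))
  partition <- max.col(-d2, ties.method = "first")
  assignment <- tibble(gene_id = rownames(x) %||%
                         as.character(seq_len(nrow(x))),
                       partition = partition)
  prof <- list()
  for (u in seq_len(n_units)) {
    members <- x[partition == u, , drop = FALSE]
    prof[[u]] <- tibble(
      partition = u, row = coords[u, 1], col = coords[u, 2],
      comparison = colnames(x) %||% as.character(seq_len(ncol(x))),
      mean = if (nrow(members)) colMeans(members) else rep(NA_real_, ncol(x)),
      var = if (nrow(members) > 1) apply(members, 2, stats::var)
            else rep(NA_real_, ncol(x)),
      n = nrow(members))
  }
  structure(list(assignment = assignment, profiles = bind_rows(prof),
                 codes = codes, grid_rows = grid_rows,
                 grid_cols = grid_cols),
            class = "som_partition")
}

#' Expression matrix of the four light comparisons for SOM input
#'
#' Restricts to genes differentially expressed in at least one of the four
#' light comparisons (the mutant-dark comparison is not part of the
#' clustering input).
#'
#' @param de DE table from [call_de()]
#' @param de_restrict keep only genes DE in >= 1 light comparison
#' @return numeric matrix genes x 4 comparisons of mean log2 ratios
#' @export
som_input_matrix <- function(de, de_restrict = TRUE) {
  comps <- c("wt_1h_vs_D", "wt_6h_vs_D", "hub_1h_vs_D", "hub_6h_vs_D")
  sub <- de[de$comparison %in% comps, ]
  genes <- sort(unique(sub$gene_id))
  mat <- sapply(comps, function(comp) {
    tt <- sub[sub$comparison == comp, ]
    tt$mean_log2[match(genes, tt$gene_id)]
  })
  rownames(mat) <- genes
  if (de_restrict) {
    is_de <- sapply(comps, function(comp) {
      tt <- sub[sub$comparison == comp, ]
      (tt$de_flag != "ns")[match(genes, tt$gene_id)]
    })
    keep <- rowSums(is_de, na.rm = TRUE) >= 1
    mat <- mat[keep, , drop = FALSE]
  }
  mat[!is.finite(mat)] <- 0
  mat
}

#' Identify SOM partitions with a defective response in the mutant
#'
#' For `"defective_up"`, partitions whose mean wild-type light response is
#' clearly up (mean of the two wild-type comparisons above `min_wt`) and
#' whose mutant response is reduced by at least `min_rel_gap` relative to
#' the wild type; `"defective_down"` is symmetric.
#'
#' @param som a [som_cluster()] result
#' @param type `"defective_up"` or `"defective_down"`
#' @param min_wt minimum |mean wild-type response| (log2)
#' @param min_rel_gap minimum relative reduction of the mutant response
#' @return integer vector of partition numbers
#' @export
identify_defective_partitions <- function(som,
                                          type = c("defective_up",
                                                   "defective_down"),
                                          min_wt = 0.3,
                                          min_rel_gap = 0.3) {
  type <- match.arg(type)
  prof <- som$profiles
  wt <- prof[prof$comparison %in% c("wt_1h_vs_D", "wt_6h_vs_D"), ] %>%
    group_by(.data$partition) %>%
    summarise(wt_mean = mean(.data$mean), .groups = "drop")
  hub <- prof[prof$comparison %in% c("hub_1h_vs_D", "hub_6h_vs_D"), ] %>%
    group_by(.data$partition) %>%
    summarise(hub_mean = mean(.data$mean), .groups = "drop")
  j <- left_join(wt, hub, by = "partition")
  if (type == "defective_up") {
    sel <- !is.na(j$wt_mean) & j$wt_mean > min_wt &
      (j$wt_mean - j$hub_mean) / j$wt_mean >= min_rel_gap
  } else {
    sel <- !is.na(j$wt_mean) & j$wt_mean < -min_wt &
      (j$wt_mean - j$hub_mean) / j$wt_mean >= min_rel_gap
  }
  j$partition[sel]
}
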