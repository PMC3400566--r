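#' Criterion for calling a gene H2Bub-marked
#'
#' A gene is marked when the central fraction of its transcribed region
#' overlaps an enriched domain.
#'
#' @param central_fraction fraction of the transcribed region defining the
#'   central segment, in (0, 1]; default 0.40
#' @param min_overlap_bp minimum total overlap (bp) between central segment
#'   and the domain union; default 1 (any overlap)
#' @param min_covered_fraction optional minimum fraction of the central
#'   segment that must be covered; default 0
#' @return list of class `marking_criterion`
#' @export
marking_criterion <- function(central_fraction = 0.40, min_overlap_bp = 1L,
                              min_covered_fraction = 0) {
  if (central_fraction <= 0 || central_fraction > 1) {
    stop("central_fraction must be in (0, 1]")
  }
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  if (min_covered_fraction < 0 || min_covered_fraction > 1) {
    stop("min_covered_fraction must be in [0, 1]")
  }
  structure(list(central_fraction = central_fraction,
                 min_overlap_bp = as.integer(min_overlap_bp),
                 min_covered_fraction = min_covered_fraction),
            class = "marking_criterion")
}

#' Central segment of each transcribed region
#'
#' For a gene spanning L bp and central fraction f, the segment covers
#' offsets `floor(L * (0.5 - f/2))` to `ceiling(L * (0.5 + f/2))` from the
#' gene start (floor on the start boundary, ceiling on the end), so it is
#' never empty. Strand-agnostic.
#'
#' @param genes gene tibble (gene_id, chrom, start, end; 1-based closed)
#' @param crit a [marking_criterion()]
#' @return tibble: gene_id, chrom, start, end of the central segment
#'   (1-based closed)
#' @export
central_segment <- function(genes, crit = marking_criterion()) {
  f <- crit$central_fraction
  L <- genes$end - genes$start + 1L
  lo <- floor(L * (0.5 - f / 2))
  hi <- ceiling(L * (0.5 + f / 2))
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = as.integer(genes$start + lo),
         end = as.integer(genes$start - 1L + hi))
}

#' Call H2Bub-marked genes from enriched domains
#'
#' A gene is marked iff the total overlap between its central segment and
#' the union of the domains reaches `min_overlap_bp` and covers at least
#' `min_covered_fraction` of the segment. Invariant to domain
#' fragmentation: splitting a domain into abutting pieces never changes a
#' gene's status.
#'
#' @param genes gene tibble
#' @param domains domain tibble (chrom, start, end)
#' @param crit a [marking_criterion()]
#' @return tibble: gene_id, overlap_bp, covered_fraction, marked
#' @export
call_marked_genes <- function(genes, domains, crit = marking_criterion()) {
  cs <- central_segment(genes, crit)
  seg_w <- cs$end - cs$start + 1L
  overlap <- integer(nrow(genes))
  if (nrow(domains) > 0 && nrow(genes) > 0) {
    dom_gr <- GenomicRanges::reduce(intervals_to_granges(domains))
    cs_gr <- intervals_to_granges(cs)
    hits <- GenomicRanges::findOverlaps(cs_gr, dom_gr)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(cs_gr)[q], IRanges::ranges(dom_gr)[s]))
      agg <- tapply(w, q, sum)
      overlap[as.integer(names(agg))] <- as.integer(agg)
    }
  }
  covered <- overlap / seg_w
  tibble(gene_id = genes$gene_id, overlap_bp = overlap,
         covered_fraction = covered,
         marked = overlap >= crit$min_overlap_bp &
           covered >= crit$min_covered_fraction)
}

#' Build the gene x condition marking matrix
#'
#' @param genes gene tibble
#' @param domains_by_condition named list: condition -> domain tibble
#' @param crit a [marking_criterion()]
#' @return tibble with gene_id and one logical column per condition
#' @export
build_mark_matrix <- function(genes, domains_by_condition,
                              crit = marking_criterion()) {
  mm <- tibble(gene_id = genes$gene_id)
  for (cond in names(domains_by_condition)) {
    mm[[cond]] <- call_marked_genes(genes, domains_by_condition[[cond]],
                                    crit)$marked
  }
  mm
}

#' Venn partition of marked-gene sets across conditions
#'
#' Returns all `2^k - 1` nonempty membership classes. Classes are disjoint
#' and their union is the union of the marked sets.
#'
#' @param mark_matrix tibble with gene_id and one logical column per
#'   condition
#' @param conditions condition columns to partition over
#' @return tibble: class (e.g. `"D&1h"`), n, gene_ids (list column)
#' @export
venn_partitions <- function(mark_matrix, conditions) {
  if (!all(conditions %in% names(mark_matrix))) {
    stop("mark matrix lacks condition column(s): ",
         paste(setdiff(conditions, names(mark_matrix)), collapse = ", "))
  }
  memb <- as.matrix(mark_matrix[, conditions, drop = FALSE])
  k <- length(conditions)
  classes <- list()
  for (code in seq_len(2^k - 1)) {
    in_class <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1)))
    sel <- rep(TRUE, nrow(memb))
    for (j in seq_len(k)) {
      sel <- sel & (memb[, j] == in_class[j])
    }
    classes[[code]] <- tibble(
      class = paste(conditions[in_class], collapse = "&"),
      n = sum(sel),
      gene_ids = list(mark_matrix$gene_id[sel]))
  }
  bind_rows(classes)
}

parse_comparison <- function(comparison) {
  parts <- strsplit(comparison, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("unknown comparison label: ", comparison)
  list(later = parts[1], first = parts[2])
}

#' Combine differential domains with marking status into gene categories
#'
#' Differential domains are mapped to genes (central-segment overlap by
#' default, any transcribed-region overlap optionally); gain-domain genes
#' unmarked at the first time point of the comparison are `de_novo`, the
#' rest `increased`; loss-domain genes unmarked at the later time point are
#' `complete_loss`, the rest `decreased`. Gene lists are de-duplicated.
#'
#' @param diff_domains tibble from [call_differential_domains()] with
#'   `comparison` and `direction` columns
#' @param genes gene tibble
#' @param mark_matrix marking matrix from [build_mark_matrix()]
#' @param comparison comparison label like `"1h_vs_D"`; both its conditions
#'   must be columns of the mark matrix
#' @param crit a [marking_criterion()] (used in `"central"` mode)
#' @param mode map domains to genes by central-segment overlap
#'   (`"central"`) or any overlap of the transcribed region (`"any"`)
#' @return tibble: gene_id, comparison, direction, subtype
#' @export
combine_differential_with_marking <- function(diff_domains, genes,
                                              mark_matrix, comparison,
                                              crit = marking_criterion(),
                                              mode = c("central", "any")) {
  mode <- match.arg(mode)
  cmp <- parse_comparison(comparison)
  for (cond in c(cmp$first, cmp$later)) {
    if (!(cond %in% names(mark_matrix))) {
      stop("unknown comparison label: ", comparison,
           " (condition '", cond, "' not in mark matrix)")
    }
  }
  dd <- diff_domains[diff_domains$comparison == comparison, , drop = FALSE]
  out <- list()
  for (dir in intersect(c("gain", "loss"), unique(dd$direction))) {
    doms <- dd[dd$direction == dir, , drop = FALSE]
    if (nrow(doms) == 0) next
    hit_genes <- if (mode == "central") {
      crit_any <- marking_criterion(crit$central_fraction, 1L, 0)
      call_marked_genes(genes, doms, crit_any) %>%
        filter(.data$marked) %>% pull(.data$gene_id)
    } else {
      gr <- genes_to_granges(genes)
      hits <- GenomicRanges::findOverlaps(gr, intervals_to_granges(doms),
                                          ignore.strand = TRUE)
      unique(genes$gene_id[S4Vectors::queryHits(hits)])
    }
    if (length(hit_genes) == 0) next
    idx <- match(hit_genes, mark_matrix$gene_id)
    subtype <- if (dir == "gain") {
      ifelse(mark_matrix[[cmp$first]][idx], "increased", "de_novo")
    } else {
      ifelse(mark_matrix[[cmp$later]][idx], "decreased", "complete_loss")
    }
    out[[dir]] <- tibble(gene_id = hit_genes, comparison = comparison,
                         direction = dir, subtype = subtype)
  }
  if (length(out) == 0) {
    return(tibble(gene_id = character(), comparison = character(),
                  direction = character(), subtype = character()))
  }
  bind_rows(out) %>% distinct() %>% arrange(.data$gene_id)
}

#' Assign genes to length bins with separated extreme groups
#'
#' Genes shorter than the lower bound form bin 1 and genes longer than the
#' upper bound form the last bin; the remaining genes are split into
#' `n_quantiles - 2` equal-count bins by transcribed-region length (bin
#' sizes differ by at most 1).
#'
#' @param genes gene tibble with a `length` column
#' @param n_quantiles total number of bins (>= 3)
#' @param extreme_bounds c(lower, upper) length bounds in bp
#' @return tibble: gene_id, length, bin
#' @export
length_quantiles <- function(genes, n_quantiles = 8L,
                             extreme_bounds = c(1000, 3000)) {
  if (n_quantiles < 3) stop("n_quantiles must be >= 3")
  if (extreme_bounds[1] > extreme_bounds[2]) {
    stop("extreme_bounds must be (lower, upper) with lower <= upper")
  }
  len <- genes$length
  bin <- integer(nrow(genes))
  bin[len < extreme_bounds[1]] <- 1L
  bin[len > extreme_bounds[2]] <- as.integer(n_quantiles)
  mid <- which(bin == 0L)
  if (length(mid) > 0) {
    n_mid_bins <- n_quantiles - 2L
    ord <- mid[order(len[mid], genes$gene_id[mid])]
    rk <- seq_along(ord)
    bin[ord] <- 1L + as.integer(
      ceiling(rk * n_mid_bins / length(ord)))
  }
  tibble(gene_id = genes$gene_id, length = len, bin = bin)
}
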