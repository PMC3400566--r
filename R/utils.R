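#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n pull select summarise ungroup
#' @importFrom rlang .data
#' @useDynLib h2bdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average with partial windows at chromosome edges
#'
#' @param x numeric vector
#' @param window odd window size in elements
#' @return numeric vector of the same length; positions near the edges are
#'   averaged over the available part of the window.
#' @keywords internal
moving_average <- function(x, window) {
  if (window %% 2 == 0) stop("window must be odd")
  n <- length(x)
  if (n == 0) return(x)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Find runs of TRUE values, merging short gaps and dropping short runs
#'
#' @param flag logical vector (no NA)
#' @param max_gap maximum number of consecutive FALSE elements bridged when
#'   merging adjacent runs
#' @param min_run minimum run length (in elements, after merging) to keep
#' @return data.frame with columns `start`, `end` (1-based element indices)
#' @keywords internal
find_runs <- function(flag, max_gap = 0L, min_run = 1L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  runs <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(runs) > 1 && max_gap > 0) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= max_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}

intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}
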