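#' Combine dye-swap replicates into one standardized signal track
#'
#' The combined score is the mean of the replicate scores per tile (NA
#' replicates are dropped from the mean). The combined track is then
#' median-centered and scaled by the MAD per chromosome (MAD floored at
#' 1e-6), so emission parameters of the segmentation HMM are comparable
#' across conditions. Tiles with no finite replicate are imputed to the
#' center (standardized 0) and flagged.
#'
#' @param chip long tile-score tibble (tile_id, chrom, start, end,
#'   condition, replicate, score)
#' @param condition condition label to combine
#' @return tibble: tile_id, chrom, start, end, score_raw (pre-
#'   standardization mean), score (standardized), imputed; the per-
#'   chromosome (center, scale) pairs are recorded in the
#'   `"standardization"` attribute
#' @export
combine_replicates <- function(chip, condition) {
  sub <- chip[chip$condition == condition, ]
  if (nrow(sub) == 0) stop("condition '", condition, "' absent from input")
  wide <- sub %>%
    group_by(.data$tile_id, .data$chrom, .data$start, .data$end) %>%
    summarise(
      score_raw = if (all(is.na(.data$score))) NA_real_
                  else mean(.data$score, na.rm = TRUE),
      .groups = "drop") %>%
    arrange(.data$chrom, .data$start)
  standardize_track(wide)
}

#' Median/MAD-standardize a combined track per chromosome
#'
#' Idempotent (within numerical tolerance) on an already-standardized track.
#'
#' @param track tibble with chrom, start and either `score_raw` or `score`
#' @return the track with standardized `score`, an `imputed` flag, and a
#'   `"standardization"` attribute
#' @export
standardize_track <- function(track) {
  x <- if ("score_raw" %in% names(track)) track$score_raw else track$score
  if (!("score_raw" %in% names(track))) track$score_raw <- x
  imputed <- is.na(x)
  out <- track
  out$score <- NA_real_
  std <- list()
  for (chrom in unique(track$chrom)) {
    sel <- track$chrom == chrom
    v <- x[sel]
    center <- stats::median(v, na.rm = TRUE)
    if (is.na(center)) center <- 0
    scale <- max(stats::mad(v, center = center, na.rm = TRUE), 1e-6)
    out$score[sel] <- (v - center) / scale
    std[[chrom]] <- c(center = center, scale = scale)
  }
  out$score[imputed] <- 0
  out$imputed <- imputed
  attr(out, "standardization") <- std
  out
}

#' Build one standardized track per condition
#'
#' @param chip long tile-score tibble
#' @param conditions condition labels (default: all present)
#' @return named list of standardized tracks (see [combine_replicates()])
#' @export
combine_all_conditions <- function(chip, conditions = NULL) {
  conditions <- conditions %||% unique(chip$condition)
  stats::setNames(lapply(conditions, function(cc) {
    combine_replicates(chip, cc)
  }), conditions)
}
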