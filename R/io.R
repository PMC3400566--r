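#' Write a gene annotation as GFF3
#'
#' Coordinates are written 1-based inclusive as GFF3 requires.
#'
#' @param genes tibble: gene_id, chrom, start, end, strand
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- genes_to_granges(genes)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$source <- "h2bdyn"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' Keeps `gene`-typed records (or everything, if no type column).
#'
#' @param path GFF3 file
#' @return tibble: gene_id, chrom, start, end, strand, length
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    keep <- as.character(gr$type) == "gene"
    if (any(keep)) gr <- gr[keep]
  }
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$ID)
  } else {
    paste0("gene", seq_along(gr))
  }
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    length = GenomicRanges::width(gr)
  )
}

#' Write a per-tile score track as bedGraph
#'
#' @param track tibble with chrom, start, end (1-based closed) and a score
#'   column
#' @param path output file
#' @param score_col name of the score column
#' @return `path`, invisibly
#' @export
write_track_bedgraph <- function(track, path, score_col = "score") {
  gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start, track$end),
    score = track[[score_col]])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a sorted tile tibble
#'
#' @param path bedGraph file
#' @return tibble: chrom, start, end (1-based closed), score
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    score = gr$score
  ) %>% arrange(.data$chrom, .data$start)
}

#' Read per-condition, per-replicate bedGraph score files onto a tile layout
#'
#' All files must share the layout's chrom/start/end grid. Tiles absent from
#' a file get `NA` scores (with a warning); a tile present in a file but not
#' in the layout is a hard error naming the first discordant tile.
#'
#' @param paths named list: condition -> character vector of bedGraph files,
#'   one per replicate
#' @param layout tile layout tibble (tile_id, chrom, start, end)
#' @return long tibble: tile_id, chrom, start, end, condition, replicate,
#'   score
#' @export
read_tracks <- function(paths, layout) {
  key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")
  layout_key <- key(layout$chrom, layout$start, layout$end)
  out <- list()
  for (cond in names(paths)) {
    files <- paths[[cond]]
    for (rep_i in seq_along(files)) {
      bg <- read_bedgraph(files[[rep_i]])
      bg_key <- key(bg$chrom, bg$start, bg$end)
      bad <- which(!(bg_key %in% layout_key))
      if (length(bad) > 0) {
        stop("tile layout mismatch in ", files[[rep_i]], ": tile ",
             bg_key[bad[1]], " not in layout")
      }
      score <- bg$score[match(layout_key, bg_key)]
      if (anyNA(score)) {
        warning(sum(is.na(score)), " layout tile(s) missing from ",
                files[[rep_i]], "; scores set to NA")
      }
      out[[length(out) + 1L]] <- tibble(
        tile_id = layout$tile_id, chrom = layout$chrom,
        start = layout$start, end = layout$end,
        condition = cond, replicate = rep_i, score = score)
    }
  }
  bind_rows(out)
}

#' Write enriched domains as BED6
#'
#' Name encodes the condition (or comparison:direction); score is
#' 1000 x mean posterior, capped at 1000.
#'
#' @param domains domain tibble from [call_domains()] or
#'   [call_differential_domains()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_domains_bed <- function(domains, path) {
  name <- if ("direction" %in% names(domains)) {
    paste0(domains$comparison, ":", domains$direction)
  } else {
    domains$condition
  }
  gr <- GenomicRanges::GRanges(
    domains$chrom, IRanges::IRanges(domains$start, domains$end),
    name = name,
    score = pmin(1000, round(1000 * domains$mean_posterior)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
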