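#' Per-base coverage from bedGraph intervals
#'
#' bedGraph coverage is held as a tibble `chrom start end depth` with 0-based
#' half-open, non-overlapping intervals; positions not covered by any interval
#' have depth 0.
#'
#' @name coverage
NULL

#' Read / write bedGraph coverage
#'
#' @param path bedGraph file path.
#' @return `read_bedgraph()` returns a tibble `chrom start end depth`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    depth = as.numeric(gr$score)
  )
}

#' @rdname read_bedgraph
#' @param bedgraph Tibble `chrom start end depth` (0-based half-open).
#' @export
write_bedgraph <- function(bedgraph, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = bedgraph$chrom,
    ranges = IRanges::IRanges(start = bedgraph$start + 1L, end = bedgraph$end),
    score = bedgraph$depth
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Per-base coverage profile over a region
#'
#' Expands bedGraph intervals into a per-nucleotide depth vector over
#' `[start, end)`; gaps are 0. Overlapping intervals are an error. For
#' minus-strand regions the vector is reversed so that position 1 is the
#' 5'-most base in transcript sense.
#'
#' @param bedgraph Tibble `chrom start end depth` (0-based half-open,
#'   non-overlapping), e.g. from [read_bedgraph()].
#' @param chrom,start,end Region (0-based half-open).
#' @param strand `"+"` or `"-"` (orientation of the returned vector).
#' @return Numeric vector of length `end - start`.
#' @export
profile_from_bedgraph <- function(bedgraph, chrom, start, end, strand = "+") {
  stopifnot(end > start)
  rows <- bedgraph |>
    filter(.data$chrom == !!chrom, .data$end > !!start, .data$start < !!end) |>
    arrange(.data$start)
  if (nrow(rows) > 1 && any(rows$start[-1] < rows$end[-nrow(rows)])) {
    abort("bedGraph intervals overlap within the requested region")
  }
  depth <- numeric(end - start)
  for (i in seq_len(nrow(rows))) {
    a <- max(rows$start[i], start) - start + 1L
    b <- min(rows$end[i], end) - start
    depth[a:b] <- rows$depth[i]
  }
  if (strand == "-") rev(depth) else depth
}

#' Assemble per-site coverage profiles for activation analysis
#'
#' For every catalog site, extracts the per-base coverage over its exon
#' extension region (between the annotated donor and the candidate GT, in
#' transcript sense) from each sample's bedGraph, and attaches the per-sample
#' normalisation factor: the number of split reads supporting the annotated
#' 5'SS junction in that sample (floored at 1 read-equivalent).
#'
#' @param catalog An `lss_catalog` (or subset of its rows).
#' @param coverage Named list of bedGraph tibbles, one per sample.
#' @param junctions Named list of `junction_counts`, aligned with `coverage`.
#' @return Tibble: `site_key sample_id condition replicate norm depth`
#'   (`depth` is a list column of per-base vectors).
#' @export
assemble_profiles <- function(catalog, coverage, junctions) {
  stopifnot(length(coverage) == length(junctions))
  purrr::imap(junctions, function(jx, nm) {
    bg <- coverage[[nm]]
    canon <- catalog |>
      left_join(
        select(as_tibble(jx), "chrom", donor = "donor", acceptor = "acceptor", canon = "count"),
        by = c("chrom", "intron_start" = "donor", "intron_end" = "acceptor")
      ) |>
      mutate(canon = tidyr::replace_na(.data$canon, 0L))
    ext <- purrr::map(seq_len(nrow(canon)), function(i) {
      row <- canon[i, ]
      if (row$strand == "-") {
        profile_from_bedgraph(bg, row$chrom, row$intron_end - row$extension_length,
          row$intron_end,
          strand = "-"
        )
      } else {
        profile_from_bedgraph(bg, row$chrom, row$intron_start,
          row$intron_start + row$extension_length,
          strand = "+"
        )
      }
    })
    tibble(
      site_key = canon$site_key,
      sample_id = attr(jx, "sample_id") %||% nm,
      condition = attr(jx, "condition"),
      replicate = attr(jx, "replicate"),
      norm = pmax(canon$canon, 1),
      depth = ext
    )
  }) |> bind_rows()
}
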