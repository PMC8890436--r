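#' Split-read junction counts
#'
#' A junction-count table is a tibble keyed by (chromosome, donor, acceptor)
#' in 0-based half-open genomic coordinates: `donor` is the first intronic
#' base of the gap and `acceptor` the first base after the gap, so
#' `[donor, acceptor)` is exactly the intron skipped by the split read.
#' Sample metadata (`sample_id`, `condition`, `replicate`) and the total
#' number of primary mapped reads travel as attributes.
#'
#' @name junction_counts
NULL

new_junction_counts <- function(tbl, sample_id, condition, replicate, total_mapped) {
  structure(
    arrange(tbl, .data$chrom, .data$donor, .data$acceptor),
    sample_id = sample_id, condition = condition, replicate = replicate,
    total_mapped = total_mapped,
    class = c("junction_counts", class(tbl))
  )
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf(
    "<junction_counts> sample=%s condition=%s replicate=%s total_mapped=%s\n",
    attr(x, "sample_id"), attr(x, "condition"), attr(x, "replicate"),
    format(attr(x, "total_mapped"))
  ))
  NextMethod()
}

# strand of a junction from the annotated splice sites at its ends
.infer_strand <- function(chrom, donor, acceptor, annotation) {
  if (is.null(annotation)) return(rep("*", length(chrom)))
  d <- annotation$donors
  a <- annotation$acceptors
  key <- function(c, p, s) paste(c, p, s, sep = ":")
  plus <- key(chrom, donor, "+") %in% key(d$chrom, d$pos, d$strand) |
    key(chrom, acceptor, "+") %in% key(a$chrom, a$pos, a$strand)
  minus <- key(chrom, acceptor - 1L, "-") %in% key(d$chrom, d$pos, d$strand) |
    key(chrom, donor, "-") %in% key(a$chrom, a$pos, a$strand)
  dplyr::case_when(plus & !minus ~ "+", minus & !plus ~ "-", TRUE ~ "*")
}

#' Extract junction counts from spliced alignments
#'
#' Reads a SAM (or BAM) file, skips secondary, supplementary and unmapped
#' records, and tallies one junction observation per `N` CIGAR operation at
#' its genomic gap. `total_mapped` is the number of primary mapped reads.
#' Junction strand is inferred from the annotation at the gap ends when an
#' annotation is supplied (`"*"` otherwise).
#'
#' @param sam Path to a SAM or BAM file.
#' @param annotation Optional `genome_annotation` for strand inference.
#' @param sample_id,condition,replicate Sample metadata attached as attributes;
#'   `condition` should be `"case"` or `"control"` for the activation caller.
#' @return A `junction_counts` tibble: `chrom donor acceptor strand count`.
#' @export
extract_junctions_from_sam <- function(sam, annotation = NULL,
                                       sample_id = basename(sam),
                                       condition = NA_character_,
                                       replicate = NA_integer_) {
  bam <- sam
  if (!grepl("\\.bam$", sam, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    )
  )
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  total_mapped <- length(gal)

  jx <- unlist(GenomicAlignments::junctions(gal), use.names = FALSE)
  tbl <- if (length(jx) == 0) {
    tibble(chrom = character(), donor = integer(), acceptor = integer())
  } else {
    tibble(
      chrom = as.character(GenomicRanges::seqnames(jx)),
      donor = GenomicRanges::start(jx) - 1L, # first intronic base, 0-based
      acceptor = GenomicRanges::end(jx) # one past the last intronic base
    )
  }
  tbl <- tbl |>
    count(.data$chrom, .data$donor, .data$acceptor, name = "count") |>
    mutate(strand = .infer_strand(.data$chrom, .data$donor, .data$acceptor, annotation)) |>
    select("chrom", "donor", "acceptor", "strand", "count")

  new_junction_counts(tbl, sample_id, condition, replicate, total_mapped)
}

#' Write / read a junction table as TSV
#'
#' Header comment lines carry the sample metadata and total mapped reads
#' (`#total_mapped=`); the body is `chrom donor acceptor strand count`.
#' A written table reloads identically.
#'
#' @param x A `junction_counts` tibble.
#' @param path File path.
#' @export
write_junctions <- function(x, path) {
  hdr <- c(
    paste0("#sample_id=", attr(x, "sample_id")),
    paste0("#condition=", attr(x, "condition")),
    paste0("#replicate=", attr(x, "replicate")),
    paste0("#total_mapped=", attr(x, "total_mapped"))
  )
  writeLines(hdr, path)
  readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_junctions
#' @export
read_junctions <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(name, cast = identity) {
    ln <- hdr[startsWith(hdr, paste0("#", name, "="))]
    if (length(ln) != 1) abort(paste0("junction file missing header: ", name))
    cast(sub(paste0("#", name, "="), "", ln))
  }
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      chrom = "c", donor = "i", acceptor = "i", strand = "c", count = "i"
    )
  )
  new_junction_counts(
    tbl,
    sample_id = get("sample_id"),
    condition = get("condition"),
    replicate = get("replicate", as.integer),
    total_mapped = get("total_mapped", as.numeric)
  )
}

#' Normalised LSS usage
#'
#' Usage of a latent junction relative to its canonical (annotated-donor)
#' junction: `lss_reads / canonical_reads`. Usage is undefined (not zero) when
#' the canonical junction has no split-read support; undefined records are
#' excluded from fold computations rather than pseudocounted.
#'
#' @param lss_reads,canonical_reads Nonnegative integer vectors (recycled).
#' @return Tibble with columns `lss_reads`, `canonical_reads`, `usage`,
#'   `defined`.
#' @export
#' @examples
#' usage_ratio(c(4, 0, 5), c(100, 100, 0))
usage_ratio <- function(lss_reads, canonical_reads) {
  if (any(lss_reads < 0) || any(canonical_reads < 0)) {
    abort("read counts must be nonnegative")
  }
  n <- max(length(lss_reads), length(canonical_reads))
  lss_reads <- rep_len(lss_reads, n)
  canonical_reads <- rep_len(canonical_reads, n)
  defined <- canonical_reads > 0
  tibble(
    lss_reads = lss_reads, canonical_reads = canonical_reads,
    usage = ifelse(defined, lss_reads / canonical_reads, NA_real_),
    defined = defined
  )
}

#' Depth-normalise junction counts
#'
#' Scales counts to reads per million primary mapped reads. Used for
#' cross-sample tallies of supported sites; never for usage ratios, which are
#' self-normalising.
#'
#' @param x A `junction_counts` tibble.
#' @return The same tibble with an added `cpm` column.
#' @export
depth_normalize <- function(x) {
  total <- attr(x, "total_mapped")
  if (is.null(total) || !is.finite(total) || total <= 0) {
    abort("total_mapped must be positive to depth-normalise")
  }
  mutate(x, cpm = .data$count * 1e6 / total)
}
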