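#' Genome annotation for latent-site scanning
#'
#' The internal annotation container holds, as tibbles with 0-based half-open
#' coordinates: transcript metadata, exon intervals, CDS intervals, and the set
#' of annotated donor and acceptor splice-site positions aggregated across all
#' provided annotation sources. Only multi-exon protein-coding transcripts are
#' retained for candidate generation, but annotated splice sites are collected
#' from every multi-exon transcript so that known donors are always excluded
#' from the latent-candidate set.
#'
#' Donor position = genomic 0-based position of the first intronic base in
#' transcript sense; acceptor position = 0-based position one past the last
#' intronic base on the plus strand (the half-open intron end), or the intron
#' start for minus-strand transcripts.
#'
#' @name genome_annotation
NULL

new_genome_annotation <- function(transcripts, exons, cds, donors, acceptors) {
  structure(
    list(
      transcripts = transcripts, exons = exons, cds = cds,
      donors = donors, acceptors = acceptors
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d coding multi-exon transcripts (%d genes), %d annotated donors\n",
    nrow(x$transcripts), dplyr::n_distinct(x$transcripts$gene_id), nrow(x$donors)
  ))
  invisible(x)
}

# light structural validation so malformed rows fail with a line number before
# the real parser runs
.check_gtf_lines <- function(path) {
  lines <- readLines(path)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  nfields <- lengths(strsplit(lines[data_idx], "\t", fixed = TRUE))
  bad <- data_idx[nfields < 9]
  if (length(bad) > 0) {
    abort(sprintf("malformed GTF line %d in %s (fewer than 9 tab-separated fields)", bad[1], path))
  }
  invisible(TRUE)
}

.import_gtf <- function(path) {
  .check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id)
  )
}

# order exons 5'->3' in transcript sense and attach ranks
.rank_exons <- function(ex) {
  ex |>
    group_by(.data$transcript_id) |>
    arrange(if_else(.data$strand == "-", -.data$start, .data$start), .by_group = TRUE) |>
    mutate(exon_rank = dplyr::row_number()) |>
    ungroup()
}

# donor/acceptor positions from ranked exons of one annotation source
.splice_sites <- function(ex) {
  introns <- ex |>
    group_by(.data$transcript_id, .data$chrom, .data$strand) |>
    arrange(.data$exon_rank, .by_group = TRUE) |>
    reframe(
      up_end = .data$end[-dplyr::n()], up_start = .data$start[-dplyr::n()],
      dn_start = .data$start[-1], dn_end = .data$end[-1]
    ) |>
    mutate(
      intron_start = pmin(.data$up_end, .data$dn_end),
      intron_end = pmax(.data$up_start, .data$dn_start),
      donor_pos = if_else(.data$strand == "-", .data$intron_end - 1L, .data$intron_start),
      acceptor_pos = if_else(.data$strand == "-", .data$intron_start, .data$intron_end)
    )
  list(
    donors = distinct(introns, .data$chrom, .data$strand, pos = .data$donor_pos),
    acceptors = distinct(introns, .data$chrom, .data$strand, pos = .data$acceptor_pos)
  )
}

#' Read gene annotation from GTF files
#'
#' Imports one or more GTF files (1-based inclusive coordinates on disk,
#' converted to 0-based half-open internally), keeps multi-exon protein-coding
#' transcripts (those with both exon and CDS features), and aggregates the
#' annotated splice-donor set as the union over all input files. Transcripts
#' whose CDS is not contained in their exons are skipped with a warning;
#' single-exon and non-coding transcripts are excluded from candidate
#' generation but still contribute their splice sites (if multi-exon) to the
#' annotated-donor set.
#'
#' @param gtf_paths Character vector of GTF file paths.
#' @param genome Optional genome ([Biostrings::DNAStringSet]); when given,
#'   chromosomes named in the GTF but absent from the genome raise an error.
#' @return A `genome_annotation` object.
#' @export
read_annotation <- function(gtf_paths, genome = NULL) {
  recs <- purrr::map(gtf_paths, .import_gtf)

  all_exons <- .rank_exons(bind_rows(recs) |> filter(.data$type == "exon"))
  multi <- all_exons |> count(.data$transcript_id) |> filter(.data$n >= 2)
  sites <- .splice_sites(semi_join(all_exons, multi, by = "transcript_id"))

  rec <- distinct(bind_rows(recs))
  exons <- .rank_exons(filter(rec, .data$type == "exon"))
  cds <- filter(rec, .data$type == "CDS") |> .rank_exons()

  # multi-exon and coding only
  keep <- exons |>
    count(.data$transcript_id, name = "n_exons") |>
    filter(.data$n_exons >= 2) |>
    semi_join(distinct(cds, .data$transcript_id), by = "transcript_id")

  # CDS must be contained in exons
  contained <- cds |>
    left_join(exons, by = c("transcript_id", "chrom", "strand"),
      suffix = c("", ".ex"), relationship = "many-to-many"
    ) |>
    group_by(.data$transcript_id, .data$start, .data$end) |>
    summarise(ok = any(.data$start >= .data$start.ex & .data$end <= .data$end.ex),
      .groups = "drop"
    ) |>
    group_by(.data$transcript_id) |>
    summarise(ok = all(.data$ok))
  bad_tx <- contained$transcript_id[!contained$ok]
  if (length(bad_tx) > 0) {
    warn(sprintf(
      "skipping %d transcript(s) with CDS not contained in exons: %s",
      length(bad_tx), paste(utils::head(bad_tx, 5), collapse = ", ")
    ))
    keep <- filter(keep, !.data$transcript_id %in% bad_tx)
  }

  exons <- semi_join(exons, keep, by = "transcript_id")
  cds <- semi_join(cds, keep, by = "transcript_id")
  transcripts <- exons |>
    distinct(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    left_join(
      cds |>
        group_by(.data$transcript_id) |>
        summarise(cds_length = sum(.data$end - .data$start)),
      by = "transcript_id"
    )

  ann <- new_genome_annotation(
    transcripts = transcripts,
    exons = select(exons, "transcript_id", "gene_id", "chrom", "strand",
      "start", "end", "exon_rank"
    ),
    cds = select(cds, "transcript_id", "gene_id", "chrom", "strand",
      "start", "end", "exon_rank"
    ),
    donors = sites$donors, acceptors = sites$acceptors
  )
  if (!is.null(genome)) .check_chroms(ann, genome)
  ann
}

.check_chroms <- function(annotation, genome) {
  missing <- setdiff(unique(annotation$exons$chrom), names(genome))
  if (length(missing) > 0) {
    abort(paste0(
      "chromosome(s) present in annotation but absent from genome: ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that strips FASTA
#' description text from the sequence names.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write annotation back to GTF
#'
#' Exports exon and CDS features (1-based inclusive on disk) with `gene_id`
#' and `transcript_id` attributes.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  cds <- annotation$cds |>
    group_by(.data$transcript_id) |>
    arrange(.data$exon_rank, .by_group = TRUE) |>
    mutate(phase = (3L - (cumsum(.data$end - .data$start) -
      (.data$end - .data$start)) %% 3L) %% 3L) |>
    ungroup()
  feats <- bind_rows(
    mutate(annotation$exons, type = "exon", phase = NA_integer_),
    mutate(cds, type = "CDS")
  )
  gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand,
    type = feats$type, source = "latsplice",
    phase = feats$phase,
    gene_id = feats$gene_id, transcript_id = feats$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
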