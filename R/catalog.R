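#' Latent and alternative donor-site catalogs
#'
#' A site catalog is a tibble of intronic GT dinucleotides that could act as
#' alternative 5' splice donors. Each candidate would extend the upstream
#' coding exon by `extension_length` nucleotides (1-1000) while leaving a
#' residual intron of at least 20 nt, must not coincide with an annotated
#' donor, and must pass the donor-model score threshold. Candidates are
#' classified by their reading-frame consequence:
#'
#' * `LSS` - the extension introduces at least one in-frame STOP codon
#'   (a premature termination codon if the site were used);
#' * `adSS_3n` - no in-frame STOP and the extension length is a multiple of 3
#'   (no PTC introduced);
#' * `adSS_fs` - no in-frame STOP but the extension shifts the reading frame,
#'   introducing a PTC downstream.
#'
#' Coordinates are 0-based half-open genomic; minus-strand introns are scanned
#' on the reverse complement.
#'
#' @name lss_catalog
NULL

# per-transcript within-CDS introns with sequence context.
# Returns one row per intron flanked by CDS-bearing exons whose CDS reaches
# the splice junction on both sides.
transcript_introns <- function(annotation, genome) {
  .check_chroms(annotation, genome)
  tx_ids <- annotation$transcripts$transcript_id
  ex_by_tx <- split(annotation$exons, annotation$exons$transcript_id)
  cds_by_tx <- split(annotation$cds, annotation$cds$transcript_id)

  rows <- purrr::map(tx_ids, function(tx) {
    ex <- arrange(ex_by_tx[[tx]], .data$exon_rank)
    cd <- arrange(cds_by_tx[[tx]], .data$exon_rank)
    strand <- ex$strand[1]
    chrom <- ex$chrom[1]

    # map each CDS interval to its containing exon rank
    cd$host_rank <- vapply(seq_len(nrow(cd)), function(i) {
      hit <- which(ex$start <= cd$start[i] & ex$end >= cd$end[i])
      if (length(hit) == 0) NA_integer_ else ex$exon_rank[hit[1]]
    }, integer(1))
    if (anyNA(cd$host_rank)) return(NULL)
    cd <- arrange(cd, .data$host_rank)

    cds_seq <- paste0(
      vapply(seq_len(nrow(cd)), function(i) {
        genome_subseq(genome, chrom, cd$start[i], cd$end[i], strand)
      }, ""),
      collapse = ""
    )
    cum <- cumsum(cd$end - cd$start)

    out <- list()
    for (i in seq_len(nrow(cd) - 1)) {
      up <- cd[i, ]
      dn <- cd[i + 1, ]
      if (dn$host_rank != up$host_rank + 1L) next # non-adjacent coding exons
      up_ex <- ex[ex$exon_rank == up$host_rank, ]
      dn_ex <- ex[ex$exon_rank == dn$host_rank, ]
      within_cds <- if (strand == "-") {
        up$start == up_ex$start && dn$end == dn_ex$end
      } else {
        up$end == up_ex$end && dn$start == dn_ex$start
      }
      if (!within_cds) next
      if (strand == "-") {
        intron_start <- dn_ex$end
        intron_end <- up_ex$start
      } else {
        intron_start <- up_ex$end
        intron_end <- dn_ex$start
      }
      if (cum[i] < 3) next # need 3 upstream coding bases for the donor 9-mer
      out[[length(out) + 1]] <- tibble(
        transcript_id = tx, gene_id = ex$gene_id[1], chrom = chrom, strand = strand,
        intron_start = intron_start, intron_end = intron_end,
        donor_pos = if (strand == "-") intron_end - 1L else intron_start,
        acceptor_pos = if (strand == "-") intron_start else intron_end,
        frame_offset = cum[i] %% 3L,
        last3 = substr(cds_seq, cum[i] - 2, cum[i]),
        intron_seq = genome_subseq(genome, chrom, intron_start, intron_end, strand),
        cds_length = cum[length(cum)]
      )
    }
    bind_rows(out)
  })
  bind_rows(rows)
}

#' Test an exon extension for an in-frame STOP codon
#'
#' Translates the extension region in the reading frame continued from the
#' upstream exon. `frame_offset` is the number of bases of the current codon
#' already emitted at the exon end (cumulative CDS length mod 3), so the first
#' codon may span the old exon/intron junction; such a codon counts as long as
#' at least one of its bases lies in the extension. A codon that would run past
#' the candidate GT (an incomplete trailing codon) never counts.
#'
#' @param extension Character vector of extension sequences (exon end up to,
#'   not including, the candidate GT), in transcript sense.
#' @param frame_offset Integer vector (0, 1 or 2), recycled.
#' @param upstream Upstream exonic sequence supplying the `frame_offset` bases
#'   that open the spanning codon (at least `frame_offset` characters;
#'   recycled).
#' @return Logical vector: `TRUE` if any complete in-frame codon within the
#'   extension (or spanning into it) is a STOP; `NA` for extensions containing
#'   non-ACGT characters.
#' @export
#' @examples
#' has_inframe_stop("TAAGGG", 0)       # TRUE: planted STOP
#' has_inframe_stop("GGGGGGGGG", 0)    # FALSE: no STOP, 9 nt
has_inframe_stop <- function(extension, frame_offset, upstream = "") {
  n <- length(extension)
  frame_offset <- rep_len(as.integer(frame_offset), n)
  upstream <- rep_len(upstream, n)
  vapply(seq_len(n), function(i) {
    f <- frame_offset[i]
    if (f > 0 && nchar(upstream[i]) < f) {
      abort("upstream sequence shorter than frame_offset")
    }
    prefix <- if (f > 0) substr(upstream[i], nchar(upstream[i]) - f + 1, nchar(upstream[i])) else ""
    full <- paste0(prefix, extension[i])
    if (grepl("[^ACGT]", full)) return(NA)
    nc <- nchar(full) %/% 3
    if (nc == 0) return(FALSE)
    codons <- substring(full, seq(1, 3 * nc - 2, by = 3), seq(3, 3 * nc, by = 3))
    any(codons %in% STOP_CODONS)
  }, logical(1))
}

#' Classify a candidate extension
#'
#' Assigns the site class from the in-frame STOP test and the extension
#' length: `LSS` if the extension introduces an in-frame STOP, otherwise
#' `adSS_3n` (length a multiple of 3) or `adSS_fs` (frameshifting length).
#'
#' @inheritParams has_inframe_stop
#' @return Character vector of classes (`"LSS"`, `"adSS_3n"`, `"adSS_fs"`), or
#'   `"rejected"` for extensions containing ambiguous bases.
#' @export
#' @examples
#' classify_extension("TAAGGG", 0)      # LSS
#' classify_extension("GGGGGGGGG", 0)   # adSS_3n
#' classify_extension("GGGGGGGGGC", 0)  # adSS_fs
classify_extension <- function(extension, frame_offset, upstream = "") {
  stop_flag <- has_inframe_stop(extension, frame_offset, upstream)
  dplyr::case_when(
    is.na(stop_flag) ~ "rejected",
    stop_flag ~ "LSS",
    nchar(extension) %% 3 == 0 ~ "adSS_3n",
    TRUE ~ "adSS_fs"
  )
}

#' Enumerate unclassified GT candidates
#'
#' Scans every within-CDS intron (in transcript sense) for GT dinucleotides
#' with extension length between `min_extension` and `max_extension` and a
#' residual intron of at least `min_residual` nt, excluding positions in the
#' annotated-donor set. Emitted once per parent annotated 5'SS.
#'
#' @param annotation A `genome_annotation`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param max_extension Maximum exon extension in nt (default 1000).
#' @param min_residual Minimum residual intron length in nt (default 20).
#' @return Tibble of unclassified candidates with sequence context columns.
#' @export
enumerate_candidates <- function(annotation, genome, max_extension = 1000L,
                                 min_residual = 20L) {
  introns <- transcript_introns(annotation, genome)
  if (nrow(introns) == 0) {
    return(structure(tibble(), introns = introns))
  }
  donor_keys <- paste(annotation$donors$chrom, annotation$donors$strand,
    annotation$donors$pos,
    sep = ":"
  )

  cand <- purrr::map(seq_len(nrow(introns)), function(i) {
    row <- introns[i, ]
    len <- nchar(row$intron_seq)
    ch <- strsplit(row$intron_seq, "", fixed = TRUE)[[1]]
    off <- which(ch[-len] == "G" & ch[-1] == "T") - 1L # 0-based GT offsets
    off <- off[off >= 1L & off <= max_extension & (len - off) >= min_residual]
    if (length(off) == 0) return(NULL)
    cand_donor <- if (row$strand == "-") row$intron_end - 1L - off else row$intron_start + off
    keep <- !(paste(row$chrom, row$strand, cand_donor, sep = ":") %in% donor_keys)
    off <- off[keep]
    cand_donor <- cand_donor[keep]
    if (length(off) == 0) return(NULL)
    context <- paste0(row$last3, row$intron_seq)
    tibble(
      chrom = row$chrom, strand = row$strand,
      gt_start = if (row$strand == "-") row$intron_end - off - 2L else row$intron_start + off,
      cand_donor_pos = cand_donor,
      parent5ss = row$donor_pos,
      extension_length = off,
      residual_intron = len - off,
      gap_start = if (row$strand == "-") row$intron_start else row$intron_start + off,
      gap_end = if (row$strand == "-") row$intron_end - off else row$intron_end,
      intron_start = row$intron_start, intron_end = row$intron_end,
      seq9 = substring(context, off + 1L, off + 9L),
      extension_seq = substring(context, 4L, off + 3L),
      frame_offset = row$frame_offset,
      upstream3 = row$last3,
      gene_id = row$gene_id, transcript_id = row$transcript_id,
      cds_length = row$cds_length
    )
  })
  structure(bind_rows(cand), introns = introns)
}

#' Build a site catalog
#'
#' Full pipeline over one genome + annotation: enumerate GT candidates, score
#' their donor 9-mers under `model`, drop candidates failing `threshold`,
#' classify the survivors, and deduplicate by
#' (chromosome, strand, GT position, parent 5'SS), merging transcript ids.
#' When transcripts of a gene disagree on the reading frame at a shared site,
#' the frame of the transcript with the longest CDS wins and the disagreement
#' is reported via [message()].
#'
#' @inheritParams enumerate_candidates
#' @param model A `donor_model` used for scoring.
#' @param threshold A `score_threshold` (or bare number); default inclusive 0.
#' @return A tibble of classified sites (class `lss_catalog`), one row per
#'   deduplicated candidate, with the scored annotated donors in
#'   `attr(, "donors")`.
#' @export
build_catalog <- function(annotation, genome, model,
                          threshold = score_threshold(0, inclusive = TRUE),
                          max_extension = 1000L, min_residual = 20L) {
  if (is.numeric(threshold)) threshold <- score_threshold(threshold)
  cand <- enumerate_candidates(annotation, genome, max_extension, min_residual)
  introns <- attr(cand, "introns")

  donors <- tibble()
  if (nrow(introns) > 0) {
    donors <- introns |>
      mutate(seq9 = paste0(.data$last3, substr(.data$intron_seq, 1, 6))) |>
      distinct(.data$chrom, .data$strand, .data$donor_pos, .data$seq9,
        .data$gene_id
      ) |>
      filter(!grepl("[^ACGT]", .data$seq9)) |>
      mutate(score = score_kmer(model, .data$seq9)) |>
      distinct(.data$chrom, .data$strand, .data$donor_pos, .keep_all = TRUE)
  }

  empty <- tibble(
    site_key = character(), chrom = character(), strand = character(),
    gt_start = integer(), parent5ss = integer(), extension_length = integer(),
    residual_intron = integer(), site_class = character(),
    has_inframe_stop = logical(), score = numeric(), seq9 = character(),
    gene_id = character(), transcript_ids = character(),
    intron_start = integer(), intron_end = integer(),
    gap_start = integer(), gap_end = integer()
  )
  if (nrow(cand) == 0) {
    return(structure(empty, donors = donors, threshold = threshold,
      class = c("lss_catalog", class(empty))
    ))
  }

  cand <- cand |>
    filter(!grepl("[^ACGT]", .data$seq9)) |>
    mutate(score = score_kmer(model, .data$seq9)) |>
    filter(passes_threshold(.data$score, threshold)) |>
    mutate(
      has_stop = has_inframe_stop(.data$extension_seq, .data$frame_offset, .data$upstream3),
      site_class = classify_extension(.data$extension_seq, .data$frame_offset, .data$upstream3)
    ) |>
    filter(.data$site_class != "rejected")

  if (nrow(cand) == 0) {
    return(structure(empty, donors = donors, threshold = threshold,
      class = c("lss_catalog", class(empty))
    ))
  }

  grouped <- cand |>
    group_by(.data$chrom, .data$strand, .data$gt_start, .data$parent5ss)
  n_disagree <- grouped |>
    summarise(d = dplyr::n_distinct(.data$site_class) > 1, .groups = "drop") |>
    summarise(n = sum(.data$d)) |>
    dplyr::pull(.data$n)
  if (n_disagree > 0) {
    message(sprintf(
      "%d site(s) with transcript frame disagreement; using the longest-CDS transcript",
      n_disagree
    ))
  }

  catalog <- grouped |>
    arrange(desc(.data$cds_length), .data$transcript_id, .by_group = TRUE) |>
    summarise(
      extension_length = dplyr::first(.data$extension_length),
      residual_intron = dplyr::first(.data$residual_intron),
      site_class = dplyr::first(.data$site_class),
      has_inframe_stop = dplyr::first(.data$has_stop),
      score = dplyr::first(.data$score),
      seq9 = dplyr::first(.data$seq9),
      gene_id = dplyr::first(.data$gene_id),
      transcript_ids = paste(unique(.data$transcript_id), collapse = ","),
      intron_start = dplyr::first(.data$intron_start),
      intron_end = dplyr::first(.data$intron_end),
      gap_start = dplyr::first(.data$gap_start),
      gap_end = dplyr::first(.data$gap_end),
      .groups = "drop"
    ) |>
    mutate(site_key = paste(.data$chrom, .data$strand, .data$gt_start,
      .data$parent5ss,
      sep = ":"
    )) |>
    select(names(empty)) |>
    arrange(.data$chrom, .data$gt_start)

  structure(catalog, donors = donors, threshold = threshold,
    class = c("lss_catalog", class(catalog))
  )
}

#' Summarise a site catalog
#'
#' Per-5'SS and per-gene summaries for one site class (default `LSS`):
#' the highest-scoring and closest latent site per annotated donor, the score
#' difference (annotated donor score minus strongest latent score), whether a
#' stronger latent site exists, extension-length distributions, and per-gene
#' site counts (strand-agnostic).
#'
#' @param catalog An `lss_catalog`.
#' @param site_class Class to summarise (default `"LSS"`).
#' @return List with elements `per_5ss`, `per_gene` and `overall` (tibbles).
#' @export
summarize_catalog <- function(catalog, site_class = "LSS") {
  stopifnot(inherits(catalog, "lss_catalog"))
  donors <- attr(catalog, "donors")
  sites <- filter(catalog, .data$site_class == !!site_class)
  if (nrow(sites) == 0) abort("catalog has no sites of the requested class")

  per_5ss <- sites |>
    group_by(.data$chrom, .data$strand, .data$parent5ss) |>
    summarise(
      n_sites = dplyr::n(),
      strongest_score = max(.data$score),
      strongest_extension = .data$extension_length[which.max(.data$score)],
      closest_extension = min(.data$extension_length),
      .groups = "drop"
    ) |>
    left_join(
      select(donors, "chrom", "strand", parent5ss = "donor_pos", donor_score = "score"),
      by = c("chrom", "strand", "parent5ss")
    ) |>
    mutate(
      score_diff = .data$donor_score - .data$strongest_score,
      stronger_exists = .data$strongest_score > .data$donor_score
    )

  per_gene <- sites |> count(.data$gene_id, name = "n_sites")

  overall <- tibble(
    site_class = site_class,
    n_sites = nrow(sites),
    n_5ss = nrow(per_5ss),
    n_genes = nrow(per_gene),
    frac_5ss_with_stronger = mean(per_5ss$stronger_exists, na.rm = TRUE),
    median_site_score = stats::median(sites$score),
    median_donor_score = stats::median(per_5ss$donor_score, na.rm = TRUE),
    mean_strongest_extension = mean(per_5ss$strongest_extension)
  )

  list(per_5ss = per_5ss, per_gene = per_gene, overall = overall)
}

#' Write / read a catalog as BED-like TSV
#'
#' Columns: `chrom start end name score strand class extension_len
#' residual_intron has_stop gene parent5ss` plus the intron and junction-gap
#' coordinates needed to re-attach junction counts. Coordinates are 0-based
#' half-open.
#'
#' @param catalog An `lss_catalog`.
#' @param path Output path.
#' @return `write_catalog()` returns `path` invisibly; `read_catalog()` an
#'   `lss_catalog` tibble (without the scored-donor attribute).
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog |>
    transmute(
      chrom = .data$chrom, start = .data$gt_start, end = .data$gt_start + 2L,
      name = .data$site_key, score = .data$score, strand = .data$strand,
      class = .data$site_class, extension_len = .data$extension_length,
      residual_intron = .data$residual_intron, has_stop = .data$has_inframe_stop,
      gene = .data$gene_id, parent5ss = .data$parent5ss,
      intron_start = .data$intron_start, intron_end = .data$intron_end,
      gap_start = .data$gap_start, gap_end = .data$gap_end,
      transcript_ids = .data$transcript_ids, seq9 = .data$seq9
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  catalog <- tibble(
    site_key = x$name, chrom = x$chrom, strand = x$strand,
    gt_start = as.integer(x$start), parent5ss = as.integer(x$parent5ss),
    extension_length = as.integer(x$extension_len),
    residual_intron = as.integer(x$residual_intron),
    site_class = x$class, has_inframe_stop = x$has_stop, score = x$score,
    seq9 = x$seq9, gene_id = x$gene, transcript_ids = x$transcript_ids,
    intron_start = as.integer(x$intron_start), intron_end = as.integer(x$intron_end),
    gap_start = as.integer(x$gap_start), gap_end = as.integer(x$gap_end)
  )
  structure(catalog, class = c("lss_catalog", class(catalog)))
}
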