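#' Simulation parameters for synthetic latent-splicing experiments
#'
#' Defines a toy multi-exon coding annotation with planted candidate donor
#' sites of all three classes and a 2-case / 2-control split-read experiment
#' with a known activation truth. Defaults emulate a modest bulk RNA-seq
#' knockdown design: negative-binomial canonical junction counts
#' (overdispersed, mean 200), latent junctions at 1% of canonical usage,
#' a 5-fold usage increase at activated sites in case samples, and mild
#' log-normal replicate jitter.
#'
#' @param n_genes Number of genes (one chromosome each).
#' @param exons_per_gene Integer range (min, max) of exons per gene.
#' @param exon_length Integer range of exon lengths (nt).
#' @param intron_length Integer range of intron lengths (nt).
#' @param n_planted Named integer vector: planted sites per class
#'   (`LSS`, `adSS_3n`, `adSS_fs`); at most one per intron.
#' @param n_activated Named integer vector: how many planted sites of each
#'   class are activated in case samples.
#' @param planted_score_range Target donor-model score window for planted
#'   sites (log2 units).
#' @param annotated_min_score Minimum score for sampled annotated donors.
#' @param extension_range Integer range of planted extension lengths (nt;
#'   minimum 12).
#' @param canonical_mean,canonical_dispersion Negative-binomial mean and
#'   dispersion of canonical junction counts (variance
#'   `mu + dispersion * mu^2`).
#' @param baseline_usage Latent usage as a fraction of canonical support.
#' @param effect_fold Usage fold increase at activated sites in cases (> 1,
#'   or exactly 1 for a null experiment).
#' @param depth Total primary mapped reads recorded per sample.
#' @param replicate_jitter_sd Standard deviation of the per-replicate
#'   log-normal usage jitter.
#' @param coverage_read_length Read length used for the exon-extension
#'   coverage pileup (nt).
#' @param background_gt If `TRUE` (default), intron background sequence may
#'   contain chance GT dinucleotides (realistic); if `FALSE`, background GTs
#'   are suppressed so the catalog contains exactly the planted sites.
#' @param flank Flanking sequence per chromosome end (nt).
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_genes = 8L,
                       exons_per_gene = c(3L, 5L),
                       exon_length = c(90L, 150L),
                       intron_length = c(300L, 500L),
                       n_planted = c(LSS = 6L, adSS_3n = 3L, adSS_fs = 3L),
                       n_activated = c(LSS = 4L, adSS_3n = 0L, adSS_fs = 0L),
                       planted_score_range = c(2, 10),
                       annotated_min_score = 3,
                       extension_range = c(30L, 250L),
                       canonical_mean = 200,
                       canonical_dispersion = 0.15,
                       baseline_usage = 0.01,
                       effect_fold = 5,
                       depth = 5e4,
                       replicate_jitter_sd = 0.1,
                       coverage_read_length = 50L,
                       background_gt = TRUE,
                       flank = 100L) {
  p <- as.list(environment())
  if (any(p$n_activated > p$n_planted[names(p$n_activated)])) {
    abort("n_activated cannot exceed n_planted for any class")
  }
  if (p$baseline_usage < 0 || p$baseline_usage >= 1) abort("baseline_usage must lie in [0, 1)")
  if (p$effect_fold < 1) abort("effect_fold must be >= 1")
  if (p$extension_range[1] < 12) abort("planted extensions need at least 12 nt")
  if (p$extension_range[2] > p$intron_length[1] - 26) {
    abort("extension_range too long for intron_length (need residual intron >= 20 plus donor context)")
  }
  if (p$n_planted["adSS_3n"] > 0 &&
    !any(seq(p$extension_range[1], p$extension_range[2]) %% 3 == 0)) {
    abort("infeasible: adSS_3n requires an extension length divisible by 3 within extension_range")
  }
  n_introns <- p$n_genes * (p$exons_per_gene[1] - 1L)
  if (sum(p$n_planted) > n_introns) {
    abort(sprintf(
      "infeasible: %d planted sites but only %d guaranteed introns",
      sum(p$n_planted), n_introns
    ))
  }
  structure(p, class = "sim_params")
}

# donor 9-mer consensus sampler (AG|GTRAGT-like); the model training source
.donor_consensus_pwm <- function() {
  m <- matrix(c(
    # A     C     G     T
    0.35, 0.35, 0.20, 0.10, # -3
    0.60, 0.12, 0.13, 0.15, # -2
    0.10, 0.03, 0.82, 0.05, # -1
    0.00, 0.00, 1.00, 0.00, # +1 (G)
    0.00, 0.00, 0.00, 1.00, # +2 (T)
    0.55, 0.02, 0.41, 0.02, # +3 (R)
    0.70, 0.08, 0.11, 0.11, # +4
    0.08, 0.05, 0.80, 0.07, # +5
    0.18, 0.16, 0.19, 0.47  # +6
  ), nrow = 4)
  rownames(m) <- DNA_BASES
  m
}

.sample_donor9 <- function(n, pwm = .donor_consensus_pwm()) {
  chars <- vapply(seq_len(ncol(pwm)), function(j) {
    sample(DNA_BASES, n, replace = TRUE, prob = pwm[, j])
  }, character(n))
  if (n == 1) paste(chars, collapse = "") else apply(chars, 1, paste, collapse = "")
}

#' Training sequences for the default donor model
#'
#' Donor 9-mers sampled from the package's donor consensus (AG|GTRAGT with
#' position-specific noise), under a fixed internal seed so the default model
#' is reproducible.
#'
#' @param n Number of sequences (default 500).
#' @param seed RNG seed (default 1).
#' @return Character vector of 9-mers.
#' @export
donor_training_sequences <- function(n = 500L, seed = 1L) {
  with_seed(seed, .sample_donor9(n))
}

#' Default donor model
#'
#' Maximum-entropy donor model (singleton + adjacent-pair constraints) fitted
#' to [donor_training_sequences()]. Cached per session.
#'
#' @return A `donor_model`.
#' @export
default_donor_model <- function() {
  if (is.null(.latsplice_env$default_model)) {
    .latsplice_env$default_model <- fit_maxent(donor_training_sequences())
  }
  .latsplice_env$default_model
}

# random background sequence; optionally GT-free
.background_seq <- function(n, allow_gt = TRUE) {
  if (n <= 0) return("")
  ch <- sample(DNA_BASES, n, replace = TRUE)
  if (!allow_gt && n >= 2) {
    repeat {
      gt <- which(ch[-n] == "G" & ch[-1] == "T")
      if (length(gt) == 0) break
      ch[gt + 1] <- "C"
    }
  }
  paste(ch, collapse = "")
}

# rejection-sample a 9-mer whose score falls in `window`, with GT only at
# positions 4-5 (and nowhere else)
.sample_scored_9mer <- function(model, window, max_attempts = 10000L) {
  for (i in seq_len(max_attempts)) {
    s <- if (i %% 2 == 1) {
      .sample_donor9(1)
    } else { # uniform proposal reaches low-probability windows
      paste0(
        paste(sample(DNA_BASES, 3, replace = TRUE), collapse = ""), "GT",
        paste(sample(DNA_BASES, 4, replace = TRUE), collapse = "")
      )
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    gt_at <- which(ch[-9] == "G" & ch[-1] == "T")
    if (!identical(gt_at, 4L)) next
    sc <- score_kmer(model, s)
    if (sc >= window[1] && sc <= window[2]) {
      return(list(seq = s, score = sc))
    }
  }
  abort(sprintf(
    "could not sample a donor 9-mer with score in [%.2f, %.2f] after %d attempts",
    window[1], window[2], max_attempts
  ))
}

# construct one intron sequence (sense space), optionally with a planted site.
# Returns list(seq, planted = NULL | list(extension, class, score, seq9))
.build_intron <- function(len, frame_offset, site = NULL, model, params,
                          max_attempts = 10000L) {
  allow_gt <- params$background_gt
  for (attempt in seq_len(max_attempts)) {
    donor <- .sample_scored_9mer(model, c(params$annotated_min_score, Inf))
    last3 <- substr(donor$seq, 1, 3)
    suffix6 <- substr(donor$seq, 4, 9)
    if (is.null(site)) {
      body <- .background_seq(len - 8L, allow_gt = allow_gt)
      # no GT across the suffix/body and body/AG boundaries in controlled mode
      if (!allow_gt && substr(body, 1, 1) == "T") {
        body <- paste0("A", substr(body, 2, nchar(body)))
      }
      return(list(
        seq = paste0(suffix6, body, "AG"), donor9 = donor$seq,
        last3 = last3, planted = NULL
      ))
    }

    e <- site$extension
    cand <- .sample_scored_9mer(model, params$planted_score_range)
    cand_prefix <- substr(cand$seq, 1, 3)
    # extension body: T-free (stop-free, GT-free) codon filler between the
    # donor suffix and the planted 9-mer prefix
    body_len <- e - 9L # offsets 6 .. e-4
    body <- paste(sample(c("A", "C", "G"), body_len, replace = TRUE), collapse = "")
    if (substr(body, body_len, body_len) == "G" && substr(cand_prefix, 1, 1) == "T") {
      body <- paste0(substr(body, 1, body_len - 1), "A")
    }
    ext <- paste0(suffix6, body, cand_prefix)

    if (site$class == "LSS") {
      ch <- strsplit(ext, "", fixed = TRUE)[[1]]
      starts <- seq_len(e - 2) - 1L # 0-based codon starts
      starts <- starts[(frame_offset + starts) %% 3 == 0 & starts >= 6 & (starts + 2) <= (e - 4)]
      if (length(starts) == 0) next
      i <- starts[ceiling(length(starts) / 2)] + 1L # 1-based
      ch[i:(i + 2)] <- c("T", "A", "A")
      if (i > 1 && ch[i - 1] == "G") ch[i - 1] <- "A" # avoid creating a GT
      ext <- paste(ch, collapse = "")
    }
    if (classify_extension(ext, frame_offset, last3) != site$class) next

    post_len <- len - e - 6L - 2L # between planted suffix and trailing AG
    post <- .background_seq(post_len, allow_gt = allow_gt)
    if (!allow_gt && post_len > 0 &&
      substr(cand$seq, 9, 9) == "G" && substr(post, 1, 1) == "T") {
      post <- paste0("A", substr(post, 2, post_len))
    }
    seq <- paste0(ext, substr(cand$seq, 4, 9), post, "AG")
    # verify the full planted construct
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    gt_off <- which(ch[-len] == "G" & ch[-1] == "T") - 1L
    if (!(e %in% gt_off)) next
    if (!allow_gt && !setequal(gt_off, c(0L, e))) next
    return(list(
      seq = seq, donor9 = donor$seq, last3 = last3,
      planted = list(
        extension = e, class = site$class, score = cand$score,
        seq9 = cand$seq
      )
    ))
  }
  abort("could not construct a planted intron within the attempt budget")
}

# sample a planted extension length compatible with the class
.sample_extension <- function(class, range) {
  pool <- seq(range[1], range[2])
  pool <- switch(class,
    adSS_3n = pool[pool %% 3 == 0],
    adSS_fs = pool[pool %% 3 != 0],
    pool
  )
  if (length(pool) == 0) abort("no feasible extension length for class ", class)
  pool[sample.int(length(pool), 1)]
}

#' Generate a synthetic reference (genome + annotation + truth)
#'
#' Builds a toy genome of single-transcript multi-exon coding genes (one
#' chromosome per gene, alternating strands), with consensus-like annotated
#' donors and planted latent/alternative donor sites of the requested classes:
#' LSS extensions carry an in-frame STOP, adSS extensions are STOP-free with
#' the class-appropriate length modulo 3, and planted 9-mers are
#' rejection-sampled to the target score window. Fully deterministic given
#' `(params, seed)`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer RNG seed.
#' @param model Donor model used for score control (default
#'   [default_donor_model()]).
#' @return A `lss_reference` list: `genome` ([Biostrings::DNAStringSet]),
#'   `annotation` (`genome_annotation`), `truth` (tibble of planted sites with
#'   `activated` flags), `params`, `model`.
#' @export
generate_reference <- function(params = sim_params(), seed = 1L,
                               model = default_donor_model()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)

  # assign planted sites to (gene, intron) slots
  gene_exons <- sample(seq(params$exons_per_gene[1], params$exons_per_gene[2]),
    params$n_genes,
    replace = TRUE
  )
  slots <- purrr::map(seq_len(params$n_genes), function(g) {
    tibble(gene = g, intron = seq_len(gene_exons[g] - 1L))
  }) |> bind_rows()
  classes <- rep(names(params$n_planted), params$n_planted)
  if (length(classes) > nrow(slots)) abort("infeasible: more planted sites than introns")
  picked <- slots[sample.int(nrow(slots), length(classes)), , drop = FALSE]
  picked$class <- sample(classes) # shuffle class-to-slot assignment
  activated_flags <- unlist(purrr::map(names(params$n_planted), function(cl) {
    n_cl <- params$n_planted[[cl]]
    c(rep(TRUE, params$n_activated[[cl]]), rep(FALSE, n_cl - params$n_activated[[cl]]))
  }))
  picked$activated <- FALSE
  for (cl in names(params$n_planted)) {
    idx <- which(picked$class == cl)
    picked$activated[idx] <- utils::head(
      c(rep(TRUE, params$n_activated[[cl]]), rep(FALSE, length(idx))),
      length(idx)
    )
  }

  genomes <- character(params$n_genes)
  chrom_names <- sprintf("chrS%02d", seq_len(params$n_genes))
  strands <- rep(c("+", "-"), length.out = params$n_genes)
  exon_rows <- list()
  truth_rows <- list()

  for (g in seq_len(params$n_genes)) {
    n_ex <- gene_exons[g]
    ex_len <- sample(seq(params$exon_length[1], params$exon_length[2]), n_ex, replace = TRUE)
    total_cds <- sum(ex_len)
    ex_len[n_ex] <- ex_len[n_ex] + (3L - total_cds %% 3L) %% 3L
    in_len <- sample(seq(params$intron_length[1], params$intron_length[2]),
      n_ex - 1L,
      replace = TRUE
    )
    cum_cds <- cumsum(ex_len)

    exon_seqs <- vapply(ex_len, .background_seq, "", allow_gt = TRUE)
    exon_seqs[1] <- paste0("ATG", substr(exon_seqs[1], 4, ex_len[1]))
    exon_seqs[n_ex] <- paste0(
      substr(exon_seqs[n_ex], 1, ex_len[n_ex] - 3), "TAA"
    )

    intron_seqs <- character(n_ex - 1L)
    gene_truth <- list()
    for (j in seq_len(n_ex - 1L)) {
      site_row <- picked[picked$gene == g & picked$intron == j, ]
      site <- NULL
      if (nrow(site_row) == 1) {
        site <- list(
          class = site_row$class,
          extension = .sample_extension(site_row$class, params$extension_range)
        )
      }
      built <- .build_intron(in_len[j], cum_cds[j] %% 3L, site, model, params)
      intron_seqs[j] <- built$seq
      # overwrite donor exon tail with the sampled donor 9-mer prefix
      exon_seqs[j] <- paste0(
        substr(exon_seqs[j], 1, ex_len[j] - 3), built$last3
      )
      if (!is.null(built$planted)) {
        gene_truth[[length(gene_truth) + 1]] <- tibble(
          gene = g, intron = j, site_class = built$planted$class,
          extension_length = built$planted$extension,
          score = built$planted$score, seq9 = built$planted$seq9,
          activated = site_row$activated
        )
      }
    }

    # sense-space coordinates
    sense_seq <- paste0(
      .background_seq(params$flank, allow_gt = TRUE),
      paste0(purrr::map_chr(seq_len(n_ex), function(i) {
        paste0(exon_seqs[i], if (i < n_ex) intron_seqs[i] else "")
      }), collapse = ""),
      .background_seq(params$flank, allow_gt = TRUE)
    )
    M <- nchar(sense_seq)
    starts <- params$flank + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ex_s <- starts
    ex_e <- starts + ex_len
    in_s <- ex_e[-n_ex]
    in_e <- ex_s[-1]

    strand <- strands[g]
    flip <- function(a, b) if (strand == "-") cbind(M - b, M - a) else cbind(a, b)
    genomes[g] <- if (strand == "-") revcomp(sense_seq) else sense_seq

    ex_g <- flip(ex_s, ex_e)
    exon_rows[[g]] <- tibble(
      transcript_id = sprintf("tx%02d", g), gene_id = sprintf("gene%02d", g),
      chrom = chrom_names[g], strand = strand,
      start = as.integer(ex_g[, 1]), end = as.integer(ex_g[, 2]),
      exon_rank = seq_len(n_ex)
    )

    for (tr in gene_truth) {
      j <- tr$intron
      e <- tr$extension_length
      ig <- flip(in_s[j], in_e[j])
      gt_sense <- in_s[j] + e
      gt_g <- flip(gt_sense, gt_sense + 2L)
      gap_sense <- c(in_s[j] + e, in_e[j])
      gap_g <- flip(gap_sense[1], gap_sense[2])
      donor_sense <- in_s[j] # first intron base in sense space
      parent5ss <- if (strand == "-") M - 1L - donor_sense else donor_sense
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        gene_id = sprintf("gene%02d", g), transcript_id = sprintf("tx%02d", g),
        chrom = chrom_names[g], strand = strand,
        site_class = tr$site_class, activated = tr$activated,
        effect_fold = ifelse(tr$activated, params$effect_fold, 1),
        extension_length = e,
        gt_start = as.integer(gt_g[1]), parent5ss = as.integer(parent5ss),
        intron_start = as.integer(ig[1]), intron_end = as.integer(ig[2]),
        gap_start = as.integer(gap_g[1]), gap_end = as.integer(gap_g[2]),
        score = tr$score, seq9 = tr$seq9
      )
    }
  }

  exons <- bind_rows(exon_rows)
  truth <- bind_rows(truth_rows) |>
    mutate(site_key = paste(.data$chrom, .data$strand, .data$gt_start,
      .data$parent5ss,
      sep = ":"
    ))
  sites <- .splice_sites(exons)
  transcripts <- exons |>
    distinct(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    left_join(
      exons |> group_by(.data$transcript_id) |>
        summarise(cds_length = sum(.data$end - .data$start)),
      by = "transcript_id"
    )
  annotation <- new_genome_annotation(
    transcripts = transcripts, exons = exons, cds = exons,
    donors = sites$donors, acceptors = sites$acceptors
  )
  genome <- Biostrings::DNAStringSet(stats::setNames(genomes, chrom_names))

  structure(
    list(
      genome = genome, annotation = annotation, truth = truth,
      params = params, model = model, seed = seed
    ),
    class = "lss_reference"
  )
}

#' Simulate a 2-case / 2-control split-read experiment
#'
#' Each intron receives a gamma-distributed expression level shared across
#' samples, and per-sample canonical counts are Poisson around it, so marginal
#' canonical counts are negative binomial with the requested mean and
#' dispersion while biological replicates stay correlated as in real RNA-seq.
#' Latent junction counts are Poisson with mean `expression * usage`, where
#' usage is `baseline_usage` multiplied by the effect fold in case samples at
#' activated sites, with per-replicate log-normal jitter. Exon-extension
#' coverage is a piecewise-constant read pileup whose Poisson read count is
#' scaled so the expected per-base depth equals the latent junction count.
#' Fully deterministic given `(reference, seed)`.
#'
#' @param reference An `lss_reference` from [generate_reference()].
#' @param seed Integer RNG seed.
#' @return An `lss_experiment` list: `junctions` (named list of 4
#'   `junction_counts`), `coverage` (named list of 4 bedGraph tibbles),
#'   `samples` (metadata tibble), `truth`, `params`.
#' @export
simulate_experiment <- function(reference, seed = 1L) {
  stopifnot(inherits(reference, "lss_reference"))
  params <- reference$params
  set.seed(seed + 1L)

  samples <- tibble(
    sample_id = c("case_rep1", "case_rep2", "control_rep1", "control_rep2"),
    condition = c("case", "case", "control", "control"),
    replicate = c(1L, 2L, 1L, 2L)
  )

  introns <- transcript_introns(reference$annotation, reference$genome) |>
    mutate(
      gap_start = .data$intron_start, gap_end = .data$intron_end
    )
  truth <- reference$truth
  size <- 1 / params$canonical_dispersion

  # per-site expression shared across samples (gamma-mixed, so marginal counts
  # are negative binomial with the requested mean and dispersion); per-sample
  # variation is Poisson sequencing noise
  site_mean <- stats::rgamma(nrow(introns), shape = size,
    scale = params$canonical_mean / size
  )
  canon_key <- paste(introns$chrom, introns$intron_start, introns$intron_end, sep = ":")
  truth_mean <- site_mean[match(
    paste(truth$chrom, truth$intron_start, truth$intron_end, sep = ":"),
    canon_key
  )]

  junctions <- list()
  coverage <- list()
  for (si in seq_len(nrow(samples))) {
    cond <- samples$condition[si]
    canonical <- as.integer(stats::rpois(nrow(introns), site_mean))

    usage <- params$baseline_usage *
      exp(stats::rnorm(nrow(truth), 0, params$replicate_jitter_sd)) *
      ifelse(truth$activated & cond == "case", params$effect_fold, 1)
    latent <- as.integer(stats::rpois(nrow(truth), truth_mean * usage))

    tbl <- bind_rows(
      tibble(
        chrom = introns$chrom, donor = as.integer(introns$intron_start),
        acceptor = as.integer(introns$intron_end), strand = introns$strand,
        count = canonical
      ),
      tibble(
        chrom = truth$chrom, donor = as.integer(truth$gap_start),
        acceptor = as.integer(truth$gap_end), strand = truth$strand,
        count = latent
      )
    ) |> filter(.data$count > 0)

    n_junction_reads <- sum(tbl$count)
    total <- max(params$depth, n_junction_reads)
    if (params$depth < n_junction_reads) {
      warn("sequencing depth lower than simulated junction reads; total_mapped raised to match")
    }
    junctions[[samples$sample_id[si]]] <- new_junction_counts(
      tbl,
      sample_id = samples$sample_id[si], condition = cond,
      replicate = samples$replicate[si], total_mapped = total
    )

    cov_rows <- purrr::map(seq_len(nrow(truth)), function(ti) {
      lam <- latent[ti]
      ext <- truth$extension_length[ti]
      region_start <- if (truth$strand[ti] == "-") {
        truth$intron_end[ti] - ext
      } else {
        truth$intron_start[ti]
      }
      # read pileup: expected per-base depth equals the latent read count
      rl <- params$coverage_read_length
      n_reads <- stats::rpois(1, lam * (ext + rl - 1) / rl)
      if (n_reads == 0) return(NULL)
      starts <- sample.int(ext + rl - 1L, n_reads, replace = TRUE) - rl # 0-based, rel.
      depth <- integer(ext)
      for (rs in starts) {
        a <- max(rs, 0L) + 1L
        b <- min(rs + rl, ext)
        if (b >= a) depth[a:b] <- depth[a:b] + 1L
      }
      r <- rle(depth)
      ends <- cumsum(r$lengths)
      keep <- r$values > 0
      if (!any(keep)) return(NULL)
      tibble(
        chrom = truth$chrom[ti],
        start = as.integer(region_start + (ends - r$lengths)[keep]),
        end = as.integer(region_start + ends[keep]),
        depth = as.numeric(r$values[keep])
      )
    })
    coverage[[samples$sample_id[si]]] <- bind_rows(cov_rows) |>
      arrange(.data$chrom, .data$start)
  }

  structure(
    list(
      junctions = junctions, coverage = coverage, samples = samples,
      truth = truth, params = params, seed = seed
    ),
    class = "lss_experiment"
  )
}

#' Write reference and experiment files
#'
#' `write_reference()` writes `ref.fa`, `genes.gtf` and `truth.tsv`;
#' `write_experiment()` writes per-sample junction TSVs and bedGraphs;
#' `emit_sam()` writes per-sample SAM files whose spliced reads reproduce the
#' junction counts exactly (20M gap 20M CIGARs) padded with ungapped 30M reads
#' so that the number of primary mapped records equals `total_mapped`.
#'
#' @param reference An `lss_reference`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(reference$genome, file.path(dir, "ref.fa"))
  write_annotation_gtf(reference$annotation, file.path(dir, "genes.gtf"))
  readr::write_tsv(reference$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_reference
#' @param experiment An `lss_experiment`.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(experiment$junctions)) {
    write_junctions(experiment$junctions[[nm]], file.path(dir, paste0(nm, ".junctions.tsv")))
    write_bedgraph(experiment$coverage[[nm]], file.path(dir, paste0(nm, ".coverage.bedgraph")))
  }
  invisible(dir)
}

#' @rdname write_reference
#' @export
emit_sam <- function(experiment, reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom_len <- Biostrings::width(reference$genome)
  names(chrom_len) <- names(reference$genome)
  paths <- character(0)
  for (nm in names(experiment$junctions)) {
    jx <- experiment$junctions[[nm]]
    hdr <- c(
      "@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len), chrom_len)
    )
    body <- character(0)
    rid <- 0L
    for (i in seq_len(nrow(jx))) {
      gap <- jx$acceptor[i] - jx$donor[i]
      pos <- jx$donor[i] - 20L + 1L # 1-based read start
      cigar <- sprintf("20M%dN20M", gap)
      ids <- sprintf("read_%s_%d", nm, rid + seq_len(jx$count[i]))
      rid <- rid + jx$count[i]
      body <- c(body, sprintf(
        "%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*", ids, jx$chrom[i], pos, cigar
      ))
    }
    n_fill <- attr(jx, "total_mapped") - length(body)
    if (n_fill > 0) {
      chrom1 <- names(chrom_len)[1]
      body <- c(body, sprintf(
        "filler_%s_%d\t0\t%s\t1\t60\t30M\t*\t0\t0\t*\t*",
        nm, seq_len(n_fill), chrom1
      ))
    }
    path <- file.path(dir, paste0(nm, ".sam"))
    writeLines(c(hdr, body), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
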