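# Independent oracles and small fixture builders. Everything here deliberately
# avoids the package's implementation paths: plain string scanning, naive
# translation, direct combinatorics, and generic numerical optimization.

# reverse complement without Biostrings
rc_chr <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# ---- maximum-entropy oracle: dual optimization over feature weights --------
# Solves the same constrained problem as fit_maxent (identical smoothed
# targets) by minimizing the dual objective log Z(lambda) - lambda . t with
# BFGS; independent of the iterative-scaling code path.
oracle_maxent <- function(train, constraint_sets, pseudocount = 0.5) {
  k <- nchar(train[1])
  kmers <- kmer_space(k)
  km <- matrix(unlist(strsplit(kmers, "", fixed = TRUE)), ncol = k, byrow = TRUE)
  trm <- matrix(unlist(strsplit(train, "", fixed = TRUE)), ncol = k, byrow = TRUE)
  n <- length(train)
  max_m <- max(vapply(constraint_sets, function(S) 4^length(S), numeric(1)))
  alpha_total <- pseudocount * max_m

  feats <- list()
  targets <- numeric(0)
  for (S in constraint_sets) {
    cfgs <- kmer_space(length(S))
    key <- apply(km[, S, drop = FALSE], 1, paste, collapse = "")
    tkey <- apply(trm[, S, drop = FALSE], 1, paste, collapse = "")
    cnt <- as.numeric(table(factor(tkey, levels = cfgs)))
    tgt <- (cnt + alpha_total / length(cfgs)) / (n + alpha_total)
    for (ci in seq_along(cfgs)) {
      feats[[length(feats) + 1]] <- as.numeric(key == cfgs[ci])
      targets <- c(targets, tgt[ci])
    }
  }
  FM <- do.call(cbind, feats)

  dual <- function(lambda) {
    eta <- as.vector(FM %*% lambda)
    mx <- max(eta)
    log(sum(exp(eta - mx))) + mx - sum(lambda * targets)
  }
  grad <- function(lambda) {
    eta <- as.vector(FM %*% lambda)
    p <- exp(eta - max(eta))
    p <- p / sum(p)
    as.vector(crossprod(FM, p)) - targets
  }
  fit <- stats::optim(rep(0, ncol(FM)), dual, grad, method = "BFGS",
    control = list(maxit = 2000, reltol = 1e-14)
  )
  eta <- as.vector(FM %*% fit$par)
  p <- exp(eta - max(eta))
  stats::setNames(p / sum(p), kmers)
}

kl_div <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

# ---- brute-force catalog scan ----------------------------------------------
# Regex GT scan + naive translation, working directly from the annotation
# tibbles and plain character chromosomes.
brute_catalog <- function(genome, annotation, model, threshold = 0,
                          max_extension = 1000, min_residual = 20) {
  chrs <- stats::setNames(as.character(genome), names(genome))
  score_of <- function(s) log2(model$prob[s] / model$background[s])
  stops <- c("TAA", "TAG", "TGA")

  donor_keys <- paste(annotation$donors$chrom, annotation$donors$strand,
    annotation$donors$pos,
    sep = ":"
  )

  rows <- list()
  for (tx in annotation$transcripts$transcript_id) {
    ex <- annotation$exons[annotation$exons$transcript_id == tx, ]
    ex <- ex[order(ex$exon_rank), ]
    cd <- annotation$cds[annotation$cds$transcript_id == tx, ]
    cd <- cd[order(cd$exon_rank), ]
    strand <- ex$strand[1]
    chrom <- ex$chrom[1]
    cseq <- chrs[[chrom]]

    piece <- function(s, e) {
      p <- substr(cseq, s + 1, e)
      if (strand == "-") rc_chr(p) else p
    }
    cds_seq <- paste(vapply(seq_len(nrow(cd)), function(i) {
      piece(cd$start[i], cd$end[i])
    }, ""), collapse = "")
    cum <- cumsum(cd$end - cd$start)
    total_cds <- cum[length(cum)]

    for (i in seq_len(nrow(cd) - 1)) {
      # only adjacent CDS exons whose CDS reaches the junction
      upx <- ex[ex$exon_rank == cd$exon_rank[i], ]
      dnx <- ex[ex$exon_rank == cd$exon_rank[i] + 1, ]
      if (nrow(dnx) == 0 || cd$exon_rank[i + 1] != cd$exon_rank[i] + 1) next
      ok <- if (strand == "-") {
        cd$start[i] == upx$start && cd$end[i + 1] == dnx$end
      } else {
        cd$end[i] == upx$end && cd$start[i + 1] == dnx$start
      }
      if (!ok) next
      if (cum[i] < 3) next
      istart <- if (strand == "-") dnx$end else upx$end
      iend <- if (strand == "-") upx$start else dnx$start
      iseq <- piece(istart, iend)
      len <- nchar(iseq)
      f <- cum[i] %% 3
      last3 <- substr(cds_seq, cum[i] - 2, cum[i])

      hits <- gregexpr("(?=GT)", iseq, perl = TRUE)[[1]]
      if (hits[1] == -1) next
      for (o in as.integer(hits) - 1L) {
        if (o < 1 || o > max_extension || (len - o) < min_residual) next
        dpos <- if (strand == "-") iend - 1 - o else istart + o
        if (paste(chrom, strand, dpos, sep = ":") %in% donor_keys) next
        ctx <- paste0(last3, iseq)
        s9 <- substr(ctx, o + 1, o + 9)
        if (grepl("[^ACGT]", s9)) next
        sc <- unname(score_of(s9))
        if (!(sc >= threshold)) next
        extension <- substr(iseq, 1, o)
        prefix <- if (f > 0) substr(last3, 3 - f + 1, 3) else ""
        full <- paste0(prefix, extension)
        ncod <- nchar(full) %/% 3
        codons <- if (ncod > 0) {
          substring(full, seq(1, 3 * ncod - 2, 3), seq(3, 3 * ncod, 3))
        } else {
          character(0)
        }
        has_stop <- any(codons %in% stops)
        cls <- if (has_stop) "LSS" else if (o %% 3 == 0) "adSS_3n" else "adSS_fs"
        gt <- if (strand == "-") iend - o - 2 else istart + o
        parent <- if (strand == "-") iend - 1 else istart
        rows[[length(rows) + 1]] <- data.frame(
          site_key = paste(chrom, strand, gt, parent, sep = ":"),
          site_class = cls, extension_length = o, residual_intron = len - o,
          score = sc, has_inframe_stop = has_stop, cds_length = total_cds,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(
      site_key = character(), site_class = character(),
      extension_length = integer(), residual_intron = integer(),
      score = numeric(), has_inframe_stop = logical()
    ))
  }
  # dedup: longest CDS wins
  out <- out[order(out$site_key, -out$cds_length), ]
  out <- out[!duplicated(out$site_key), ]
  out[order(out$site_key), c(
    "site_key", "site_class", "extension_length",
    "residual_intron", "score", "has_inframe_stop"
  )]
}

# ---- exhaustive one-sided Fisher tail --------------------------------------
# Direct hypergeometric enumeration with lchoose; no phyper.
enum_fisher_tail <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- a:min(m, k)
  xs <- xs[k - xs <= n & k - xs >= 0]
  if (length(xs) == 0) return(0)
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# ---- small hand-built single-gene fixture ----------------------------------
# Two-exon plus-strand gene around a caller-supplied intron sequence; exons
# are GT-free with controlled tails so every candidate comes from the intron.
toy_single_gene <- function(intron, exon1_tail = "CAG", frame_pad = 0) {
  stopifnot(frame_pad %in% 0:2)
  fill <- function(n) paste(rep(c("A", "C"), length.out = n), collapse = "")
  e1_len <- 60 + frame_pad
  exon1 <- paste0("ATG", fill(e1_len - 6), exon1_tail)
  exon2 <- paste0(fill(57), "TAA")
  chrom_seq <- paste0(fill(50), exon1, intron, exon2, fill(50))
  e1s <- 50L
  e1e <- e1s + nchar(exon1)
  i_s <- e1e
  i_e <- i_s + nchar(intron)
  e2s <- i_e
  e2e <- e2s + 60L
  exons <- tibble::tibble(
    transcript_id = "t1", gene_id = "g1", chrom = "chrT", strand = "+",
    start = c(e1s, e2s), end = c(e1e, e2e), exon_rank = 1:2
  )
  sites <- latsplice:::.splice_sites(exons)
  ann <- latsplice:::new_genome_annotation(
    transcripts = tibble::tibble(
      transcript_id = "t1", gene_id = "g1", chrom = "chrT", strand = "+",
      cds_length = nchar(exon1) + 60L
    ),
    exons = exons, cds = exons,
    donors = sites$donors, acceptors = sites$acceptors
  )
  list(
    genome = Biostrings::DNAStringSet(c(chrT = chrom_seq)),
    annotation = ann, intron_start = i_s, intron_end = i_e,
    frame_offset = (nchar(exon1)) %% 3
  )
}

# reverse-complement a reference: flip genome and annotation strands
flip_reference <- function(genome, annotation) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  fx <- function(df) {
    ns <- lens[df$chrom] - df$end
    ne <- lens[df$chrom] - df$start
    df$start <- as.integer(ns)
    df$end <- as.integer(ne)
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  ex <- fx(annotation$exons)
  cds <- fx(annotation$cds)
  tx <- annotation$transcripts
  tx$strand <- ifelse(tx$strand == "+", "-", "+")
  sites <- latsplice:::.splice_sites(ex)
  ann <- latsplice:::new_genome_annotation(
    transcripts = tx,
    exons = ex, cds = cds, donors = sites$donors, acceptors = sites$acceptors
  )
  list(genome = Biostrings::reverseComplement(genome), annotation = ann)
}

# compare catalog against brute-force scan, site for site
expect_catalog_matches_brute <- function(catalog, brute) {
  got <- as.data.frame(catalog)[order(catalog$site_key), c(
    "site_key", "site_class", "extension_length", "residual_intron",
    "score", "has_inframe_stop"
  )]
  rownames(got) <- NULL
  rownames(brute) <- NULL
  expect_equal(nrow(got), nrow(brute))
  expect_identical(got$site_key, brute$site_key)
  expect_identical(got$site_class, brute$site_class)
  expect_equal(got$extension_length, brute$extension_length)
  expect_equal(got$residual_intron, brute$residual_intron)
  expect_equal(got$score, brute$score, tolerance = 1e-12)
  expect_identical(got$has_inframe_stop, brute$has_inframe_stop)
}

# scaled-down simulation parameters for small-genome tests
small_params <- function(n_genes = 3L, ...) {
  sim_params(
    n_genes = n_genes,
    n_planted = c(LSS = 2L, adSS_3n = 1L, adSS_fs = 1L),
    n_activated = c(LSS = 2L, adSS_3n = 0L, adSS_fs = 0L),
    ...
  )
}
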