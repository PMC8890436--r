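test_that("in-frame STOP detection continues the upstream exon frame", {
  # planted STOP at the start of the extension
  expect_true(has_inframe_stop("TAAGGG", 0))
  # 9 nt without STOP: none found
  expect_false(has_inframe_stop("GGGGGGGGG", 0))
  # spanning codon: upstream contributes 2 bases -> "GTA ..." no, "ATA"+"A.."
  # upstream "CA" + extension "ATTT": codons CAA, TTT -> no STOP
  expect_false(has_inframe_stop("ATTT", 2, upstream = "CCA"))
  # upstream "TA" + extension "AGGG": spanning codon TAA is a STOP
  expect_true(has_inframe_stop("AGGG", 2, upstream = "CTA"))
  # a STOP whose codon would run past the extension end does not count
  expect_false(has_inframe_stop("GGGTA", 0))
  # ambiguous bases flag NA
  expect_true(is.na(has_inframe_stop("TANGG", 0)))

  expect_identical(
    classify_extension(c("TAAGGG", "GGGGGGGGG", "GGGGGGGGGC", "TANGG"), 0),
    c("LSS", "adSS_3n", "adSS_fs", "rejected")
  )
})

test_that("GTF coordinates convert to 0-based half-open and donors union across files", {
  gtf1 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\ttoy\texon\t100\t200\t.\t+\t.\t",
      'gene_id "g1"; transcript_id "t1";'
    ),
    paste0("chr1\ttoy\tCDS\t100\t200\t.\t+\t0\t",
      'gene_id "g1"; transcript_id "t1";'
    ),
    paste0("chr1\ttoy\texon\t301\t400\t.\t+\t.\t",
      'gene_id "g1"; transcript_id "t1";'
    ),
    paste0("chr1\ttoy\tCDS\t301\t400\t.\t+\t0\t",
      'gene_id "g1"; transcript_id "t1";'
    ),
    # single-exon coding transcript: excluded from candidate generation
    paste0("chr1\ttoy\texon\t500\t600\t.\t+\t.\t",
      'gene_id "g2"; transcript_id "t2";'
    ),
    paste0("chr1\ttoy\tCDS\t500\t600\t.\t+\t0\t",
      'gene_id "g2"; transcript_id "t2";'
    )
  ), gtf1)
  gtf2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\ttoy\texon\t100\t250\t.\t+\t.\t",
      'gene_id "g1"; transcript_id "t1b";'
    ),
    paste0("chr1\ttoy\texon\t351\t400\t.\t+\t.\t",
      'gene_id "g1"; transcript_id "t1b";'
    )
  ), gtf2)

  ann <- read_annotation(c(gtf1, gtf2))
  expect_identical(ann$transcripts$transcript_id, "t1") # t2 single-exon, t1b non-coding
  e1 <- ann$exons[ann$exons$exon_rank == 1, ]
  expect_equal(e1$start, 99L) # GTF 100 -> internal 99
  expect_equal(e1$end, 200L)
  # donor set is the union across files: t1 donor at 200, t1b donor at 350
  expect_setequal(ann$donors$pos, c(200L, 250L))

  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\ttoy\texon\t100", "ok"), bad)
  expect_error(read_annotation(bad), "line 1")
})

test_that("candidate enumeration applies window, residual and known-donor filters", {
  fill <- function(n) paste(rep(c("A", "C"), length.out = n), collapse = "")
  # GT offsets: 0 (annotated donor), 5, 30; intron end has 25 nt after last GT
  intron <- paste0(
    "GTAAGC", fill(24), # offset 0 donor, no other GT until...
    "GT", fill(10), # offset 30... recompute below
    fill(13), "AG"
  )
  # place GTs explicitly: offset 0 donor; offset 6; offset 40; one 10 nt from end
  ch <- strsplit(paste0("GTAAGC", fill(100)), "", fixed = TRUE)[[1]]
  ch[7:8] <- c("G", "T") # offset 6
  ch[41:42] <- c("G", "T") # offset 40
  ch[89:90] <- c("G", "T") # offset 88: residual = 106 - 88 = 18 < 20 -> rejected
  intron <- paste(ch, collapse = "")
  toy <- toy_single_gene(intron)
  cand <- enumerate_candidates(toy$annotation, toy$genome)
  expect_setequal(cand$extension_length, c(6L, 40L))
  # annotated donor at offset 0 self-excluded
  expect_false(any(cand$extension_length == 0))
  # residual intron lengths consistent
  expect_equal(cand$residual_intron, nchar(intron) - cand$extension_length)

  # extension window: GT beyond max_extension rejected
  cand2 <- enumerate_candidates(toy$annotation, toy$genome, max_extension = 10)
  expect_setequal(cand2$extension_length, 6L)
})

test_that("toy genome catalog matches the brute-force scan including classes", {
  ref <- generate_reference(sim_params(background_gt = FALSE), seed = 42)
  catalog <- build_catalog(ref$annotation, ref$genome, ref$model)
  brute <- brute_catalog(ref$genome, ref$annotation, ref$model)
  expect_catalog_matches_brute(catalog, brute)

  # planted truth recovered exactly, classes as planted
  truth <- ref$truth
  got <- catalog[match(truth$site_key, catalog$site_key), ]
  expect_false(anyNA(got$site_key))
  expect_identical(got$site_class, truth$site_class)
  expect_equal(nrow(catalog), nrow(truth)) # controlled background: no extras
})

test_that("every catalog site is in exactly one class and passes the threshold", {
  ref <- generate_reference(sim_params(), seed = 13)
  catalog <- build_catalog(ref$annotation, ref$genome, ref$model)
  expect_true(all(catalog$site_class %in% c("LSS", "adSS_3n", "adSS_fs")))
  expect_identical(
    catalog$site_class == "LSS", catalog$has_inframe_stop,
    info = "LSS if and only if the extension has an in-frame STOP"
  )
  expect_true(all(passes_threshold(catalog$score, 0)))
  expect_true(all(catalog$extension_length >= 1 & catalog$extension_length <= 1000))
  expect_true(all(catalog$residual_intron >= 20))
  expect_false(any(duplicated(catalog$site_key)))
})

test_that("raising the threshold never adds sites, +Inf empties the catalog", {
  ref <- generate_reference(sim_params(), seed = 21)
  c0 <- build_catalog(ref$annotation, ref$genome, ref$model, threshold = 0)
  c3 <- build_catalog(ref$annotation, ref$genome, ref$model, threshold = 3)
  c9 <- build_catalog(ref$annotation, ref$genome, ref$model, threshold = 9)
  expect_true(all(c3$site_key %in% c0$site_key))
  expect_true(all(c9$site_key %in% c3$site_key))
  cinf <- build_catalog(ref$annotation, ref$genome, ref$model,
    threshold = score_threshold(Inf)
  )
  expect_equal(nrow(cinf), 0)
})

test_that("catalog is strand-symmetric under reverse complement", {
  ref <- generate_reference(small_params(n_genes = 4L), seed = 31)
  cat1 <- build_catalog(ref$annotation, ref$genome, ref$model)
  flipped <- flip_reference(ref$genome, ref$annotation)
  cat2 <- build_catalog(flipped$annotation, flipped$genome, ref$model)
  key <- function(x) {
    as.data.frame(x)[order(x$chrom, x$gene_id, x$extension_length, x$score), c(
      "chrom", "gene_id", "extension_length", "residual_intron",
      "site_class", "has_inframe_stop", "score"
    )]
  }
  a <- key(cat1)
  b <- key(cat2)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("chromosomes missing from the genome are reported by name", {
  ref <- generate_reference(small_params(n_genes = 2L), seed = 3)
  genome <- ref$genome[1]
  expect_error(
    build_catalog(ref$annotation, genome, ref$model),
    "chrS02"
  )
})

test_that("catalog summaries report strongest/closest sites and score differences", {
  ref <- generate_reference(sim_params(), seed = 17)
  catalog <- build_catalog(ref$annotation, ref$genome, ref$model)
  s <- summarize_catalog(catalog, site_class = "LSS")
  lss <- catalog[catalog$site_class == "LSS", ]

  one <- s$per_5ss[1, ]
  sites_here <- lss[lss$parent5ss == one$parent5ss & lss$chrom == one$chrom, ]
  expect_equal(one$strongest_score, max(sites_here$score))
  expect_equal(one$closest_extension, min(sites_here$extension_length))
  expect_equal(one$score_diff, one$donor_score - one$strongest_score)
  expect_identical(one$stronger_exists, one$strongest_score > one$donor_score)

  # per-gene counts are plain totals
  expect_equal(sum(s$per_gene$n_sites), nrow(lss))
  # a 5'SS with a single LSS has closest == strongest extension
  singles <- s$per_5ss[s$per_5ss$n_sites == 1, ]
  if (nrow(singles) > 0) {
    expect_equal(singles$closest_extension, singles$strongest_extension)
  }
})

test_that("catalog TSV round-trips through write and read", {
  ref <- generate_reference(small_params(n_genes = 3L), seed = 5)
  catalog <- build_catalog(ref$annotation, ref$genome, ref$model)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(catalog, path)
  back <- read_catalog(path)
  expect_equal(as.data.frame(back), as.data.frame(catalog)[, names(back)],
    tolerance = 1e-12
  )
})
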