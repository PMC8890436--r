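test_that("generation is fully deterministic given (params, seed)", {
  p <- small_params(n_genes = 3L)
  r1 <- generate_reference(p, seed = 99)
  r2 <- generate_reference(p, seed = 99)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_equal(r1$truth, r2$truth)
  e1 <- simulate_experiment(r1, seed = 99)
  e2 <- simulate_experiment(r2, seed = 99)
  for (nm in names(e1$junctions)) {
    expect_equal(tibble::as_tibble(e1$junctions[[nm]]), tibble::as_tibble(e2$junctions[[nm]]))
    expect_equal(e1$coverage[[nm]], e2$coverage[[nm]])
  }
  # a different seed changes the genome
  r3 <- generate_reference(p, seed = 100)
  expect_false(identical(as.character(r1$genome), as.character(r3$genome)))
})

test_that("infeasible simulation parameter sets are rejected before generation", {
  expect_error(sim_params(n_activated = c(LSS = 99L, adSS_3n = 0L, adSS_fs = 0L)),
    "n_activated"
  )
  expect_error(
    sim_params(extension_range = c(31L, 32L),
      n_planted = c(LSS = 0L, adSS_3n = 1L, adSS_fs = 0L),
      n_activated = c(LSS = 0L, adSS_3n = 0L, adSS_fs = 0L)
    ),
    "divisible by 3"
  )
  expect_error(
    sim_params(n_genes = 1L, exons_per_gene = c(2L, 2L),
      n_planted = c(LSS = 5L, adSS_3n = 0L, adSS_fs = 0L),
      n_activated = c(LSS = 0L, adSS_3n = 0L, adSS_fs = 0L)
    ),
    "infeasible"
  )
  expect_error(sim_params(effect_fold = 0.5), "effect_fold")
  expect_error(sim_params(baseline_usage = 1.2), "baseline_usage")
})

test_that("planted sites carry their class, score window and activation truth", {
  p <- sim_params(background_gt = FALSE)
  ref <- generate_reference(p, seed = 23)
  expect_equal(
    as.integer(table(ref$truth$site_class)[c("LSS", "adSS_3n", "adSS_fs")]),
    as.integer(p$n_planted[c("LSS", "adSS_3n", "adSS_fs")])
  )
  expect_equal(sum(ref$truth$activated), sum(p$n_activated))
  expect_true(all(ref$truth$score >= p$planted_score_range[1] &
    ref$truth$score <= p$planted_score_range[2]))
  expect_true(all(ref$truth$extension_length %% 3 == 0 |
    ref$truth$site_class != "adSS_3n"))
  expect_true(all(ref$truth$extension_length %% 3 != 0 |
    ref$truth$site_class != "adSS_fs"))
  # activated sites are a subset of planted sites
  expect_true(all(ref$truth$site_key[ref$truth$activated] %in% ref$truth$site_key))
})

test_that("written reference files reload into an equivalent annotation", {
  ref <- generate_reference(small_params(n_genes = 2L), seed = 44)
  d <- withr::local_tempdir()
  write_reference(ref, d)
  genome <- read_genome(file.path(d, "ref.fa"))
  expect_identical(as.character(genome), as.character(ref$genome))
  ann <- read_annotation(file.path(d, "genes.gtf"), genome = genome)
  srt <- function(df, keys) {
    out <- as.data.frame(df)[do.call(order, as.data.frame(df)[keys]), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  expect_equal(
    srt(ann$exons, c("transcript_id", "exon_rank"))[, c("start", "end", "strand")],
    srt(ref$annotation$exons, c("transcript_id", "exon_rank"))[, c("start", "end", "strand")]
  )
  expect_equal(
    srt(ann$donors, c("chrom", "pos")),
    srt(ref$annotation$donors, c("chrom", "pos"))
  )
  # the catalog built from reloaded files equals the in-memory catalog
  c1 <- build_catalog(ref$annotation, ref$genome, ref$model)
  c2 <- build_catalog(ann, genome, ref$model)
  expect_equal(as.data.frame(c1), as.data.frame(c2), tolerance = 1e-12)
})

test_that("simulated usage matches its analytic expectation", {
  # aggregate planted latent usage over several seeds: expected case usage =
  # baseline * effect_fold at activated sites, baseline elsewhere
  p <- sim_params(n_planted = c(LSS = 8L, adSS_3n = 2L, adSS_fs = 2L),
    n_activated = c(LSS = 8L, adSS_3n = 0L, adSS_fs = 0L),
    n_genes = 8L, exons_per_gene = c(3L, 5L)
  )
  usage_case <- c()
  usage_ctrl <- c()
  for (s in 1:4) {
    ref <- generate_reference(p, seed = s)
    exp <- simulate_experiment(ref, seed = s)
    act <- ref$truth[ref$truth$activated, ]
    for (nm in c("case_rep1", "case_rep2")) {
      j <- tibble::as_tibble(exp$junctions[[nm]])
      lat <- j$count[match(paste(act$chrom, act$gap_start, act$gap_end), paste(j$chrom, j$donor, j$acceptor))]
      can <- j$count[match(paste(act$chrom, act$intron_start, act$intron_end), paste(j$chrom, j$donor, j$acceptor))]
      usage_case <- c(usage_case, ifelse(is.na(lat), 0, lat) / can)
    }
    for (nm in c("control_rep1", "control_rep2")) {
      j <- tibble::as_tibble(exp$junctions[[nm]])
      lat <- j$count[match(paste(act$chrom, act$gap_start, act$gap_end), paste(j$chrom, j$donor, j$acceptor))]
      can <- j$count[match(paste(act$chrom, act$intron_start, act$intron_end), paste(j$chrom, j$donor, j$acceptor))]
      usage_ctrl <- c(usage_ctrl, ifelse(is.na(lat), 0, lat) / can)
    }
  }
  # 64 case and 64 control observations; jitter sd 0.1 => mean within ~15%
  expect_equal(mean(usage_case, na.rm = TRUE),
    p$baseline_usage * p$effect_fold,
    tolerance = 0.15
  )
  expect_equal(mean(usage_ctrl, na.rm = TRUE), p$baseline_usage, tolerance = 0.2)
})

test_that("emitted SAM files reproduce the generating junction tables exactly", {
  ref <- generate_reference(small_params(n_genes = 3L), seed = 55)
  exp <- simulate_experiment(ref, seed = 55)
  d <- withr::local_tempdir()
  sams <- emit_sam(exp, ref, d)
  for (nm in names(exp$junctions)) {
    orig <- exp$junctions[[nm]]
    back <- extract_junctions_from_sam(
      file.path(d, paste0(nm, ".sam")), ref$annotation,
      sample_id = attr(orig, "sample_id"),
      condition = attr(orig, "condition"),
      replicate = attr(orig, "replicate")
    )
    expect_equal(tibble::as_tibble(back), tibble::as_tibble(orig))
    expect_equal(attr(back, "total_mapped"), attr(orig, "total_mapped"))
  }
})

test_that("a null experiment with effect fold 1 yields almost no calls", {
  p <- sim_params(effect_fold = 1, n_activated = c(LSS = 0L, adSS_3n = 0L, adSS_fs = 0L))
  ref <- generate_reference(p, seed = 66)
  ctl <- build_catalog(ref$annotation, ref$genome, ref$model)
  exp <- simulate_experiment(ref, seed = 66)
  calls <- call_activated(ctl, exp$junctions, exp$coverage)
  sw <- label_switch(ctl, exp$junctions, exp$coverage)
  expect_lte(sum(calls$called), 2)
  expect_lte(sum(sw$called), 2)
})
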