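# rep vectors: c(lss_case, canonical_case, lss_control, canonical_control)

test_that("initial criteria need one strong replicate and any increase in the other", {
  # 4-read/1.5-fold in rep1 plus 1-read/any-increase in rep2
  expect_true(check_initial_criteria(c(6, 100, 2, 100), c(1, 50, 0, 50)))
  # no replicate reaches 4 reads
  expect_false(check_initial_criteria(c(3, 100, 1, 100), c(3, 100, 1, 100)))
  # either replicate may play the primary role
  expect_true(check_initial_criteria(c(1, 50, 0, 50), c(6, 100, 2, 100)))
  # fold 1.33 in rep1 cannot be primary; rep2 strong primary + rep1 secondary
  expect_true(check_initial_criteria(c(8, 100, 6, 100), c(10, 100, 2, 100)))
  # neither assignment works: rep1 fails fold, rep2 fails the 4-read requirement
  expect_false(check_initial_criteria(c(8, 100, 6, 100), c(3, 100, 1, 100)))
  # secondary replicate must show an increase (fold > 1), not equality
  expect_false(check_initial_criteria(c(6, 100, 2, 100), c(1, 100, 1, 100)))
  # undefined usage (canonical 0) fails regardless of reads
  expect_false(check_initial_criteria(c(6, 100, 2, 0), c(6, 100, 2, 100)))
  # control usage 0 with case reads satisfies any fold requirement
  expect_true(check_initial_criteria(c(6, 100, 0, 100), c(1, 100, 0, 100)))
})

test_that("stringent criteria impose 4 reads and 1.5-fold on both replicates", {
  expect_true(check_stringent_criteria(c(6, 100, 2, 100), c(6, 100, 2, 100)))
  # one replicate at fold 1.4 fails
  expect_false(check_stringent_criteria(c(6, 100, 2, 100), c(14, 100, 10, 100)))
  expect_false(check_stringent_criteria(c(3, 100, 0, 100), c(6, 100, 2, 100)))
})

test_that("stringent implies initial over random replicate data", {
  set.seed(99)
  for (i in 1:300) {
    r1 <- c(rpois(1, 5), rpois(1, 120) + 1, rpois(1, 3), rpois(1, 120) + 1)
    r2 <- c(rpois(1, 5), rpois(1, 120) + 1, rpois(1, 3), rpois(1, 120) + 1)
    if (check_stringent_criteria(r1, r2)) {
      expect_true(check_initial_criteria(r1, r2))
    }
  }
})

test_that("profile support requires presence throughout and consistent excess", {
  cfg <- activation_config()
  up10 <- rep(10, 50)
  zero <- rep(0, 50)
  expect_true(check_profile_support(list(up10, up10), list(zero, zero)))
  # an internal uncovered base violates presence at fraction 1.0
  gap <- up10
  gap[25] <- 0
  expect_false(check_profile_support(list(gap, up10), list(zero, zero)))
  # identical case and control profiles show no excess
  expect_false(check_profile_support(list(up10, up10), list(up10, up10)))
  # normalisation can flip the comparison
  expect_true(check_profile_support(list(up10, up10), list(up10, up10),
    case_norm = c(10, 10), control_norm = c(100, 100)
  ))
  expect_error(
    check_profile_support(list(rep(1, 10)), list(rep(1, 9))),
    "length mismatch"
  )
})

test_that("call_activated validates the 2+2 design and respects undefined usage", {
  ref <- generate_reference(small_params(n_genes = 3L), seed = 12)
  ctl <- build_catalog(ref$annotation, ref$genome, ref$model)
  exp <- simulate_experiment(ref, seed = 12)
  expect_error(
    call_activated(ctl, exp$junctions[1:3]),
    "2 case and 2 control"
  )

  calls <- call_activated(ctl, exp$junctions, exp$coverage)
  expect_s3_class(calls, "activation_calls")
  expect_equal(nrow(calls), nrow(ctl))
  # undefined rows are never called
  expect_false(any(calls$called & !calls$defined))
  # stringent calls are a subset of initial calls
  expect_false(any(calls$passes_stringent & !calls$passes_initial))
})

test_that("all-equal counts across samples produce zero calls", {
  ref <- generate_reference(small_params(n_genes = 3L, background_gt = FALSE), seed = 14)
  ctl <- build_catalog(ref$annotation, ref$genome, ref$model)
  introns <- dplyr::distinct(ctl[, c("chrom", "intron_start", "intron_end", "strand")])
  flat <- function(sample_id, condition, replicate) {
    tbl <- dplyr::bind_rows(
      tibble::tibble(
        chrom = introns$chrom, donor = introns$intron_start,
        acceptor = introns$intron_end, strand = introns$strand, count = 100L
      ),
      tibble::tibble(
        chrom = ctl$chrom, donor = ctl$gap_start, acceptor = ctl$gap_end,
        strand = ctl$strand, count = 5L
      )
    )
    latsplice:::new_junction_counts(tbl, sample_id, condition, replicate, 1e5)
  }
  jx <- list(
    flat("c1", "case", 1L), flat("c2", "case", 2L),
    flat("k1", "control", 1L), flat("k2", "control", 2L)
  )
  calls <- call_activated(ctl, jx)
  expect_equal(sum(calls$called), 0)

  # label switching on symmetric data is symmetric, and an involution
  sw <- label_switch(ctl, jx)
  expect_equal(sum(sw$called), sum(calls$called))
  sw2 <- label_switch(ctl, lapply(jx, function(j) {
    attr(j, "condition") <- ifelse(attr(j, "condition") == "case", "control", "case")
    j
  }))
  expect_equal(tibble::as_tibble(sw2)[setdiff(names(sw2), "label_switched")],
    tibble::as_tibble(calls)[setdiff(names(calls), "label_switched")]
  )
  expect_true(all(sw$label_switched))
})

test_that("ranking uses per-replicate Fisher tests combined by Fisher's method", {
  ref <- generate_reference(sim_params(), seed = 16)
  ctl <- build_catalog(ref$annotation, ref$genome, ref$model)
  exp <- simulate_experiment(ref, seed = 16)
  calls <- call_activated(ctl, exp$junctions, exp$coverage)
  ranked <- rank_calls(calls)
  expect_true(all(diff(ranked$combined_p) >= 0))
  expect_equal(ranked$rank, seq_len(nrow(ranked)))

  # per-replicate p matches a direct one-sided Fisher's exact test
  row <- calls[which(calls$defined & calls$lss_case1 > 0)[1], ]
  ft <- stats::fisher.test(
    matrix(c(row$lss_case1, row$lss_control1,
      row$canonical_case1, row$canonical_control1
    ), nrow = 2),
    alternative = "greater"
  )
  expect_equal(row$p1, ft$p.value, tolerance = 1e-9)
  # combined p is Fisher's method over the two replicates
  expect_equal(
    row$combined_p,
    fishers_method(c(row$p1, row$p2)),
    tolerance = 1e-12
  )
  # geometric-mean fold (finite replicate folds)
  fin <- calls$defined & is.finite(calls$fold1) & is.finite(calls$fold2)
  expect_equal(calls$fold_geomean[fin], sqrt(calls$fold1 * calls$fold2)[fin])
  expect_equal(sqrt(2 * 8), 4) # the geometric-mean convention itself
})

test_that("the comparison set needs canonical support of 10 in both controls", {
  ref <- generate_reference(small_params(n_genes = 3L, background_gt = FALSE), seed = 18)
  ctl <- build_catalog(ref$annotation, ref$genome, ref$model)
  lss <- ctl[ctl$site_class == "LSS", ]
  mk <- function(counts, sample_id) {
    tbl <- tibble::tibble(
      chrom = lss$chrom, donor = lss$intron_start, acceptor = lss$intron_end,
      strand = lss$strand, count = counts
    )
    latsplice:::new_junction_counts(tbl, sample_id, "control", 1L, 1e5)
  }
  n <- nrow(lss)
  c1 <- rep(10L, n)
  c2 <- rep(10L, n)
  c2[1] <- 9L # first 5'SS fails the both-controls requirement
  cs <- build_comparison_set(ctl, list(mk(c1, "k1"), mk(c2, "k2")))
  expect_false(lss$parent5ss[1] %in% cs$parent5ss)
  kept <- lss[lss$parent5ss %in% cs$parent5ss, ]
  # each retained 5'SS is paired with its highest-scoring LSS
  for (p in unique(kept$parent5ss)) {
    expect_equal(
      cs$best_score[cs$parent5ss == p],
      max(kept$score[kept$parent5ss == p])
    )
  }
})

test_that("composite profiles give order-statistic CIs and 100 standardized bins", {
  calls <- tibble::tibble(site_key = c("s1", "s2", "s3"), called = TRUE)
  mkprof <- function(key, fold, len = 40) {
    tibble::tibble(
      site_key = key,
      sample_id = c("c1", "c2", "k1", "k2"),
      condition = c("case", "case", "control", "control"),
      replicate = c(1L, 2L, 1L, 2L),
      norm = 1,
      depth = list(rep(fold, len), rep(fold, len), rep(1, len), rep(1, len))
    )
  }
  profiles <- dplyr::bind_rows(mkprof("s1", 1), mkprof("s2", 2), mkprof("s3", 9))
  cp <- composite_profile(calls, profiles)
  # folds {1, 2, 9} at every position: median 2, order-statistic CI [1, 9]
  expect_true(all(cp$composite$median_fold == 2))
  expect_true(all(cp$composite$ci_lo == 1))
  expect_true(all(cp$composite$ci_hi == 9))
  expect_true(all(cp$composite$n_sites == 3))
  # standardized representation has exactly 100 bins per site
  expect_equal(nrow(cp$standardized), 300)
  expect_true(all(table(cp$standardized$site_key) == 100))
  expect_true(all(cp$standardized$mean_fold[cp$standardized$site_key == "s2"] == 2))
  # CI band contains the median pointwise
  expect_true(all(cp$composite$ci_lo <= cp$composite$median_fold &
    cp$composite$median_fold <= cp$composite$ci_hi))

  # constant fold across sites: zero-width CI
  profiles2 <- dplyr::bind_rows(mkprof("s1", 2), mkprof("s2", 2), mkprof("s3", 2))
  cp2 <- composite_profile(calls, profiles2)
  expect_true(all(cp2$composite$ci_lo == 2 & cp2$composite$ci_hi == 2))

  # single site: the median is that site's profile, degenerate CI flagged
  expect_message(
    cp1 <- composite_profile(calls[1, ], mkprof("s1", 3)),
    "single activated site"
  )
  expect_true(all(cp1$composite$median_fold == 3))
})
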