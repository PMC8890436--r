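#' Activation-calling configuration
#'
#' Tunable criteria for calling a latent/alternative donor site activated in a
#' 2-case vs 2-control replicate design:
#'
#' * initial criteria: at least one case replicate with `min_reads_primary`
#'   (default 4) reads supporting the latent junction and a usage fold
#'   increase of at least `min_fold` (default 1.5) over its paired control,
#'   while the other replicate shows `min_reads_secondary` (default 1) reads
#'   and any usage increase;
#' * stringent criteria: the 4-read / 1.5-fold requirement imposed on both
#'   replicates;
#' * profile criteria: coverage present throughout the exon extension in both
#'   case replicates (fraction of positions >= `profile_presence_fraction`)
#'   and normalised case coverage exceeding control at
#'   `profile_higher_fraction` of positions.
#'
#' A control usage of 0 with positive case usage counts as satisfying any fold
#' condition (the fold is `+Inf`); usage undefined in any sample (canonical
#' support 0) fails the site.
#'
#' @param min_reads_primary Minimum latent-junction reads in the primary
#'   replicate (default 4).
#' @param min_fold Minimum usage fold increase in the primary replicate
#'   (default 1.5; must be > 1).
#' @param min_reads_secondary Minimum latent-junction reads in the secondary
#'   replicate (default 1).
#' @param stringent Call on stringent rather than initial criteria.
#' @param profile_presence_fraction Fraction of extension positions that must
#'   be covered (depth >= 1) in each case replicate (default 1.0).
#' @param profile_higher_fraction Fraction of positions where normalised case
#'   coverage must exceed control (default 0.95).
#' @param min_canonical_for_comparison Minimum canonical split-read support in
#'   both control samples for the background comparison set (default 10).
#' @param depth_floor Read-equivalent floor applied to control depth when
#'   computing per-position coverage folds (default 1).
#' @return An `activation_config` list.
#' @export
activation_config <- function(min_reads_primary = 4L, min_fold = 1.5,
                              min_reads_secondary = 1L, stringent = FALSE,
                              profile_presence_fraction = 1.0,
                              profile_higher_fraction = 0.95,
                              min_canonical_for_comparison = 10L,
                              depth_floor = 1) {
  if (min_fold <= 1) abort("min_fold must be > 1")
  if (profile_presence_fraction <= 0 || profile_presence_fraction > 1 ||
    profile_higher_fraction <= 0 || profile_higher_fraction > 1) {
    abort("profile fractions must lie in (0, 1]")
  }
  structure(
    list(
      min_reads_primary = min_reads_primary, min_fold = min_fold,
      min_reads_secondary = min_reads_secondary, stringent = isTRUE(stringent),
      profile_presence_fraction = profile_presence_fraction,
      profile_higher_fraction = profile_higher_fraction,
      min_canonical_for_comparison = min_canonical_for_comparison,
      depth_floor = depth_floor
    ),
    class = "activation_config"
  )
}

# usage fold for case vs control; control usage 0 with case usage > 0 is +Inf
# ("any increase" is satisfiable from zero); both zero is fold 1 (no increase).
.usage_fold <- function(u_case, u_ctrl) {
  dplyr::case_when(
    u_ctrl > 0 ~ u_case / u_ctrl,
    u_case > 0 ~ Inf,
    TRUE ~ 1
  )
}

# vectorised criteria engine; all arguments are parallel vectors
.initial_pass <- function(lss1, fold1, lss2, fold2, defined, cfg) {
  primary1 <- lss1 >= cfg$min_reads_primary & fold1 >= cfg$min_fold
  primary2 <- lss2 >= cfg$min_reads_primary & fold2 >= cfg$min_fold
  secondary1 <- lss1 >= cfg$min_reads_secondary & fold1 > 1
  secondary2 <- lss2 >= cfg$min_reads_secondary & fold2 > 1
  defined & ((primary1 & secondary2) | (primary2 & secondary1))
}

.stringent_pass <- function(lss1, fold1, lss2, fold2, defined, cfg) {
  defined &
    (lss1 >= cfg$min_reads_primary & fold1 >= cfg$min_fold) &
    (lss2 >= cfg$min_reads_primary & fold2 >= cfg$min_fold)
}

.rep_stats <- function(rep) {
  if (length(rep) != 4 || any(rep < 0)) {
    abort("each replicate must be c(lss_case, canonical_case, lss_control, canonical_control)")
  }
  u <- usage_ratio(rep[c(1, 3)], rep[c(2, 4)])
  list(
    lss_case = rep[1],
    defined = all(u$defined),
    fold = .usage_fold(u$usage[1], u$usage[2])
  )
}

#' Initial and stringent activation criteria for one site
#'
#' `check_initial_criteria()` is true when one replicate meets the strong
#' requirement (>= 4 latent reads, usage fold >= 1.5) and the other shows any
#' increase with >= 1 latent read; either replicate may play the primary role.
#' `check_stringent_criteria()` imposes the strong requirement on both
#' replicates. Usage undefined in any of the four samples fails.
#'
#' @param rep1,rep2 Numeric vectors
#'   `c(lss_case, canonical_case, lss_control, canonical_control)` for
#'   replicate pairs 1 and 2.
#' @param config An [activation_config()].
#' @return Logical scalar.
#' @export
#' @examples
#' check_initial_criteria(c(6, 100, 2, 100), c(1, 50, 0, 50)) # TRUE
#' check_initial_criteria(c(3, 100, 1, 100), c(3, 100, 1, 100)) # FALSE
check_initial_criteria <- function(rep1, rep2, config = activation_config()) {
  r1 <- .rep_stats(rep1)
  r2 <- .rep_stats(rep2)
  .initial_pass(r1$lss_case, r1$fold, r2$lss_case, r2$fold,
    r1$defined & r2$defined, config
  )
}

#' @rdname check_initial_criteria
#' @export
check_stringent_criteria <- function(rep1, rep2, config = activation_config()) {
  r1 <- .rep_stats(rep1)
  r2 <- .rep_stats(rep2)
  .stringent_pass(r1$lss_case, r1$fold, r2$lss_case, r2$fold,
    r1$defined & r2$defined, config
  )
}

#' Exon-extension expression-profile check
#'
#' Verifies that, in both case replicates, coverage is present throughout the
#' exon extension (raw depth >= 1 at a fraction of positions of at least
#' `profile_presence_fraction`) and that the normalised case depth exceeds the
#' paired control's at `profile_higher_fraction` of positions. Profiles are
#' normalised by the per-sample annotated-5'SS split-read count.
#'
#' @param case_profiles,control_profiles Lists of per-base raw depth vectors
#'   (one per replicate, paired by position in the list).
#' @param case_norm,control_norm Per-replicate normalisation factors
#'   (annotated-donor split reads; floored at 1).
#' @param config An [activation_config()].
#' @return Logical scalar.
#' @export
check_profile_support <- function(case_profiles, control_profiles,
                                  case_norm = rep(1, length(case_profiles)),
                                  control_norm = rep(1, length(control_profiles)),
                                  config = activation_config()) {
  stopifnot(length(case_profiles) == length(control_profiles))
  for (i in seq_along(case_profiles)) {
    cp <- case_profiles[[i]]
    kp <- control_profiles[[i]]
    if (length(cp) != length(kp)) abort("profile length mismatch between case and control")
    present <- mean(cp >= 1) >= config$profile_presence_fraction
    higher <- mean(cp / pmax(case_norm[i], 1) > kp / pmax(control_norm[i], 1)) >=
      config$profile_higher_fraction
    if (!(present && higher)) return(FALSE)
  }
  TRUE
}

# arrange a list of junction_counts into 2 case + 2 control, paired by replicate
.split_conditions <- function(junctions, replicates_override = FALSE) {
  cond <- vapply(junctions, function(j) as.character(attr(j, "condition")), "")
  if (!replicates_override && (sum(cond == "case") != 2 || sum(cond == "control") != 2)) {
    abort("expected exactly 2 case and 2 control samples (set condition attributes, or replicates_override = TRUE)")
  }
  reorder <- function(idx) idx[order(vapply(junctions[idx], function(j) {
    r <- attr(j, "replicate")
    if (is.null(r) || is.na(r)) 0L else as.integer(r)
  }, integer(1)))]
  list(
    case = junctions[reorder(which(cond == "case"))],
    control = junctions[reorder(which(cond == "control"))]
  )
}

# latent + canonical junction support for every catalog site in one sample
.site_support <- function(catalog, jx) {
  j <- as_tibble(jx)
  lat <- catalog |>
    left_join(select(j, "chrom", "donor", "acceptor", lss = "count"),
      by = c("chrom", "gap_start" = "donor", "gap_end" = "acceptor")
    ) |>
    left_join(select(j, "chrom", "donor", "acceptor", canonical = "count"),
      by = c("chrom", "intron_start" = "donor", "intron_end" = "acceptor")
    )
  tibble(
    site_key = lat$site_key,
    lss = tidyr::replace_na(lat$lss, 0L),
    canonical = tidyr::replace_na(lat$canonical, 0L)
  )
}

#' Call activated sites
#'
#' The full activation pipeline over a catalog and a 2-case / 2-control
#' junction set: per-site usage criteria (initial and stringent), optional
#' exon-extension coverage-profile verification, per-replicate one-sided
#' Fisher's exact tests on the latent-vs-canonical read table, Fisher's-method
#' combination, and geometric-mean usage folds.
#'
#' Case replicate i is paired with control replicate i (by the `replicate`
#' attribute, falling back to list order). Sites with undefined usage
#' (canonical support 0 in any sample) are never called. The profile check is
#' evaluated only for sites passing the read criteria; when `coverage` is
#' `NULL` the profile criterion is recorded as `NA` and treated as passing.
#'
#' @param catalog An `lss_catalog`.
#' @param junctions List of 4 `junction_counts` with `condition` attributes.
#' @param coverage Optional named list of bedGraph tibbles aligned with
#'   `junctions` (same order) for the profile check.
#' @param config An [activation_config()].
#' @param replicates_override Allow designs other than 2+2 (criteria are then
#'   evaluated on the first two replicates of each condition).
#' @return A tibble of class `activation_calls`: one row per catalog site with
#'   per-replicate supports, folds, Fisher p-values, combined p, criteria
#'   flags and the final `called` decision.
#' @export
call_activated <- function(catalog, junctions, coverage = NULL,
                           config = activation_config(),
                           replicates_override = FALSE) {
  stopifnot(inherits(catalog, "lss_catalog"))
  grp <- .split_conditions(junctions, replicates_override)

  sup <- list(
    case1 = .site_support(catalog, grp$case[[1]]),
    case2 = .site_support(catalog, grp$case[[2]]),
    ctrl1 = .site_support(catalog, grp$control[[1]]),
    ctrl2 = .site_support(catalog, grp$control[[2]])
  )

  u <- function(s) ifelse(s$canonical > 0, s$lss / s$canonical, NA_real_)
  defined <- sup$case1$canonical > 0 & sup$ctrl1$canonical > 0 &
    sup$case2$canonical > 0 & sup$ctrl2$canonical > 0
  fold1 <- .usage_fold(u(sup$case1), u(sup$ctrl1))
  fold2 <- .usage_fold(u(sup$case2), u(sup$ctrl2))
  fold1[!defined] <- NA_real_
  fold2[!defined] <- NA_real_

  ok1 <- tidyr::replace_na(fold1, 0)
  ok2 <- tidyr::replace_na(fold2, 0)
  passes_initial <- .initial_pass(sup$case1$lss, ok1, sup$case2$lss, ok2, defined, config)
  passes_stringent <- .stringent_pass(sup$case1$lss, ok1, sup$case2$lss, ok2, defined, config)

  p1 <- fisher_one_sided(sup$case1$lss, sup$case1$canonical,
    sup$ctrl1$lss, sup$ctrl1$canonical
  )
  p2 <- fisher_one_sided(sup$case2$lss, sup$case2$canonical,
    sup$ctrl2$lss, sup$ctrl2$canonical
  )
  combined_p <- fishers_method_vec(p1, p2)

  fold_geomean <- dplyr::case_when(
    is.infinite(fold1) | is.infinite(fold2) ~ Inf,
    TRUE ~ sqrt(fold1 * fold2)
  )

  read_pass <- if (config$stringent) passes_stringent else passes_initial
  profile_ok <- rep(NA, nrow(catalog))
  if (!is.null(coverage) && any(read_pass)) {
    idx <- which(read_pass)
    all_jx <- c(grp$case, grp$control)
    names(all_jx) <- vapply(all_jx, function(j) as.character(attr(j, "sample_id")), "")
    cov_named <- coverage
    if (is.null(names(cov_named)) || !all(names(all_jx) %in% names(cov_named))) {
      # align coverage by original junction order
      ord <- match(names(all_jx), vapply(junctions, function(j) {
        as.character(attr(j, "sample_id"))
      }, ""))
      cov_named <- stats::setNames(coverage[ord], names(all_jx))
    }
    prof <- assemble_profiles(catalog[idx, , drop = FALSE], cov_named, all_jx)
    profile_ok[idx] <- vapply(catalog$site_key[idx], function(key) {
      pr <- filter(prof, .data$site_key == key)
      ca <- filter(pr, .data$condition == "case") |> arrange(.data$replicate)
      ct <- filter(pr, .data$condition == "control") |> arrange(.data$replicate)
      check_profile_support(ca$depth, ct$depth, ca$norm, ct$norm, config)
    }, logical(1))
  }

  calls <- catalog |>
    as_tibble() |>
    select("site_key", "site_class", "chrom", "strand", "gt_start", "parent5ss",
      "extension_length", "gene_id", "score"
    ) |>
    mutate(
      lss_case1 = sup$case1$lss, canonical_case1 = sup$case1$canonical,
      lss_control1 = sup$ctrl1$lss, canonical_control1 = sup$ctrl1$canonical,
      lss_case2 = sup$case2$lss, canonical_case2 = sup$case2$canonical,
      lss_control2 = sup$ctrl2$lss, canonical_control2 = sup$ctrl2$canonical,
      defined = defined, fold1 = fold1, fold2 = fold2,
      fold_geomean = fold_geomean,
      p1 = p1, p2 = p2, combined_p = combined_p,
      passes_initial = passes_initial, passes_stringent = passes_stringent,
      profile_ok = profile_ok,
      called = (if (config$stringent) passes_stringent else passes_initial) &
        (is.na(profile_ok) | profile_ok),
      label_switched = FALSE
    )
  structure(calls, config = config,
    class = c("activation_calls", class(calls))
  )
}

#' Label-switch negative control
#'
#' Re-runs the activation pipeline with case and control labels exchanged.
#' Stress introduced by the experimental procedure itself would activate
#' latent splicing in both directions, so calls under switched labels estimate
#' the background call rate against which the true-label excess is judged.
#'
#' @inheritParams call_activated
#' @return An `activation_calls` tibble with `label_switched = TRUE`.
#' @export
label_switch <- function(catalog, junctions, coverage = NULL,
                         config = activation_config(),
                         replicates_override = FALSE) {
  swapped <- lapply(junctions, function(j) {
    cond <- attr(j, "condition")
    attr(j, "condition") <- dplyr::case_when(
      cond == "case" ~ "control", cond == "control" ~ "case", TRUE ~ cond
    )
    j
  })
  calls <- call_activated(catalog, swapped, coverage, config, replicates_override)
  calls$label_switched <- TRUE
  calls
}

#' Rank activation calls
#'
#' Called sites ordered by Fisher's-method combined p-value (ascending) over
#' the two per-replicate one-sided Fisher's exact tests, with the
#' geometric-mean usage fold.
#'
#' @param calls An `activation_calls` tibble.
#' @return Tibble of called sites sorted by `combined_p`.
#' @export
rank_calls <- function(calls) {
  calls |>
    filter(.data$called) |>
    arrange(.data$combined_p) |>
    select("site_key", "site_class", "gene_id", "extension_length",
      "p1", "p2", "combined_p", "fold1", "fold2", "fold_geomean"
    ) |>
    mutate(rank = dplyr::row_number(), .before = 1)
}

#' Background comparison set of expressed 5'SSs
#'
#' Annotated donors whose canonical junction has split-read support of at
#' least `min_canonical` reads in both control samples, each paired with its
#' highest-scoring latent site. This is the background against which the
#' scores of activated sites are compared.
#'
#' @param catalog An `lss_catalog`.
#' @param control_junctions List of 2 control `junction_counts`.
#' @param min_canonical Minimum canonical support in both controls
#'   (default 10).
#' @param site_class Catalog class used for the strongest-site pairing
#'   (default `"LSS"`).
#' @return Tibble: one row per retained 5'SS with its strongest latent site.
#' @export
build_comparison_set <- function(catalog, control_junctions, min_canonical = 10L,
                                 site_class = "LSS") {
  stopifnot(length(control_junctions) == 2)
  sup1 <- .site_support(catalog, control_junctions[[1]])
  sup2 <- .site_support(catalog, control_junctions[[2]])
  sites <- catalog |>
    as_tibble() |>
    mutate(canon1 = sup1$canonical, canon2 = sup2$canonical) |>
    filter(.data$site_class == !!site_class,
      .data$canon1 >= min_canonical, .data$canon2 >= min_canonical
    )
  sites |>
    group_by(.data$chrom, .data$strand, .data$parent5ss) |>
    arrange(desc(.data$score), .by_group = TRUE) |>
    summarise(
      best_site_key = dplyr::first(.data$site_key),
      best_score = dplyr::first(.data$score),
      best_extension = dplyr::first(.data$extension_length),
      gene_id = dplyr::first(.data$gene_id),
      canonical_control1 = dplyr::first(.data$canon1),
      canonical_control2 = dplyr::first(.data$canon2),
      .groups = "drop"
    )
}

# order-statistic (binomial) bounds for a median 95% CI; falls back to the
# sample range when n is too small for exact 95% coverage
.median_ci_idx <- function(n, conf = 0.95) {
  alpha <- (1 - conf) / 2
  lo <- stats::qbinom(alpha, n, 0.5)
  lo <- max(1L, lo)
  hi <- min(n, n + 1L - lo)
  c(lo, hi)
}

#' Composite exon-extension coverage profile
#'
#' Aggregates per-site coverage fold differences (case over control,
#' normalised by annotated-donor split reads, averaged over replicate pairs)
#' across activated sites: the point-wise median fold at nucleotide
#' resolution with an order-statistic 95% confidence band for the median, and
#' a standardised representation averaging the fold within 100 equal-width
#' bins along each extension.
#'
#' Control depth is floored at `config$depth_floor` read-equivalents before
#' normalisation so the fold is defined at uncovered control positions.
#'
#' @param calls An `activation_calls` tibble (only rows with `called = TRUE`
#'   contribute).
#' @param profiles Profile tibble from [assemble_profiles()] covering the
#'   called sites.
#' @param config An [activation_config()].
#' @param n_bins Number of standardised bins (default 100).
#' @return List of class `composite_profile`: `composite` (tibble `position
#'   n_sites median_fold ci_lo ci_hi`), `standardized` (tibble `site_key bin
#'   mean_fold`), and `site_folds` (list of per-site fold vectors).
#' @export
composite_profile <- function(calls, profiles, config = activation_config(),
                              n_bins = 100L) {
  keys <- calls$site_key[calls$called]
  if (length(keys) == 0) abort("no called sites to aggregate")

  site_folds <- purrr::map(keys, function(key) {
    pr <- filter(profiles, .data$site_key == key)
    ca <- filter(pr, .data$condition == "case") |> arrange(.data$replicate)
    ct <- filter(pr, .data$condition == "control") |> arrange(.data$replicate)
    if (nrow(ca) == 0 || nrow(ca) != nrow(ct)) return(NULL)
    per_rep <- purrr::map2(seq_len(nrow(ca)), seq_len(nrow(ct)), function(i, j) {
      (ca$depth[[i]] / pmax(ca$norm[i], 1)) /
        (pmax(ct$depth[[j]], config$depth_floor) / pmax(ct$norm[j], 1))
    })
    Reduce(`+`, per_rep) / length(per_rep)
  })
  names(site_folds) <- keys
  site_folds <- purrr::compact(site_folds)
  if (length(site_folds) == 0) abort("no profiles available for the called sites")
  if (length(site_folds) == 1) {
    inform("single activated site: median profile is that site's profile and the CI is degenerate")
  }

  max_len <- max(lengths(site_folds))
  composite <- purrr::map(seq_len(max_len), function(pos) {
    vals <- sort(purrr::map_dbl(site_folds, function(v) {
      if (length(v) >= pos) v[pos] else NA_real_
    }) |> stats::na.omit())
    n <- length(vals)
    if (n == 0) return(NULL)
    ci <- .median_ci_idx(n)
    tibble(
      position = pos, n_sites = n, median_fold = stats::median(vals),
      ci_lo = vals[ci[1]], ci_hi = vals[ci[2]]
    )
  }) |> bind_rows()

  standardized <- purrr::imap(site_folds, function(v, key) {
    len <- length(v)
    bins <- purrr::map_dbl(seq_len(n_bins), function(b) {
      a <- floor((b - 1) * len / n_bins) + 1
      z <- ceiling(b * len / n_bins)
      mean(v[a:z])
    })
    tibble(site_key = key, bin = seq_len(n_bins), mean_fold = bins)
  }) |> bind_rows()

  structure(
    list(composite = composite, standardized = standardized, site_folds = site_folds),
    class = "composite_profile"
  )
}
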