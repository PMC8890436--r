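#' One-sided Fisher's exact test
#'
#' Exact hypergeometric upper-tail probability that the first row of a 2x2
#' table is at least as enriched in the first column as observed. For a table
#' `[[a, b], [c, d]]` the p-value is `P(X >= a)` where X is hypergeometric
#' with `a + b` first-row items, `c + d` second-row items and `a + c` draws.
#' Callers order rows so that "first row enriched in first column" is the
#' alternative of interest. Any zero margin gives p = 1.
#'
#' @param a Either a 2x2 integer matrix, or the top-left cell (vectorised;
#'   then `b`, `c`, `d` supply the remaining cells row-wise).
#' @param b,c,d Remaining cells when `a` is given cell-wise.
#' @return Numeric vector of one-sided p-values.
#' @export
#' @examples
#' fisher_one_sided(matrix(c(399, 50, 82, 50), 2)) # ~2.3e-11
#' fisher_one_sided(3, 1, 1, 3) # 17/70
fisher_one_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) && is.null(b)) {
    if (!all(dim(a) == c(2, 2))) abort("table must be 2x2")
    b <- a[1, 2]
    c <- a[2, 1]
    d <- a[2, 2]
    a <- a[1, 1]
  }
  if (any(c(a, b, c, d) < 0)) abort("table entries must be nonnegative")
  # upper tail P(X >= a), inclusive
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

# vectorised two-p-value Fisher combination used by the activation caller
fishers_method_vec <- function(p1, p2) {
  p1 <- pmax(p1, .Machine$double.xmin)
  p2 <- pmax(p2, .Machine$double.xmin)
  stats::pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

#' Fisher's method for combining p-values
#'
#' Combines k independent p-values via `X2 = -2 * sum(log(p))`, referred to a
#' chi-square distribution with 2k degrees of freedom. A single p-value is
#' returned unchanged (up to floating point); zeros are clamped to the
#' smallest positive double with a warning.
#'
#' @param pvals Numeric vector of p-values in (0, 1]; must be non-empty.
#' @return Combined p-value.
#' @export
#' @examples
#' fishers_method(c(0.05, 0.05)) # ~0.0175
fishers_method <- function(pvals) {
  if (length(pvals) == 0) abort("pvals must be non-empty")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  if (any(pvals == 0)) {
    warn("p-value of 0 clamped to the smallest positive double")
    pvals <- pmax(pvals, .Machine$double.xmin)
  }
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals), lower.tail = FALSE)
}

#' Class-bias contingency test
#'
#' Compares activation-call counts between two site classes under true and
#' switched sample labels: the table `[[A_true, A_switched], [B_true,
#' B_switched]]` is tested one-sided for enrichment of class A under true
#' labels. A PTC-introducing class activated preferentially under true labels
#' (relative to the PTC-free adSS_3n baseline) indicates that the knockdown,
#' not experimental stress, drives the activation.
#'
#' @param calls_classA,calls_classA_switched Call counts for class A under
#'   true and switched labels.
#' @param calls_classB,calls_classB_switched Same for the baseline class B.
#' @return One-row tibble with the table cells, sample odds ratio and
#'   one-sided p-value.
#' @export
#' @examples
#' class_bias(399, 82, 50, 50) # LSS vs adSS_3n, p ~ 2.3e-11
class_bias <- function(calls_classA, calls_classA_switched,
                       calls_classB, calls_classB_switched) {
  a <- calls_classA
  b <- calls_classA_switched
  c <- calls_classB
  d <- calls_classB_switched
  tibble(
    a_true = a, a_switched = b, b_true = c, b_switched = d,
    odds_ratio = ifelse(b * c > 0, (a * d) / (b * c), Inf),
    p_value = fisher_one_sided(a, b, c, d)
  )
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param paths One or more GMT file paths.
#' @param collections Collection label per path (default: file base name).
#' @return Tibble with columns `collection`, `set`, `description`, `genes`
#'   (list column of character vectors).
#' @export
read_gmt <- function(paths, collections = NULL) {
  if (is.null(collections)) {
    collections <- sub("\\.gmt$", "", basename(paths), ignore.case = TRUE)
  }
  stopifnot(length(collections) == length(paths))
  purrr::map2(paths, collections, function(p, coll) {
    parts <- strsplit(readLines(p), "\t", fixed = TRUE)
    parts <- parts[lengths(parts) >= 3]
    tibble(
      collection = coll,
      set = vapply(parts, `[`, "", 1),
      description = vapply(parts, `[`, "", 2),
      genes = purrr::map(parts, function(x) unique(x[-(1:2)]))
    )
  }) |> bind_rows()
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail (inclusive) hypergeometric test of the overlap between a query
#' gene list and each gene set, within an explicit gene universe. Genes
#' outside the universe are ignored in both the query and the sets. Bonferroni
#' adjustment is reported at the collection level (times the number of sets in
#' that collection) and globally (times the total number of sets supplied).
#'
#' @param query_genes Character vector of query genes (e.g. genes with
#'   activated latent sites).
#' @param gene_sets Tibble from [read_gmt()] (columns `collection`, `set`,
#'   `genes`).
#' @param universe_genes Character vector defining the testable universe.
#' @return Tibble of class `enrichment_result`, one row per gene set, sorted
#'   by raw p-value.
#' @export
hypergeom_enrichment <- function(query_genes, gene_sets, universe_genes) {
  universe <- unique(universe_genes)
  query <- intersect(unique(query_genes), universe)
  if (length(universe) == 0) abort("universe is empty")
  if (length(query) == 0) abort("query has no genes in the universe")

  n_total_sets <- nrow(gene_sets)
  res <- gene_sets |>
    mutate(
      set_genes = purrr::map(.data$genes, intersect, universe),
      set_size = lengths(.data$set_genes),
      overlap = purrr::map_int(.data$set_genes, function(g) length(intersect(g, query))),
      universe_size = length(universe),
      query_size = length(query),
      p_value = stats::phyper(.data$overlap - 1, .data$set_size,
        .data$universe_size - .data$set_size, .data$query_size,
        lower.tail = FALSE
      )
    ) |>
    group_by(.data$collection) |>
    mutate(p_bonferroni_collection = pmin(1, .data$p_value * dplyr::n())) |>
    ungroup() |>
    mutate(p_bonferroni_global = pmin(1, .data$p_value * n_total_sets)) |>
    select("collection", "set", "overlap", "set_size", "universe_size",
      "query_size", "p_value", "p_bonferroni_collection", "p_bonferroni_global"
    ) |>
    arrange(.data$p_value)
  structure(res, class = c("enrichment_result", class(res)))
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties; the p-value uses the large-sample
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom (two-sided). Constant input yields an undefined correlation,
#' flagged with a warning.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("constant input: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) == 1) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
  tibble(rho = rho, p_value = p, n = n)
}
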