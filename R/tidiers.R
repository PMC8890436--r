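#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a donor model
#'
#' One row per k-mer with its model probability, background probability and
#' log2-odds score.
#'
#' @param x A `donor_model`.
#' @param ... Unused.
#' @return A tibble `kmer prob background score`.
#' @method tidy donor_model
#' @export
tidy.donor_model <- function(x, ...) {
  tibble(
    kmer = names(x$prob),
    prob = unname(x$prob),
    background = unname(x$background),
    score = log2(unname(x$prob) / unname(x$background))
  )
}

#' @rdname tidy.donor_model
#' @method glance donor_model
#' @export
glance.donor_model <- function(x, ...) {
  tibble(
    kind = x$kind, k = x$k, n_kmers = length(x$prob),
    n_constraint_sets = length(x$constraint_sets),
    n_train = x$fit$n_train %||% NA_integer_,
    iterations = x$fit$iterations %||% NA_integer_,
    max_discrepancy = x$fit$max_discrepancy %||% NA_real_,
    converged = x$fit$converged %||% NA
  )
}

#' Summaries of catalogs and activation calls
#'
#' `glance.lss_catalog()` gives one row of catalog-level counts;
#' `glance.activation_calls()` one row per site class with call counts under
#' the configured criteria.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @method glance lss_catalog
#' @export
glance.lss_catalog <- function(x, ...) {
  as_tibble(x) |>
    count(.data$site_class, name = "n_sites") |>
    tidyr::pivot_wider(names_from = "site_class", values_from = "n_sites",
      values_fill = 0L
    ) |>
    mutate(
      n_total = nrow(x),
      n_genes = dplyr::n_distinct(x$gene_id),
      n_5ss = dplyr::n_distinct(paste(x$chrom, x$strand, x$parent5ss))
    )
}

#' @rdname glance.lss_catalog
#' @method glance activation_calls
#' @export
glance.activation_calls <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$site_class) |>
    summarise(
      n_sites = dplyr::n(),
      n_defined = sum(.data$defined),
      n_initial = sum(.data$passes_initial),
      n_stringent = sum(.data$passes_stringent),
      n_called = sum(.data$called),
      label_switched = dplyr::first(.data$label_switched),
      .groups = "drop"
    )
}

#' Count activation calls per site class
#'
#' Convenience accessor used by the class-bias analysis: the number of called
#' sites of each class.
#'
#' @param calls An `activation_calls` tibble.
#' @return Named integer vector (one element per class present).
#' @export
count_calls <- function(calls) {
  tab <- calls |>
    filter(.data$called) |>
    count(.data$site_class)
  stats::setNames(as.integer(tab$n), tab$site_class)
}
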