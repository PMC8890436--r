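#' Splice-donor sequence models
#'
#' A donor-site model assigns a probability to every DNA k-mer spanning a
#' candidate 5' splice donor (by default a 9-mer: the last 3 exonic plus the
#' first 6 intronic nucleotides, with the invariant GT at intronic positions
#' 1-2). Scores are signed log2 odds against a background distribution, so an
#' uninformative site scores near 0 and implausible sites score far below 0.
#'
#' Two model kinds are supported: a position weight matrix ([fit_pwm()]), which
#' treats positions independently, and a maximum-entropy model
#' ([fit_maxent()]), which matches low-order marginal distributions of the
#' training data (by default all single positions and all adjacent position
#' pairs) while staying as close to the background as possible. The
#' maximum-entropy family captures the pairwise dependencies between donor
#' positions that a PWM ignores; with only first-order constraints it reduces
#' exactly to the PWM.
#'
#' @name donor_model
NULL

new_donor_model <- function(kind, k, prob, background, constraint_sets, pwm, fit) {
  structure(
    list(
      kind = kind, k = k, prob = prob, background = background,
      constraint_sets = constraint_sets, pwm = pwm, fit = fit
    ),
    class = "donor_model"
  )
}

#' @export
print.donor_model <- function(x, ...) {
  cat(sprintf(
    "<donor_model> kind=%s k=%d (%d k-mers), %d constraint sets\n",
    x$kind, x$k, length(x$prob), length(x$constraint_sets)
  ))
  if (!is.null(x$fit$iterations)) {
    cat(sprintf(
      "  fit: %d iterations, max marginal discrepancy %.3g (tol %.3g), converged: %s\n",
      x$fit$iterations, x$fit$max_discrepancy, x$fit$tol, x$fit$converged
    ))
  }
  invisible(x)
}

.uniform_background <- function(kmers) {
  stats::setNames(rep(1 / length(kmers), length(kmers)), kmers)
}

.check_background <- function(background, kmers) {
  if (is.null(background)) return(.uniform_background(kmers))
  if (is.null(names(background)) || !setequal(names(background), kmers)) {
    abort("background must be a probability vector named by the full k-mer space")
  }
  background <- background[kmers]
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    abort("background must be a probability distribution (sums to 1, nonnegative)")
  }
  background
}

#' Fit a position weight matrix donor model
#'
#' Per-position base frequencies with an additive pseudocount; the k-mer
#' probability is the product of its per-position frequencies.
#'
#' @param training_seqs Character vector of equal-length ACGT k-mers.
#' @param pseudocount Nonnegative count added to every base count at every
#'   position before normalising: frequency `(count + pc) / (n + 4 pc)`.
#' @param background Optional background distribution named by the full k-mer
#'   space; defaults to uniform.
#' @return A `donor_model` object.
#' @seealso [fit_maxent()], [score_kmer()]
#' @export
#' @examples
#' m <- fit_pwm(c("AC", "GT"))
#' score_kmer(m, "AT")
fit_pwm <- function(training_seqs, pseudocount = 0, background = NULL) {
  k <- validate_kmers(training_seqs)
  if (length(pseudocount) != 1 || pseudocount < 0) abort("pseudocount must be >= 0")
  n <- length(training_seqs)
  mat <- kmer_matrix(training_seqs, k)
  pwm <- vapply(seq_len(k), function(j) {
    cnt <- table(factor(mat[, j], levels = DNA_BASES))
    (as.numeric(cnt) + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4))
  dimnames(pwm) <- list(DNA_BASES, paste0("pos", seq_len(k)))

  kmers <- kmer_space(k)
  km <- kmer_matrix(kmers, k)
  logp <- numeric(length(kmers))
  for (j in seq_len(k)) {
    logp <- logp + log(pwm[, j])[match(km[, j], DNA_BASES)]
  }
  prob <- stats::setNames(exp(logp), kmers)
  prob <- prob / sum(prob) # exact renormalisation against rounding drift

  new_donor_model(
    kind = "pwm", k = k, prob = prob,
    background = .check_background(background, kmers),
    constraint_sets = as.list(seq_len(k)), pwm = pwm,
    fit = list(n_train = n, pseudocount = pseudocount)
  )
}

#' Default constraint sets for the maximum-entropy donor model
#'
#' All singleton positions plus all adjacent position pairs. Low-order
#' marginals carry most of the donor signal while keeping the model
#' identifiable from modest training sets.
#'
#' @param k Number of model positions.
#' @return List of integer vectors (position subsets).
#' @export
default_constraint_sets <- function(k) {
  c(as.list(seq_len(k)), lapply(seq_len(k - 1), function(i) c(i, i + 1L)))
}

# Consistent smoothed marginal targets: the pseudocount is applied as uniform
# smoothing of the joint, scaled so each cell of the *finest* constrained
# marginal table receives `pseudocount`; coarser marginals inherit it. This
# keeps all targets mutually consistent, so the constrained maximum-entropy
# problem has an exact solution.
.marginal_targets <- function(train_mat, constraint_sets, k, pseudocount) {
  n <- nrow(train_mat)
  max_m <- max(vapply(constraint_sets, function(S) 4^length(S), numeric(1)))
  alpha_total <- pseudocount * max_m # == alpha * 4^k with alpha per joint cell
  lapply(constraint_sets, function(S) {
    cfgs <- kmer_space(length(S))
    key <- do.call(paste0, as.data.frame(train_mat[, S, drop = FALSE]))
    cnt <- tabulate(match(key, cfgs), nbins = length(cfgs))
    smooth <- alpha_total / length(cfgs)
    (cnt + smooth) / (n + alpha_total)
  })
}

#' Fit a maximum-entropy donor model
#'
#' Finds the distribution over the full k-mer space that minimises
#' Kullback-Leibler divergence to the background (maximises entropy, for a
#' uniform background) subject to matching the training marginal distribution
#' on every constrained position subset. Fitting is by iterative proportional
#' scaling: each step rescales the current distribution to satisfy one
#' marginal constraint exactly, cycling until the largest marginal discrepancy
#' falls below `tol`.
#'
#' Zero training marginals are smoothed with a pseudocount applied
#' consistently across constraint sets: each cell of the finest constrained
#' marginal table receives `pseudocount`, and coarser marginals inherit the
#' equivalent joint smoothing, so all targets remain jointly satisfiable.
#'
#' @inheritParams fit_pwm
#' @param constraint_sets List of position subsets (integer vectors) whose
#'   marginals must match the training data. Default: all singletons and all
#'   adjacent pairs ([default_constraint_sets()]).
#' @param tol Convergence tolerance on the maximum absolute marginal
#'   discrepancy.
#' @param max_iter Maximum number of constraint-cycling sweeps; non-convergence
#'   raises a warning with the residual discrepancy, never fails silently.
#' @param pseudocount Smoothing count per finest-marginal cell (see Details).
#' @return A `donor_model` object.
#' @export
#' @examples
#' m <- fit_maxent(c("AC", "GT"), constraint_sets = list(1, 2))
#' unname(m$prob["AT"]) # independence model: 0.25
fit_maxent <- function(training_seqs, constraint_sets = NULL, tol = 1e-6,
                       max_iter = 10000, pseudocount = 0.5, background = NULL) {
  k <- validate_kmers(training_seqs)
  if (is.null(constraint_sets)) constraint_sets <- default_constraint_sets(k)
  if (length(constraint_sets) == 0) abort("constraint_sets must be non-empty")
  constraint_sets <- lapply(constraint_sets, function(S) {
    S <- as.integer(S)
    if (length(S) == 0 || anyDuplicated(S) || any(S < 1 | S > k)) {
      abort("each constraint set must be a non-empty subset of model positions")
    }
    sort(S)
  })

  kmers <- kmer_space(k)
  n_space <- length(kmers)
  km <- kmer_matrix(kmers, k)
  train_mat <- kmer_matrix(training_seqs, k)
  targets <- .marginal_targets(train_mat, constraint_sets, k, pseudocount)

  # per-set precomputation: permutation grouping the k-mer space into
  # equal-sized blocks, one per marginal configuration
  prep <- purrr::map2(constraint_sets, targets, function(S, tgt) {
    cfgs <- kmer_space(length(S))
    key <- do.call(paste0, as.data.frame(km[, S, drop = FALSE]))
    grp <- match(key, cfgs)
    list(ord = order(grp), m = length(cfgs), target = tgt)
  })

  background <- .check_background(background, kmers)
  p <- unname(background)
  it <- 0L
  disc <- Inf
  while (it < max_iter) {
    it <- it + 1L
    disc <- 0
    for (s in prep) {
      gsz <- n_space %/% s$m
      blocks <- p[s$ord]
      cur <- colSums(matrix(blocks, nrow = gsz))
      disc <- max(disc, max(abs(cur - s$target)))
      p[s$ord] <- blocks * rep(s$target / pmax(cur, .Machine$double.xmin), each = gsz)
    }
    p <- p / sum(p)
    if (disc < tol) break
  }
  converged <- disc < tol
  if (!converged) {
    warn(sprintf(
      "fit_maxent did not converge after %d sweeps (max marginal discrepancy %.3g > tol %.3g)",
      it, disc, tol
    ))
  }

  new_donor_model(
    kind = "maxent", k = k, prob = stats::setNames(p, kmers),
    background = background, constraint_sets = constraint_sets, pwm = NULL,
    fit = list(
      n_train = length(training_seqs), pseudocount = pseudocount,
      tol = tol, iterations = it, max_discrepancy = disc, converged = converged
    )
  )
}

#' Score k-mers under a donor model
#'
#' Log2 odds of the model probability over the background probability.
#' Sequences with zero model probability score `-Inf`, which compares below
#' any finite threshold.
#'
#' @param model A `donor_model`.
#' @param seq Character vector of ACGT sequences of the model's k.
#' @return Numeric vector of scores (log2 units), one per input sequence.
#' @export
#' @examples
#' m <- fit_pwm(c("AC", "GT"))
#' score_kmer(m, c("AC", "AT", "CC"))
score_kmer <- function(model, seq) {
  stopifnot(inherits(model, "donor_model"))
  if (any(nchar(seq) != model$k)) abort("sequence length does not match model k")
  if (any(grepl("[^ACGT]", seq))) abort("sequences must contain only ACGT")
  unname(log2(model$prob[seq] / model$background[seq]))
}

#' Donor score thresholds
#'
#' A threshold in log2-odds units together with its strictness. The default
#' catalog threshold of 0 is inclusive (score >= 0 passes): 0 excludes the
#' bulk of intronic GT dinucleotides while retaining nearly all annotated
#' donors, and strictness at the boundary is configurable because either
#' reading is defensible. A stringent alternative around 6.77 retains roughly
#' the strongest 80% of annotated donors.
#'
#' @param value Threshold score (log2 units; must be finite).
#' @param inclusive If `TRUE` (default), a score equal to the threshold passes.
#' @return A `score_threshold` object.
#' @export
#' @examples
#' passes_threshold(c(-1, 0, 3), score_threshold(0))
score_threshold <- function(value = 0, inclusive = TRUE) {
  if (!is.finite(value) && value != Inf) abort("threshold value must be finite (or +Inf)")
  structure(list(value = value, inclusive = isTRUE(inclusive)), class = "score_threshold")
}

#' @rdname score_threshold
#' @param score Numeric vector of scores.
#' @param threshold A `score_threshold` (a bare number is promoted to an
#'   inclusive threshold).
#' @export
passes_threshold <- function(score, threshold = score_threshold()) {
  if (is.numeric(threshold)) threshold <- score_threshold(threshold)
  if (threshold$inclusive) score >= threshold$value else score > threshold$value
}
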