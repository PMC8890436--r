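#' Read and write donor models
#'
#' Plain-text serialisation: a small `#`-prefixed header (kind, k, background
#' spec, constraint sets, fit metadata) followed by a `kmer<TAB>prob` table
#' (with a third `background` column when the background is not uniform).
#' Probabilities are written with 17 significant digits so the table
#' round-trips exactly.
#'
#' @param model A `donor_model`.
#' @param path File path.
#' @return `write_donor_model()` returns `path` invisibly; `read_donor_model()`
#'   returns a `donor_model`.
#' @export
write_donor_model <- function(model, path) {
  stopifnot(inherits(model, "donor_model"))
  uniform_bg <- length(unique(model$background)) == 1
  cs <- paste(vapply(model$constraint_sets, paste, "", collapse = ","), collapse = ";")
  fit <- model$fit
  hdr <- c(
    "# latsplice donor model",
    paste0("# kind: ", model$kind),
    paste0("# k: ", model$k),
    paste0("# background: ", if (uniform_bg) "uniform" else "table"),
    paste0("# constraint_sets: ", cs),
    paste0("# fit: ", paste(names(fit), vapply(fit, format, "", digits = 17),
      sep = "=", collapse = " "
    ))
  )
  num <- function(x) sprintf("%.17g", x)
  body <- if (uniform_bg) {
    paste(names(model$prob), num(model$prob), sep = "\t")
  } else {
    paste(names(model$prob), num(model$prob), num(model$background), sep = "\t")
  }
  writeLines(c(hdr, "kmer\tprob", body), path)
  invisible(path)
}

#' @rdname write_donor_model
#' @export
read_donor_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(name) {
    ln <- hdr[startsWith(hdr, paste0("# ", name, ":"))]
    if (length(ln) != 1) abort(paste0("model file missing header field: ", name))
    trimws(sub(paste0("^# ", name, ":"), "", ln))
  }
  kind <- get_field("kind")
  k <- as.integer(get_field("k"))
  bg_spec <- get_field("background")
  cs_txt <- get_field("constraint_sets")
  constraint_sets <- lapply(
    strsplit(cs_txt, ";", fixed = TRUE)[[1]],
    function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  )
  fit_txt <- strsplit(get_field("fit"), " ", fixed = TRUE)[[1]]
  fit_kv <- strsplit(fit_txt, "=", fixed = TRUE)
  fit <- lapply(fit_kv, function(kv) {
    v <- kv[2]
    if (v %in% c("TRUE", "FALSE")) as.logical(v) else as.numeric(v)
  })
  names(fit) <- vapply(fit_kv, `[`, "", 1)

  body <- lines[!startsWith(lines, "#")]
  body <- body[-1] # column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  kmers <- vapply(parts, `[`, "", 1)
  prob <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2)), kmers)
  background <- if (bg_spec == "uniform") {
    .uniform_background(kmers)
  } else {
    stats::setNames(as.numeric(vapply(parts, `[`, "", 3)), kmers)
  }
  pwm <- NULL
  if (kind == "pwm") {
    # reconstruct per-position frequencies from the joint (product model)
    km <- kmer_matrix(kmers, k)
    pwm <- vapply(seq_len(k), function(j) {
      vapply(split(prob, km[, j])[DNA_BASES], sum, numeric(1))
    }, numeric(4))
    dimnames(pwm) <- list(DNA_BASES, paste0("pos", seq_len(k)))
  }
  new_donor_model(kind, k, prob, background, constraint_sets, pwm, fit)
}
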