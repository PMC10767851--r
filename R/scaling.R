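#' Rank-based PHRED conversion tables
#'
#' Raw model scores have only relative meaning. To make scores comparable,
#' the raw scores of *all* possible SNVs of the reference are ranked and
#' each raw value `v` is assigned `scaled = -10 * log10(r)` where `r` is
#' its relative rank from the top, `r = #(raw >= v) / N`. A scaled score of
#' 20 marks the top 1% of all reference SNVs and 30 the top 0.1%. Tied raw
#' values share the rank of their worst member, so ties never inflate
#' scores.
#'
#' @param raw_all Numeric vector: raw scores of every possible SNV of the
#'   (mini-)reference.
#' @param max_breaks Optional cap on table size; when the number of unique
#'   raw values exceeds it, the table is compressed to `max_breaks`
#'   quantile breakpoints and the maximum absolute scaled-score error of
#'   the compression is reported in a message.
#' @return An object of class `conversion_table`: a tibble with strictly
#'   increasing `raw` breakpoints and non-decreasing `scaled` scores;
#'   attribute `n_total`.
#' @export
build_conversion_table <- function(raw_all, max_breaks = NULL) {
  if (length(raw_all) == 0) abort("raw_all is empty")
  if (anyNA(raw_all)) abort("raw_all contains NA")
  N <- length(raw_all)
  # for unique value v (ascending): #(>= v) = N - #(< v)
  uniq <- sort(unique(raw_all))
  n_lt <- c(0, cumsum(tabulate(match(raw_all, uniq), length(uniq))))[seq_along(uniq)]
  r <- (N - n_lt) / N
  scaled <- -10 * log10(r)
  out <- tibble(raw = uniq, scaled = scaled)
  if (!is.null(max_breaks) && nrow(out) > max_breaks) {
    keep <- unique(round(seq(1, nrow(out), length.out = max_breaks)))
    comp <- out[keep, , drop = FALSE]
    full_at <- scale_with(out$raw, comp)
    message(sprintf("conversion table compressed to %d breakpoints (max scaled-score error %.4f)",
                    nrow(comp), max(abs(full_at - out$scaled))))
    out <- comp
  }
  structure(out, class = c("conversion_table", class(tibble())), n_total = N)
}

#' PHRED-scale raw scores with a conversion table
#'
#' Raw values between breakpoints take the scaled score of the largest
#' breakpoint at or below them; values below every breakpoint map to 0 and
#' values above every breakpoint (e.g. indels scoring beyond any reference
#' SNV) are capped at the table maximum.
#'
#' @param raw Numeric vector of raw scores.
#' @param table A `conversion_table`.
#' @return Numeric vector of PHRED-scaled scores (>= 0).
#' @export
scale_scores <- function(raw, table) {
  scale_with(raw, table)
}

scale_with <- function(raw, table) {
  idx <- findInterval(raw, table$raw)
  out <- numeric(length(raw))
  out[idx > 0] <- table$scaled[idx[idx > 0]]
  out
}

#' Attach raw and PHRED-scaled scores to variants
#'
#' Pipe-friendly wrapper: scores a feature matrix with the trained model
#' and converts to the PHRED scale.
#'
#' @param features A `feature_matrix` built with `template = model`.
#' @param model A `deleteriousness_model`.
#' @param table A `conversion_table`.
#' @return The variant key columns of `features` with `raw` and `phred`
#'   columns appended.
#' @export
score_variants <- function(features, model, table) {
  raw <- raw_score(model, features)
  key <- intersect(c("contig", "pos", "ref", "alt", "vclass", "consequence"),
                   names(features))
  out <- as_tibble(features)[, key, drop = FALSE]
  out$raw <- raw
  out$phred <- scale_scores(raw, table)
  out
}

#' @export
print.conversion_table <- function(x, ...) {
  cat("<conversion_table> ", nrow(x), " breakpoints over ",
      attr(x, "n_total"), " reference SNVs\n", sep = "")
  NextMethod()
}

#' Serialize / read a conversion table as tsv.gz
#'
#' @param table A `conversion_table`.
#' @param path File path.
#' @return `path` invisibly; the reader returns the table.
#' @export
write_conversion_table <- function(table, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(c(paste0("#n_total=", attr(table, "n_total")), "raw\tscaled",
               sprintf("%.17g\t%.17g", table$raw, table$scaled)), con)
  invisible(path)
}

#' @rdname write_conversion_table
#' @export
read_conversion_table <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  n_total <- as.integer(sub("^#n_total=", "", lines[1]))
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  out <- tibble(raw = as.numeric(vapply(body, `[`, "", 1)),
                scaled = as.numeric(vapply(body, `[`, "", 2)))
  structure(out, class = c("conversion_table", class(tibble())), n_total = n_total)
}

#' @exportS3Method ggplot2::autoplot
autoplot.conversion_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$raw, y = .data$scaled)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "raw score (logit)", y = "PHRED-scaled score",
                  title = "Raw-to-scaled conversion table") +
    ggplot2::theme_minimal()
}
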