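#' Build a variant-by-annotation feature matrix
#'
#' Assembles the design matrix for the deleteriousness model: one row per
#' variant with (i) per-variant track values (value at the position for
#' SNVs, mean over the affected reference span for MNVs/indels), (ii)
#' missingness indicators `<name>_na` with missing cells imputed by the
#' training-set median, (iii) one-hot consequence indicators
#' `csq_<label>`, and (iv) crossed columns `<name>x<label>` equal to the
#' (imputed) feature value times the consequence indicator. Constant
#' columns are dropped with a message. Imputation medians and the realized
#' column set can be frozen via `template` so a scoring-time matrix matches
#' a training-time matrix exactly.
#'
#' @param variants A variant tibble carrying a `consequence` column (see
#'   [annotate_consequence()]).
#' @param tracks Named list of track tibbles (`contig`, `pos`, `value`).
#' @param extra Optional named list of per-variant numeric vectors
#'   (precomputed scores such as protein or regulatory model effects).
#' @param cross Character vector of continuous feature names to cross with
#'   consequence categories; defaults to all continuous features.
#' @param template A feature matrix (or trained model) whose imputation
#'   values and column set should be reused.
#' @return A tibble of class `feature_matrix`: the variant key columns plus
#'   numeric feature columns; attributes `feature_cols`, `impute`,
#'   `cross`, `consequences`.
#' @export
build_features <- function(variants, tracks = list(), extra = list(),
                           cross = NULL, template = NULL) {
  if (!"consequence" %in% names(variants)) {
    abort("variants must carry a consequence column; run annotate_consequence()")
  }
  n <- nrow(variants)
  cont <- list()
  for (nm in names(tracks)) {
    cont[[nm]] <- track_values_for_variants(tracks[[nm]], variants)
  }
  for (nm in names(extra)) {
    v <- extra[[nm]]
    if (length(v) != n) abort(paste0("extra feature '", nm, "' has wrong length"))
    cont[[nm]] <- as.numeric(v)
  }

  tmpl <- template_spec(template)
  if (is.null(cross)) {
    cross <- tmpl$cross %||% names(cont)
  }
  bad <- setdiff(cross, names(cont))
  if (length(bad)) abort(paste0("unknown feature(s) in crossing config: ",
                                paste(bad, collapse = ", ")))

  impute <- tmpl$impute %||% vapply(cont, function(v) {
    m <- median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, 0)

  out <- variants[, intersect(c("contig", "pos", "ref", "alt", "vclass", "consequence"),
                              names(variants)), drop = FALSE]
  for (nm in names(cont)) {
    miss <- is.na(cont[[nm]])
    filled <- cont[[nm]]
    filled[miss] <- impute[[nm]]
    out[[nm]] <- filled
    out[[paste0(nm, "_na")]] <- as.numeric(miss)
  }
  csq_levels <- tmpl$consequences %||% sort(unique(variants$consequence))
  for (lv in csq_levels) {
    out[[paste0("csq_", lv)]] <- as.numeric(variants$consequence == lv)
  }
  for (nm in cross) {
    for (lv in csq_levels) {
      out[[paste0(nm, "x", lv)]] <- out[[nm]] * out[[paste0("csq_", lv)]]
    }
  }

  key <- intersect(c("contig", "pos", "ref", "alt", "vclass", "consequence"), names(out))
  feats <- setdiff(names(out), key)
  if (is.null(tmpl$feature_cols)) {
    const <- feats[vapply(feats, function(f) length(unique(out[[f]])) < 2, TRUE)]
    if (length(const)) {
      message("dropping ", length(const), " constant feature column(s): ",
              paste(head(const, 8), collapse = ", "),
              if (length(const) > 8) ", ..." else "")
      out <- out[, setdiff(names(out), const), drop = FALSE]
      feats <- setdiff(feats, const)
    }
  } else {
    missing_cols <- setdiff(tmpl$feature_cols, feats)
    for (f in missing_cols) out[[f]] <- 0
    out <- out[, c(key, tmpl$feature_cols), drop = FALSE]
    feats <- tmpl$feature_cols
  }
  structure(out, class = c("feature_matrix", class(tibble())),
            feature_cols = feats, impute = impute, cross = cross,
            consequences = csq_levels)
}

template_spec <- function(template) {
  if (is.null(template)) return(list())
  if (inherits(template, "deleteriousness_model")) {
    return(list(feature_cols = template$feature_cols, impute = template$impute,
                cross = template$cross, consequences = template$consequences))
  }
  list(feature_cols = attr(template, "feature_cols"),
       impute = attr(template, "impute"), cross = attr(template, "cross"),
       consequences = attr(template, "consequences"))
}

#' Names of the model-facing columns of a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @return Character vector of feature column names, in frozen order.
#' @export
feature_columns <- function(fm) attr(fm, "feature_cols")

track_values_for_variants <- function(track, variants) {
  span_end <- variants$pos + nchar(variants$ref) - 1L
  single <- span_end == variants$pos
  out <- rep(NA_real_, nrow(variants))
  out[single] <- track_lookup(track, variants$contig[single], variants$pos[single])
  multi <- which(!single)
  if (length(multi)) {
    w <- span_end[multi] - variants$pos[multi] + 1L
    id <- rep(multi, w)
    pos <- unlist(mapply(seq.int, variants$pos[multi], span_end[multi],
                         SIMPLIFY = FALSE))
    v <- track_lookup(track, variants$contig[id], pos)
    mn <- tapply(v, id, function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    out[as.integer(names(mn))] <- as.numeric(mn)
  }
  out
}

#' Detect runs of contiguous constraint (RoCC)
#'
#' Maximal runs of contiguous positions whose track value exceeds
#' `threshold`, reported as 1-based inclusive intervals of length at least
#' `min_len`. The default threshold of 2.27 is the conventional per-base
#' constraint cutoff for phyloP-like scores.
#'
#' @param track A track tibble (`contig`, `pos`, `value`).
#' @param threshold Per-base value threshold (exclusive).
#' @param min_len Minimum run length in bp.
#' @return A tibble `contig`, `start`, `end`.
#' @export
detect_rocc <- function(track, threshold = 2.27, min_len = 1L) {
  track <- arrange(track, .data$contig, .data$pos)
  runs_where(track, track$value > threshold, min_len)
}

#' Detect ultraconserved elements (UCE)
#'
#' Maximal runs where the alignment depth reaches `min_species` (default
#' 235) and every aligning species carries the same base (a precomputed
#' per-base boolean "fixed" track).
#'
#' @param depth A track tibble of per-base species counts.
#' @param fixed A track tibble whose `value` is 1/0 (or logical) for
#'   cross-species fixation; must share support with `depth`.
#' @param min_species Minimum number of aligned species.
#' @return A tibble `contig`, `start`, `end`.
#' @export
detect_uce <- function(depth, fixed, min_species = 235L) {
  depth <- arrange(depth, .data$contig, .data$pos)
  fx <- track_lookup(fixed, depth$contig, depth$pos)
  ok <- depth$value >= min_species & !is.na(fx) & fx > 0
  runs_where(depth, ok, 1L)
}

# maximal runs of TRUE over contiguous positions, per contig
runs_where <- function(track, flag, min_len) {
  flag[is.na(flag)] <- FALSE
  if (nrow(track) == 0 || !any(flag)) {
    return(tibble(contig = character(), start = integer(), end = integer()))
  }
  newrun <- c(TRUE, diff(track$pos) != 1L |
                track$contig[-1] != track$contig[-nrow(track)])
  newrun <- newrun | c(TRUE, flag[-1] != flag[-length(flag)])
  run_id <- cumsum(newrun)
  keep <- flag
  tb <- tibble(contig = track$contig, pos = track$pos, run = run_id)[keep, ]
  out <- tb |>
    group_by(.data$run) |>
    summarise(contig = .data$contig[1], start = min(.data$pos),
              end = max(.data$pos), .groups = "drop") |>
    select("contig", "start", "end")
  out <- out[out$end - out$start + 1L >= min_len, , drop = FALSE]
  arrange(out, .data$contig, .data$start)
}

#' Serialize a feature matrix as tsv.gz
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  readr::write_tsv(as_tibble(fm), gzfile(path), progress = FALSE)
  invisible(path)
}
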