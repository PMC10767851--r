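#' Context-dependent mutation models
#'
#' A mutation model captures the mutational expectation observed in a
#' proxy-neutral variant set: trinucleotide-context substitution
#' probabilities (strand-collapsed to a pyrimidine center, with separate
#' rates for CpG dinucleotides), an empirical signed indel-length
#' distribution, per-context marginal mutability, and windowed local rate
#' multipliers. [simulate_variants()] draws a matched proxy-deleterious set
#' from such a model.
#'
#' @name mutation_model
NULL

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  out <- character(length(x))
  n <- nchar(x)
  for (len in unique(n)) {
    sel <- n == len
    comp <- chartr("ACGT", "TGCA", x[sel])
    # reverse by pasting fixed-width substrings back to front
    pieces <- lapply(len:1, function(i) substr(comp, i, i))
    out[sel] <- do.call(paste0, pieces)
  }
  out
}

# collapse a trinucleotide context (center = mutated base) to a pyrimidine
# center; returns list(context, alt) with alt complemented when flipped
collapse_context <- function(context, alt) {
  center <- substr(context, 2, 2)
  flip <- center %in% c("A", "G")
  context[flip] <- revcomp(context[flip])
  alt[flip] <- unname(COMP[alt[flip]])
  list(context = context, alt = alt)
}

all_contexts <- function() {
  g <- expand.grid(p1 = BASES, c = c("C", "T"), p3 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$c, g$p3)
}

is_cpg_context <- function(context) {
  # after pyrimidine collapse a CpG site is a C center followed by G
  substr(context, 2, 3) == "CG"
}

#' Estimate a mutation model from a proxy-neutral variant set
#'
#' Substitution probabilities are empirical frequencies per strand-collapsed
#' trinucleotide context; contexts whose (collapsed) center C is followed by
#' G form the CpG table and are estimated separately from all other
#' contexts. The indel-length distribution is the empirical signed-length
#' histogram (deletions negative). Local multipliers are per-window SNV
#' densities normalized to mean 1; windows without any neutral variant get
#' the smallest observed nonzero multiplier before normalization.
#' Contexts never observed mutated get a uniform 1/3 distribution over the
#' three alternative bases and the smallest observed context mutability.
#'
#' @param neutral A variant tibble of proxy-neutral variants.
#' @param reference Named character vector or `DNAStringSet`.
#' @param window_size Window width in bp for local rate multipliers.
#' @return An object of class `mutation_model`.
#' @export
estimate_mutation_model <- function(neutral, reference, window_size = 100000L) {
  reference <- as_reference(reference)
  snv <- neutral[neutral$vclass == "SNV", , drop = FALSE]
  if (nrow(snv) == 0) abort("neutral set contains no SNVs")

  ctx <- mapply(function(c, p) {
    if (p < 2 || p > contig_len(reference, c) - 1) NA_character_
    else ref_slice(reference, c, p - 1L, p + 1L)
  }, snv$contig, snv$pos)
  ok <- !is.na(ctx) & !grepl("[^ACGT]", ctx)
  cc <- collapse_context(ctx[ok], snv$alt[ok])

  counts <- count(tibble(context = cc$context, alt = cc$alt),
                  .data$context, .data$alt)
  grid <- tidyr::expand_grid(context = all_contexts(), alt = BASES)
  grid <- grid[substr(grid$context, 2, 2) != grid$alt, , drop = FALSE]
  rates <- left_join(grid, counts, by = c("context", "alt"))
  rates$n[is.na(rates$n)] <- 0L
  rates <- rates |>
    group_by(.data$context) |>
    mutate(total = sum(.data$n),
           prob = ifelse(.data$total == 0, 1 / 3, .data$n / pmax(.data$total, 1))) |>
    ungroup()

  # per-context marginal mutability: observed mutated fraction of context
  # occurrences in the reference (strand-collapsed)
  occ <- context_occurrences(reference)
  weight <- rates |>
    group_by(.data$context) |>
    summarise(total = .data$total[1], .groups = "drop") |>
    left_join(occ, by = "context") |>
    mutate(weight = .data$total / pmax(.data$occ, 1))
  nz <- weight$weight[weight$weight > 0]
  floorw <- if (length(nz)) min(nz) else 1
  weight$weight[weight$weight == 0] <- floorw

  indel <- neutral[neutral$vclass %in% c("INS", "DEL"), , drop = FALSE]
  if (nrow(indel) > 0) {
    len <- nchar(indel$alt) - nchar(indel$ref)
    indel_len_dist <- count(tibble(len = len), .data$len) |>
      mutate(prob = .data$n / sum(.data$n)) |>
      select("len", "prob")
  } else {
    indel_len_dist <- tibble(len = integer(), prob = double())
  }

  local_mult <- local_multipliers(snv, reference, window_size)
  comp <- base_composition(reference)

  structure(list(
    sub_rates = select(rates[!is_cpg_context(rates$context), ], "context", "alt", "prob"),
    cpg_rates = select(rates[is_cpg_context(rates$context), ], "context", "alt", "prob"),
    context_weight = select(weight, "context", "weight"),
    indel_len_dist = indel_len_dist,
    local_mult = local_mult,
    window_size = as.integer(window_size),
    composition = comp,
    n_snv = nrow(snv), n_indel = nrow(indel)
  ), class = "mutation_model")
}

context_occurrences <- function(reference) {
  tab <- Reduce(`+`, lapply(reference, function(seq) {
    Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), 3L)
  }))
  ctx3 <- names(tab)
  cc <- collapse_context(ctx3, rep("A", length(ctx3)))$context
  occ <- tapply(as.numeric(tab), cc, sum)
  tibble(context = names(occ), occ = as.numeric(occ))
}

base_composition <- function(reference) {
  tab <- Reduce(`+`, lapply(reference, function(seq) {
    Biostrings::letterFrequency(Biostrings::DNAString(seq), BASES)
  }))
  as.numeric(tab) / sum(tab)
}

local_multipliers <- function(snv, reference, window_size) {
  out <- imap(reference, function(seq, ctg) {
    n <- nchar(seq)
    nwin <- ceiling(n / window_size)
    win <- pmin(((snv$pos[snv$contig == ctg] - 1L) %/% window_size) + 1L, nwin)
    cnt <- tabulate(win, nbins = nwin)
    len <- c(rep(window_size, nwin - 1), n - (nwin - 1) * window_size)
    tibble(contig = ctg, window = seq_len(nwin), rate = cnt / len)
  })
  out <- bind_rows(out)
  nz <- out$rate[out$rate > 0]
  if (length(nz) == 0) abort("no SNVs in any window")
  out$rate[out$rate == 0] <- min(nz)
  out$mult <- out$rate / mean(out$rate)
  select(out, "contig", "window", "mult")
}

#' Simulate proxy-deleterious variants from a mutation model
#'
#' Sites are sampled with probability proportional to the local window
#' multiplier times the context's marginal mutability; alternative bases are
#' drawn from the context's substitution distribution (CpG contexts use the
#' CpG table). Indel lengths are drawn from the model's signed-length
#' distribution: deletions copy reference bases, insertions draw inserted
#' bases from the reference base composition. Output is normalized and
#' reproducible given `seed`.
#'
#' @param reference Named character vector or `DNAStringSet`.
#' @param model A `mutation_model`.
#' @param n_snv,n_indel Number of SNVs / indels to simulate.
#' @param seed Integer seed.
#' @return A variant tibble with `n_snv + n_indel` rows.
#' @export
simulate_variants <- function(reference, model, n_snv, n_indel = 0L, seed = 1L) {
  reference <- as_reference(reference)
  withr::local_seed(seed)
  rates <- bind_rows(model$sub_rates, model$cpg_rates)

  # per-position sampling weight = local multiplier x context mutability
  pos_tbl <- imap(reference, function(seq, ctg) {
    n <- nchar(seq)
    if (n < 3) return(NULL)
    ctx <- substring(seq, seq_len(n - 2L), seq_len(n - 2L) + 2L)
    pos <- 2:(n - 1L)
    keep <- !grepl("[^ACGT]", ctx)
    tibble(contig = ctg, pos = pos[keep], context = ctx[keep])
  })
  pos_tbl <- bind_rows(pos_tbl)
  cc <- collapse_context(pos_tbl$context, rep("A", nrow(pos_tbl)))
  pos_tbl$ccontext <- cc$context
  wmap <- setNames(model$context_weight$weight, model$context_weight$context)
  mult <- local_mult_at(model, pos_tbl$contig, pos_tbl$pos)
  w <- unname(wmap[pos_tbl$ccontext]) * mult

  out_snv <- NULL
  if (n_snv > 0) {
    idx <- sample.int(nrow(pos_tbl), n_snv, replace = TRUE, prob = w)
    sel <- pos_tbl[idx, , drop = FALSE]
    refb <- substr(sel$context, 2, 2)
    flip <- refb %in% c("A", "G")
    alt <- character(nrow(sel))
    for (ctx in unique(sel$ccontext)) {
      rows <- which(sel$ccontext == ctx)
      tab <- rates[rates$context == ctx, , drop = FALSE]
      alt[rows] <- sample(tab$alt, length(rows), replace = TRUE, prob = tab$prob)
    }
    alt[flip] <- unname(COMP[alt[flip]])
    out_snv <- variant_tbl(sel$contig, sel$pos, refb, alt)
  }

  out_ind <- NULL
  if (n_indel > 0) {
    if (nrow(model$indel_len_dist) == 0) {
      abort("model has no indel-length distribution; cannot simulate indels")
    }
    idx <- sample.int(nrow(pos_tbl), n_indel, replace = TRUE, prob = mult)
    lens <- sample(model$indel_len_dist$len, n_indel, replace = TRUE,
                   prob = model$indel_len_dist$prob)
    rows <- vector("list", n_indel)
    for (i in seq_len(n_indel)) {
      ctg <- pos_tbl$contig[idx[i]]; p <- pos_tbl$pos[idx[i]]; L <- lens[i]
      tries <- 0L
      while (L < 0 && p + abs(L) > contig_len(reference, ctg) && tries < 100L) {
        j <- sample.int(nrow(pos_tbl), 1L, prob = mult)
        ctg <- pos_tbl$contig[j]; p <- pos_tbl$pos[j]
        tries <- tries + 1L
      }
      if (L < 0 && p + abs(L) > contig_len(reference, ctg)) {
        abort("could not place deletion within contig after bounded retries")
      }
      if (L < 0) {
        rows[[i]] <- list(contig = ctg, pos = p,
                          ref = ref_slice(reference, ctg, p, p + abs(L)),
                          alt = ref_slice(reference, ctg, p, p))
      } else {
        ins <- paste(sample(BASES, L, replace = TRUE, prob = model$composition),
                     collapse = "")
        anchor <- ref_slice(reference, ctg, p, p)
        rows[[i]] <- list(contig = ctg, pos = p, ref = anchor,
                          alt = paste0(anchor, ins))
      }
    }
    tb <- bind_rows(rows)
    out_ind <- variant_tbl(tb$contig, tb$pos, tb$ref, tb$alt)
  }

  out <- bind_rows(out_snv, out_ind)
  normalize_variants(out, reference)
}

local_mult_at <- function(model, contig, pos) {
  win <- ((pos - 1L) %/% model$window_size) + 1L
  key <- paste(contig, win)
  lm <- model$local_mult
  m <- lm$mult[match(key, paste(lm$contig, lm$window))]
  m[is.na(m)] <- 1
  m
}

#' Tabulate the mutation spectrum of a variant set
#'
#' Diagnostic recount: strand-collapsed context-by-alternative SNV counts
#' and the signed indel-length histogram.
#'
#' @param variants A variant tibble.
#' @param reference Named character vector or `DNAStringSet`.
#' @return A list with tibbles `snv` (`context`, `alt`, `n`) and `indel`
#'   (`len`, `n`); counts sum to the SNV / indel input counts.
#' @export
spectrum_report <- function(variants, reference) {
  reference <- as_reference(reference)
  grid <- tidyr::expand_grid(context = all_contexts(), alt = BASES)
  grid <- grid[substr(grid$context, 2, 2) != grid$alt, , drop = FALSE]
  snv <- variants[variants$vclass == "SNV", , drop = FALSE]
  if (nrow(snv) > 0) {
    ctx <- mapply(function(c, p) {
      if (p < 2 || p > contig_len(reference, c) - 1) NA_character_
      else ref_slice(reference, c, p - 1L, p + 1L)
    }, snv$contig, snv$pos)
    ok <- !is.na(ctx) & !grepl("[^ACGT]", ctx)
    cc <- collapse_context(ctx[ok], snv$alt[ok])
    cnt <- count(tibble(context = cc$context, alt = cc$alt), .data$context, .data$alt)
    snv_tab <- left_join(grid, cnt, by = c("context", "alt"))
    snv_tab$n[is.na(snv_tab$n)] <- 0L
  } else {
    snv_tab <- mutate(grid, n = 0L)
  }
  ind <- variants[variants$vclass %in% c("INS", "DEL"), , drop = FALSE]
  indel_tab <- if (nrow(ind) > 0) {
    count(tibble(len = nchar(ind$alt) - nchar(ind$ref)), .data$len)
  } else tibble(len = integer(), n = integer())
  list(snv = snv_tab, indel = indel_tab)
}

#' Serialize / read a mutation model as JSON
#'
#' @param model A `mutation_model`.
#' @param path Output (input) path.
#' @return `path` invisibly; `read_mutation_model()` returns the model.
#' @export
write_mutation_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_mutation_model
#' @export
read_mutation_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("sub_rates", "cpg_rates", "context_weight", "indel_len_dist", "local_mult")) {
    x[[f]] <- as_tibble(lapply(x[[f]], unlist))
  }
  x$window_size <- as.integer(x$window_size)
  structure(x, class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("<mutation_model>\n")
  cat("  contexts:", nrow(x$sub_rates) / 3, "non-CpG +", nrow(x$cpg_rates) / 3, "CpG\n")
  cat("  indel lengths:", nrow(x$indel_len_dist), "| windows:", nrow(x$local_mult),
      "x", x$window_size, "bp\n")
  cat("  estimated from", x$n_snv, "SNVs and", x$n_indel, "indels\n")
  invisible(x)
}
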