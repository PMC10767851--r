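#' Synthetic mini-genome fixtures
#'
#' Generates a self-contained mini-genome world for exercising the whole
#' scoring pipeline offline: a random reference with planted open reading
#' frames, toy gene models, conservation and regulatory-activity tracks
#' elevated inside constrained/regulatory elements, a proxy-neutral variant
#' set produced by simulating variants from a known mutation model and
#' subjecting them to conservation-dependent purifying selection, an
#' MPRA-style readout table, and per-residue amino acid likelihood files.
#' Regeneration from the same configuration and seed is byte-identical.
#'
#' @name synthetic_fixtures
NULL

#' Fixture configuration
#'
#' Defaults define the standard study conditions of the mini-genome:
#' 2 contigs of 500 kb, 20 toy genes, constrained elements covering about
#' half of the genome (2 kb elements every 4 kb, plus coding sequence),
#' regulatory elements covering a quarter (1 kb every 4 kb), per-base
#' conservation `N(3, 0.7)` inside constrained regions and `N(0, 1.3)`
#' outside, 8000 neutral SNVs and 1000 neutral indels surviving selection,
#' and a rejection fraction of 0.99 at element-level conservation. The
#' selection rule is graded: a candidate with conservation `x` survives
#' with probability `exp(-s * max(x - thr, 0) - 0.5 * s * max(a - thr, 0))`
#' where `a` is regulatory activity, `thr = -1`, and `s` is set so that the
#' survival probability at conservation 3 (the element mean) equals
#' `1 - rejection_fraction`.
#'
#' @param contig_length,n_contigs Contig geometry.
#' @param n_genes Number of toy genes (split over contigs).
#' @param element_len,element_period Constrained-element tiling.
#' @param reg_len,reg_period,reg_offset Regulatory-element tiling.
#' @param cons_elem_mean,cons_elem_sd,cons_bg_sd Conservation track shape.
#' @param n_neutral_snv,n_neutral_indel Target neutral-set size.
#' @param rejection_fraction Rejection probability for a neutral candidate
#'   at element-level conservation.
#' @param selection_threshold Conservation below which selection is
#'   inactive.
#' @param activity_weight Relative selection weight of the activity track.
#' @param window_size Mutation-model window size in bp.
#' @param n_mpra_elements,mpra_element_len,mpra_variants_per_element
#'   MPRA-style readout table shape.
#' @return A named list of generation parameters.
#' @export
fixture_config <- function(contig_length = 500000L, n_contigs = 2L,
                           n_genes = 20L,
                           element_len = 2000L, element_period = 4000L,
                           reg_len = 1000L, reg_period = 4000L,
                           reg_offset = 2500L,
                           cons_elem_mean = 3, cons_elem_sd = 0.7,
                           cons_bg_sd = 1.3,
                           n_neutral_snv = 8000L, n_neutral_indel = 1000L,
                           rejection_fraction = 0.99,
                           selection_threshold = -1,
                           activity_weight = 0.5,
                           window_size = 100000L,
                           n_mpra_elements = 8L, mpra_element_len = 300L,
                           mpra_variants_per_element = 40L) {
  as.list(environment())
}

#' Generate the fixture bundle
#'
#' @param config A list from [fixture_config()].
#' @param seed Integer seed; the whole bundle is deterministic in it.
#' @param out_dir Optional directory; when given, all bundle components are
#'   written there (`ref.fa`, `genes.gff3`, `neutral.vcf.gz`,
#'   `conservation.bedGraph`, `activity.bedGraph`, `mpra.tsv`,
#'   `aalik_gene*<m>.tsv`, `manifest.json`).
#' @return A list with `reference`, `genes`, `conservation`, `activity`,
#'   `elements`, `regulatory`, `neutral`, `gen_model`, `mpra`, `aalik`,
#'   `manifest` (and `files` when `out_dir` is given).
#' @export
make_fixtures <- function(config = fixture_config(), seed = 7L, out_dir = NULL) {
  cfg <- utils::modifyList(fixture_config(), config)
  if (cfg$element_len > cfg$element_period || cfg$reg_len > cfg$reg_period) {
    abort("element length exceeds its period")
  }
  if (cfg$n_genes %% cfg$n_contigs != 0) {
    abort("n_genes must divide evenly over contigs")
  }
  gene_span <- 5100L
  per_ctg <- cfg$n_genes %/% cfg$n_contigs
  margin <- min(20000L, cfg$contig_length %/% 10L)
  gene_spacing <- (cfg$contig_length - 2L * margin) %/% max(per_ctg, 1L)
  if (gene_spacing < gene_span + 1000L) abort("contigs too short for the gene count")

  withr::local_seed(seed)
  ctgs <- paste0("ctg", seq_len(cfg$n_contigs))

  reference <- setNames(vapply(ctgs, function(.) {
    paste(sample(BASES, cfg$contig_length, replace = TRUE), collapse = "")
  }, ""), ctgs)

  genes <- plant_genes(cfg, ctgs, per_ctg, gene_spacing, margin)
  reference <- as_reference(plant_orfs(reference, genes))

  elements <- tile_elements(cfg, ctgs, cfg$element_len, cfg$element_period, 1L)
  regulatory <- tile_elements(cfg, ctgs, cfg$reg_len, cfg$reg_period,
                              cfg$reg_offset)
  cds <- genes[genes$type == "CDS", c("contig", "start", "end")]
  conserved <- bind_rows(elements, cds)

  conservation <- make_track(cfg, ctgs, conserved,
                             cfg$cons_elem_mean, cfg$cons_elem_sd, cfg$cons_bg_sd)
  activity <- make_track(cfg, ctgs, regulatory,
                         cfg$cons_elem_mean, cfg$cons_elem_sd, cfg$cons_bg_sd)

  gen_model <- generating_model(cfg, ctgs)
  neutral <- draw_neutral_set(reference, gen_model, conservation, activity,
                              cfg, seed)
  mpra <- make_mpra(cfg, reference, regulatory, activity, seed)
  aalik <- make_aalik(genes, reference, conservation, seed)

  manifest <- list(config = cfg, seed = seed,
                   package_version = as.character(utils::packageVersion("proxyscore")))
  bundle <- list(reference = reference, genes = genes,
                 conservation = conservation, activity = activity,
                 elements = elements, regulatory = regulatory,
                 neutral = neutral, gen_model = gen_model, mpra = mpra,
                 aalik = aalik, manifest = manifest)
  if (!is.null(out_dir)) {
    bundle$files <- write_bundle(bundle, out_dir)
  }
  bundle
}

plant_genes <- function(cfg, ctgs, per_ctg, gene_spacing, margin = 20000L) {
  rows <- list()
  gi <- 0L
  for (ci in seq_along(ctgs)) {
    for (j in seq_len(per_ctg)) {
      gi <- gi + 1L
      g <- margin + (j - 1L) * gene_spacing
      strand <- if (gi %% 2 == 1) "+" else "-"
      id <- sprintf("gene%02d", gi)
      txid <- paste0(id, ".t1")
      ex <- rbind(c(g, g + 999L), c(g + 2000L, g + 2599L), c(g + 3600L, g + 5099L))
      cds <- rbind(c(g + 600L, g + 999L), c(g + 2000L, g + 2599L),
                   c(g + 3600L, g + 4099L))
      cdslen <- cds[, 2] - cds[, 1] + 1L
      phase <- if (strand == "+") {
        c(0L, (3L - cumsum(cdslen)[-3] %% 3L) %% 3L)
      } else {
        rev(c(0L, (3L - cumsum(rev(cdslen))[-3] %% 3L) %% 3L))
      }
      rows[[gi]] <- tibble(
        gene_id = id, transcript_id = txid, contig = ctgs[ci], strand = strand,
        type = c(rep("exon", 3), rep("CDS", 3)),
        start = c(ex[, 1], cds[, 1]), end = c(ex[, 2], cds[, 2]),
        phase = c(0L, 0L, 0L, phase)
      )
    }
  }
  out <- bind_rows(rows)
  out$coding <- TRUE
  out
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# overwrite the reference under each CDS with a clean open reading frame
plant_orfs <- function(reference, genes) {
  for (tx in unique(genes$transcript_id)) {
    cds <- genes[genes$transcript_id == tx & genes$type == "CDS", , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    ctg <- cds$contig[1]
    total <- sum(cds$end - cds$start + 1L)
    orf <- paste0("ATG",
                  paste(sample(SENSE_CODONS, (total - 6L) %/% 3L, replace = TRUE),
                        collapse = ""), "TAA")
    genomic <- if (cds$strand[1] == "+") orf else revcomp(orf)
    off <- 0L
    seq <- reference[[ctg]]
    for (i in seq_len(nrow(cds))) {
      w <- cds$end[i] - cds$start[i] + 1L
      substr(seq, cds$start[i], cds$end[i]) <- substr(genomic, off + 1L, off + w)
      off <- off + w
    }
    reference[[ctg]] <- seq
  }
  reference
}

tile_elements <- function(cfg, ctgs, len, period, offset) {
  bind_rows(lapply(ctgs, function(ctg) {
    starts <- seq.int(offset, cfg$contig_length - len, by = period)
    tibble(contig = ctg, start = starts, end = starts + len - 1L)
  }))
}

make_track <- function(cfg, ctgs, elevated, mu_elem, sd_elem, sd_bg) {
  bind_rows(lapply(ctgs, function(ctg) {
    n <- cfg$contig_length
    inside <- rep(FALSE, n)
    e <- elevated[elevated$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(e))) inside[e$start[i]:e$end[i]] <- TRUE
    val <- rnorm(n, mean = ifelse(inside, mu_elem, 0),
                 sd = ifelse(inside, sd_elem, sd_bg))
    tibble(contig = ctg, pos = seq_len(n), value = val)
  }))
}

# the known generating mutation model: transition-biased spectrum with
# elevated asymmetric CpG rates, mild local rate variation
generating_model <- function(cfg, ctgs) {
  grid <- tidyr::expand_grid(context = all_contexts(), alt = BASES)
  grid <- grid[substr(grid$context, 2, 2) != grid$alt, , drop = FALSE]
  cpg <- is_cpg_context(grid$context)
  center <- substr(grid$context, 2, 2)
  ti <- (center == "C" & grid$alt == "T") | (center == "T" & grid$alt == "C")
  grid$prob <- ifelse(cpg,
                      ifelse(ti, 0.8, 0.1),
                      ifelse(ti, 0.6, 0.2))
  weight <- tibble(context = all_contexts())
  weight$weight <- ifelse(is_cpg_context(weight$context), 8, 1)
  lens <- c(-(10:1), 1:10)
  lp <- 0.6^abs(lens)
  lp <- ifelse(lens < 0, 0.6 * lp / sum(lp[lens < 0]), 0.4 * lp / sum(lp[lens > 0]))
  nwin <- ceiling(cfg$contig_length / cfg$window_size)
  mult <- rep_len(c(0.6, 0.8, 1.0, 1.2, 1.4), nwin * length(ctgs))
  mult <- mult / mean(mult)
  structure(list(
    sub_rates = grid[!cpg, c("context", "alt", "prob")],
    cpg_rates = grid[cpg, c("context", "alt", "prob")],
    context_weight = weight,
    indel_len_dist = tibble(len = lens, prob = lp),
    local_mult = tibble(contig = rep(ctgs, each = nwin),
                        window = rep(seq_len(nwin), length(ctgs)),
                        mult = mult),
    window_size = as.integer(cfg$window_size),
    composition = rep(0.25, 4),
    n_snv = NA_integer_, n_indel = NA_integer_
  ), class = "mutation_model")
}

draw_neutral_set <- function(reference, gen_model, conservation, activity,
                             cfg, seed) {
  s <- -log(1 - cfg$rejection_fraction) /
    (cfg$cons_elem_mean - cfg$selection_threshold)
  survival <- function(v) {
    cons <- track_values_for_variants(conservation, v)
    act <- track_values_for_variants(activity, v)
    exp(-s * pmax(cons - cfg$selection_threshold, 0) -
          cfg$activity_weight * s * pmax(act - cfg$selection_threshold, 0))
  }
  keep_snv <- NULL; keep_ind <- NULL
  round <- 0L
  while (is.null(keep_snv) || nrow(keep_snv) < cfg$n_neutral_snv ||
         nrow(keep_ind) < cfg$n_neutral_indel) {
    round <- round + 1L
    if (round > 40L) abort("selection rejected too many candidates")
    cand <- simulate_variants(reference, gen_model,
                              n_snv = 4L * cfg$n_neutral_snv,
                              n_indel = 4L * cfg$n_neutral_indel,
                              seed = seed + 1000L * round)
    surv <- survival(cand)
    acc <- withr::with_seed(seed + 1000L * round + 1L,
                            runif(nrow(cand)) < surv)
    cand <- cand[acc, , drop = FALSE]
    keep_snv <- bind_rows(keep_snv, cand[cand$vclass == "SNV", ])
    keep_ind <- bind_rows(keep_ind, cand[cand$vclass != "SNV", ])
  }
  out <- bind_rows(head(keep_snv, cfg$n_neutral_snv),
                   head(keep_ind, cfg$n_neutral_indel))
  arrange(out, .data$contig, .data$pos, .data$ref, .data$alt)
}

make_mpra <- function(cfg, reference, regulatory, activity, seed) {
  withr::with_seed(seed + 31L, {
    reg1 <- regulatory[regulatory$contig == regulatory$contig[1], , drop = FALSE]
    idx <- unique(round(seq(1, nrow(reg1),
                            length.out = min(cfg$n_mpra_elements, nrow(reg1)))))
    pick <- reg1[idx, , drop = FALSE]
    rows <- list()
    for (k in seq_len(nrow(pick))) {
      e_start <- pick$start[k]
      e_end <- e_start + cfg$mpra_element_len - 1L
      pos <- sort(sample(e_start:e_end, cfg$mpra_variants_per_element))
      is_del <- runif(length(pos)) < 0.15
      refb <- vapply(pos, function(p) ref_slice(reference, pick$contig[k], p, p), "")
      ref2 <- vapply(pos, function(p) ref_slice(reference, pick$contig[k], p,
                                                min(p + 1L, nchar(reference[[pick$contig[k]]]))), "")
      alt <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L), "")
      importance <- abs(rnorm(length(pos), sd = 1))
      effect <- ifelse(runif(length(pos)) < 0.5, -1, 1) * importance * 1.5 +
        rnorm(length(pos), sd = 0.3)
      barcodes <- rpois(length(pos), 28) + rbinom(length(pos), 1, 0.15) * -20L
      barcodes <- pmax(barcodes, 0L)
      p_value <- pmin(1, exp(-abs(effect) * 6) * runif(length(pos), 0.1, 1))
      rows[[k]] <- tibble(
        element = sprintf("elem%02d", k), contig = pick$contig[k], pos = pos,
        ref = ifelse(is_del, ref2, refb),
        alt = ifelse(is_del, refb, alt),
        effect = effect, barcodes = as.integer(barcodes), p_value = p_value
      )
    }
    bind_rows(rows)
  })
}

make_aalik <- function(genes, reference, conservation, seed) {
  reference <- as_reference(reference)
  txs <- unique(genes$transcript_id)[1:2]
  out <- list()
  for (i in seq_along(txs)) {
    g <- genes[genes$transcript_id == txs[i], , drop = FALSE]
    tx <- split_transcripts(g)[[1]]
    genomic <- unlist(mapply(seq.int, tx$cds$start, tx$cds$end, SIMPLIFY = FALSE))
    seq <- paste(substring(reference[[tx$contig]], genomic, genomic), collapse = "")
    if (tx$strand == "-") {
      seq <- revcomp(seq)
      genomic <- rev(genomic)
    }
    prot <- translate_to_stop(seq)
    L <- nchar(prot)
    idx <- genomic[seq_len(3L * L)]
    v <- track_lookup(conservation, rep(tx$contig, length(idx)), idx)
    cons_codon <- colMeans(matrix(v, nrow = 3L))
    conc <- pmax(cons_codon, 0) * 1.5
    out[[txs[i]]] <- synthetic_likelihood_provider(prot, seed = seed + 100L + i,
                                                   conservation_profile = conc)
  }
  out
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  files <- c(
    ref = write_fasta(bundle$reference, f("ref.fa")),
    genes = write_gene_models(bundle$genes, f("genes.gff3")),
    neutral = write_vcf(bundle$neutral, f("neutral.vcf.gz"),
                        contig_lengths = vapply(bundle$reference, nchar, 0L)),
    conservation = write_track(bundle$conservation, f("conservation.bedGraph")),
    activity = write_track(bundle$activity, f("activity.bedGraph"))
  )
  readr::write_tsv(bundle$mpra, f("mpra.tsv"), progress = FALSE)
  files <- c(files, mpra = f("mpra.tsv"))
  for (nm in names(bundle$aalik)) {
    write_aa_likelihood(bundle$aalik[[nm]], f(paste0("aalik_", nm)))
  }
  jsonlite::write_json(bundle$manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest = f("manifest.json"))
  files
}
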