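#' Molecular consequence annotation
#'
#' A deliberately minimal transcript-model annotator: it assigns one
#' consequence label per variant using a fixed severity order and, for
#' coding SNVs/MNVs, the protein-level change. It is not a full VEP
#' replacement (no splice-region beyond +/-2 bp, no NMD, no
#' selenocysteine); the scoring framework needs consequence categories,
#' not annotation parity.
#'
#' @name consequence
NULL

CONSEQUENCES <- c("canonical_splice", "nonsense", "frameshift", "missense",
                  "inframe_indel", "synonymous", "UTR5", "UTR3", "intronic",
                  "non_coding_transcript", "upstream", "downstream",
                  "intergenic")

severity_rank <- function(label) match(label, CONSEQUENCES)

#' Annotate variants with consequence labels
#'
#' Labels follow a fixed precedence (most severe wins when several
#' transcripts are hit): canonical splice (+/-2 bp into an intron) over
#' coding labels (nonsense > frameshift > missense > inframe indel >
#' synonymous) over 5'/3' UTR, intronic, non-coding transcript,
#' upstream/downstream (within `flank`), intergenic.
#'
#' @param variants A normalized variant tibble.
#' @param genes A gene-model tibble (see [read_gene_models()]).
#' @param reference Named character vector or `DNAStringSet`.
#' @param flank Upstream/downstream flank in bp (default 5000).
#' @return `variants` with added columns `consequence`, `protein_pos`,
#'   `ref_aa`, `alt_aa`, `lost_from`, `lost_to`.
#' @export
annotate_consequence <- function(variants, genes, reference, flank = 5000L) {
  reference <- as_reference(reference)
  txs <- split_transcripts(genes)
  for (i in seq_along(txs)) {
    if (txs[[i]]$coding) txs[[i]]$cds_cache <- tx_cds_cache(txs[[i]], reference)
  }
  n <- nrow(variants)
  res <- tibble(consequence = rep("intergenic", n),
                protein_pos = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_, lost_from = NA_integer_,
                lost_to = NA_integer_)
  if (length(txs) == 0 || n == 0) return(bind_cols(variants, res))

  # one master interval table over all transcripts; every non-coding label
  # is resolved by a single overlap join, only coding hits need per-variant
  # codon work
  master <- bind_rows(lapply(seq_along(txs), function(i) {
    tx_intervals(txs[[i]], i, flank)
  }))
  master$start <- pmax(master$start, 1L)
  master <- master[master$start <= master$end, , drop = FALSE]

  vstart <- variants$pos
  vend <- variants$pos + nchar(variants$ref) - 1L
  is_del <- variants$vclass == "DEL"
  is_ins <- variants$vclass == "INS"
  vstart[is_del] <- vstart[is_del] + 1L      # anchor base unchanged
  vend[is_ins] <- vend[is_ins] + 1L          # insertion sits on a boundary

  gr_v <- GenomicRanges::GRanges(variants$contig,
                                 IRanges::IRanges(vstart, pmax(vend, vstart)))
  gr_m <- GenomicRanges::GRanges(master$contig,
                                 IRanges::IRanges(master$start, master$end))
  ov <- GenomicRanges::findOverlaps(gr_v, gr_m)
  hi <- tibble(vi = S4Vectors::queryHits(ov),
               rank = master$rank[S4Vectors::subjectHits(ov)],
               tx = master$tx[S4Vectors::subjectHits(ov)])

  # best non-coding label per variant
  nc <- hi[!is.na(hi$rank), , drop = FALSE]
  if (nrow(nc)) {
    best_nc <- nc |> group_by(.data$vi) |>
      summarise(rank = min(.data$rank), .groups = "drop")
    res$consequence[best_nc$vi] <- CONSEQUENCES[best_nc$rank]
  }

  # coding hits: codon-level resolution per (variant, transcript) pair,
  # accumulated in plain vectors (tibble row assignment is too slow in bulk)
  cd <- hi[is.na(hi$rank), , drop = FALSE]
  if (nrow(cd)) {
    best_rank <- rep(14L, n)
    if (nrow(nc)) best_rank[best_nc$vi] <- best_nc$rank
    csq <- res$consequence
    ppos <- res$protein_pos; raa <- res$ref_aa; aaa <- res$alt_aa
    lfrom <- res$lost_from; lto <- res$lost_to
    vref <- variants$ref; valt <- variants$alt; vcls <- variants$vclass
    for (k in seq_len(nrow(cd))) {
      vi <- cd$vi[k]
      lab <- coding_label(txs[[cd$tx[k]]], vstart[vi], vend[vi],
                          vref[vi], valt[vi], vcls[vi])
      r <- severity_rank(lab$consequence)
      if (r < best_rank[vi]) {
        best_rank[vi] <- r
        csq[vi] <- lab$consequence
        ppos[vi] <- lab$protein_pos
        raa[vi] <- lab$ref_aa
        aaa[vi] <- lab$alt_aa
        lfrom[vi] <- lab$lost_from
        lto[vi] <- lab$lost_to
      }
    }
    res$consequence <- csq
    res$protein_pos <- ppos; res$ref_aa <- raa; res$alt_aa <- aaa
    res$lost_from <- lfrom; res$lost_to <- lto
  }
  bind_cols(variants, res)
}

# interval decomposition of one transcript; rank indexes CONSEQUENCES,
# NA rank marks CDS intervals (resolved per variant later)
tx_intervals <- function(tx, idx, flank) {
  ex <- tx$exons
  out <- list()
  add <- function(start, end, rank) {
    tibble(contig = tx$contig, start = as.integer(start),
           end = as.integer(end), rank = as.integer(rank), tx = idx)
  }
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      intron <- c(ex$end[i] + 1L, ex$start[i + 1] - 1L)
      if (intron[1] > intron[2]) next
      out <- c(out, list(
        add(intron[1], min(intron[1] + 1L, intron[2]), 1L),
        add(max(intron[2] - 1L, intron[1]), intron[2], 1L)
      ))
      if (tx$coding) {
        # intronic (splice outranks it); in non-coding transcripts interior
        # hits collapse into non_coding_transcript instead
        out <- c(out, list(add(intron[1], intron[2], 9L)))
      }
    }
  }
  if (tx$coding) {
    for (i in seq_len(nrow(tx$cds))) {
      out <- c(out, list(add(tx$cds$start[i], tx$cds$end[i], NA)))
    }
    cds_span <- c(min(tx$cds$start), max(tx$cds$end))
    left_rank <- if (tx$strand == "+") 7L else 8L   # UTR5 / UTR3
    right_rank <- if (tx$strand == "+") 8L else 7L
    for (i in seq_len(nrow(ex))) {
      if (ex$start[i] < cds_span[1]) {
        out <- c(out, list(add(ex$start[i],
                               min(ex$end[i], cds_span[1] - 1L), left_rank)))
      }
      if (ex$end[i] > cds_span[2]) {
        out <- c(out, list(add(max(ex$start[i], cds_span[2] + 1L),
                               ex$end[i], right_rank)))
      }
    }
  } else {
    out <- c(out, list(add(tx$span[1], tx$span[2], 10L)))
  }
  up_rank <- if (tx$strand == "+") 11L else 12L
  dn_rank <- if (tx$strand == "+") 12L else 11L
  out <- c(out, list(add(tx$span[1] - flank, tx$span[1] - 1L, up_rank),
                     add(tx$span[2] + 1L, tx$span[2] + flank, dn_rank)))
  bind_rows(out)
}

# label a variant overlapping a CDS, using the transcript's cached CDS
coding_label <- function(tx, vstart, vend, ref, alt, vclass) {
  out <- list(consequence = "missense", protein_pos = NA_integer_,
              ref_aa = NA_character_, alt_aa = NA_character_,
              lost_from = NA_integer_, lost_to = NA_integer_)
  cc <- tx$cds_cache
  if (vclass %in% c("INS", "DEL")) {
    shift <- abs(nchar(ref) - nchar(alt))
    if (shift %% 3 != 0) {
      out$consequence <- "frameshift"
      ti <- match(vstart:vend, cc$genomic)
      ti <- ti[!is.na(ti)]
      if (length(ti)) {
        out$lost_from <- (min(ti) - 1L) %/% 3L + 1L
        out$lost_to <- cc$n_codons
      }
    } else {
      out$consequence <- "inframe_indel"
    }
    return(out)
  }
  ti <- match(vstart:vend, cc$genomic)
  keep <- !is.na(ti)
  if (!any(keep)) return(out)
  ti <- ti[keep]
  alt_b <- strsplit(alt, "")[[1]][keep]
  if (tx$strand == "-") alt_b <- unname(COMP[alt_b])
  c1 <- (min(ti) - 1L) %/% 3L + 1L
  c2 <- (max(ti) - 1L) %/% 3L + 1L
  ref_cod <- substr(cc$cds_seq, (c1 - 1L) * 3L + 1L, c2 * 3L)
  alt_vec <- strsplit(ref_cod, "")[[1]]
  alt_vec[ti - (c1 - 1L) * 3L] <- alt_b
  ref_aa <- translate_codons(ref_cod)
  alt_aa <- translate_codons(paste(alt_vec, collapse = ""))
  diffi <- which(ref_aa != alt_aa)
  if (length(diffi) == 0) {
    out$consequence <- "synonymous"
    out$protein_pos <- c1
    out$ref_aa <- ref_aa[1]
    out$alt_aa <- ref_aa[1]
    return(out)
  }
  stops <- diffi[alt_aa[diffi] == "*"]
  if (length(stops)) {
    p <- c1 + stops[1] - 1L
    out$consequence <- "nonsense"
    out$protein_pos <- p
    out$ref_aa <- ref_aa[stops[1]]
    out$alt_aa <- "*"
    out$lost_from <- p
    out$lost_to <- cc$n_codons     # through the final (stop) codon
  } else {
    p <- c1 + diffi[1] - 1L
    out$consequence <- "missense"
    out$protein_pos <- p
    out$ref_aa <- ref_aa[diffi[1]]
    out$alt_aa <- alt_aa[diffi[1]]
  }
  out
}

# internal: one list entry per transcript with precomputed structure
split_transcripts <- function(genes) {
  lapply(split(genes, genes$transcript_id), function(g) {
    exons <- g[g$type == "exon", , drop = FALSE]
    cds <- g[g$type == "CDS", , drop = FALSE]
    exons <- exons[order(exons$start), , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    list(
      transcript_id = g$transcript_id[1], gene_id = g$gene_id[1],
      contig = g$contig[1], strand = g$strand[1],
      exons = exons[, c("start", "end")], cds = cds[, c("start", "end")],
      phase = if (nrow(cds)) cds$phase[if (g$strand[1] == "+") 1 else nrow(cds)] else 0L,
      coding = nrow(cds) > 0,
      span = c(min(exons$start), max(exons$end))
    )
  })
}

# per-transcript cache: CDS sequence in transcript orientation plus the
# genomic position of each CDS base (transcript order)
tx_cds_cache <- function(tx, reference) {
  if (!is.null(tx$cds_cache)) return(tx$cds_cache)
  genomic <- unlist(mapply(seq.int, tx$cds$start, tx$cds$end, SIMPLIFY = FALSE))
  seq <- paste(substring(reference[[tx$contig]], genomic, genomic), collapse = "")
  if (tx$strand == "-") {
    seq <- revcomp(seq)
    genomic <- rev(genomic)
  }
  list(cds_seq = seq, genomic = genomic, n_codons = nchar(seq) %/% 3L)
}

translate_codons <- function(s) {
  n <- nchar(s) %/% 3L
  cods <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[cods])
  aa[is.na(aa)] <- "X"
  aa
}

compare_proteins <- function(ref_p, alt_p) {
  r <- strsplit(ref_p, "")[[1]]
  a <- strsplit(alt_p, "")[[1]]
  L <- min(length(r), length(a))
  diffpos <- which(r[seq_len(L)] != a[seq_len(L)])
  if (length(diffpos) == 0 && length(r) == length(a)) {
    return(list(label = "synonymous", pos = NA_integer_,
                ref_aa = NA_character_, alt_aa = NA_character_))
  }
  if (length(a) < length(r) &&
      (length(diffpos) == 0 || diffpos[1] > length(a))) {
    # alt protein truncated: premature stop at residue length(a)+1
    p <- length(a) + 1L
    return(list(label = "nonsense", pos = p, ref_aa = r[p], alt_aa = "*"))
  }
  p <- diffpos[1]
  if (!is.na(a[p]) && a[p] == "*") {
    return(list(label = "nonsense", pos = p, ref_aa = r[p], alt_aa = "*"))
  }
  list(label = "missense", pos = p, ref_aa = r[p], alt_aa = a[p])
}

#' Protein-level context of a coding variant
#'
#' Rebuilds the transcript CDS from the reference, applies the variant, and
#' translates both sequences up to the first stop codon.
#'
#' @param variant A one-row variant tibble.
#' @param tx A transcript: either an entry from the internal transcript
#'   split or a gene-model tibble restricted to one transcript.
#' @param reference Named character vector or `DNAStringSet`.
#' @return A list with `ref_protein`, `residue_index` (1-based first
#'   affected residue) and `alt_protein`.
#' @export
protein_context <- function(variant, tx, reference) {
  reference <- as_reference(reference)
  if (is.data.frame(tx)) tx <- split_transcripts(tx)[[1]]
  if (!tx$coding) abort("transcript is non-coding")
  cds <- tx$cds
  if (min(cds$start) < 1 || max(cds$end) > contig_len(reference, tx$contig)) {
    abort("CDS outside the reference")
  }
  genomic <- unlist(mapply(seq.int, cds$start, cds$end, SIMPLIFY = FALSE))
  seq <- paste(substring(reference[[tx$contig]], genomic, genomic), collapse = "")
  # apply variant in genomic coordinates of the concatenated CDS
  vstart <- variant$pos; vref <- variant$ref; valt <- variant$alt
  idx <- match(vstart:(vstart + nchar(vref) - 1L), genomic)
  if (all(is.na(idx))) abort("variant does not overlap the CDS")
  first <- which(!is.na(idx))[1]
  # clip allele parts outside the CDS (exon-boundary spanning edits)
  inside <- !is.na(idx)
  ref_in <- paste(strsplit(vref, "")[[1]][inside], collapse = "")
  alt_in <- if (variant$vclass %in% c("SNV", "MNV")) {
    paste(strsplit(valt, "")[[1]][inside], collapse = "")
  } else valt  # anchored indel: anchor inside or clipped below
  cpos <- idx[inside][1]
  if (variant$vclass %in% c("INS", "DEL") && is.na(idx[1])) {
    # anchor base outside CDS: drop it from both alleles
    ref_in <- sub("^.", "", paste(strsplit(vref, "")[[1]][-1][inside[-1]], collapse = ""))
    alt_in <- sub("^.", "", valt)
  }
  alt_seq <- paste0(substr(seq, 1, cpos - 1), alt_in,
                    substr(seq, cpos + nchar(ref_in), nchar(seq)))
  if (tx$strand == "-") {
    seq <- revcomp(seq); alt_seq <- revcomp(alt_seq)
    cpos <- nchar(seq) - (cpos + nchar(ref_in) - 1L) + 1L
  }
  ref_protein <- translate_to_stop(seq)
  alt_protein <- translate_to_stop(alt_seq)
  residue_index <- ((cpos - 1L) %/% 3L) + 1L
  list(ref_protein = ref_protein, residue_index = residue_index,
       alt_protein = alt_protein, n_codons = nchar(seq) %/% 3L)
}

# translate, truncating any incomplete trailing codon, stopping at first *
translate_to_stop <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                           if.fuzzy.codon = "X"))
  sub("\\*.*$", "", aa)
}
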