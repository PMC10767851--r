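#' Read a per-base annotation track
#'
#' Reads a bedGraph (0-based half-open) or wiggle file and expands it to a
#' per-base table on 1-based coordinates. Positions not covered by the file
#' are absent from the result (missing is distinct from zero). Overlapping
#' intervals are an error.
#'
#' @param path Path to a `.bedGraph`/`.bg` or `.wig` file (optionally
#'   gzipped).
#' @param format Override format detection: `"bedGraph"` or `"wig"`.
#' @return A track tibble with columns `contig`, `pos` (1-based), `value`.
#' @export
read_track <- function(path, format = NULL) {
  if (is.null(format)) {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(wig)$", base)) "wig" else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = format)
  if (length(gr) == 0) return(tibble(contig = character(), pos = integer(), value = double()))
  if (any(BiocGenerics::width(gr) < 1)) abort("interval with start >= end in track file")
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(ov) > 0) abort("overlapping intervals in track file")
  track_from_granges(gr)
}

track_from_granges <- function(gr) {
  w <- BiocGenerics::width(gr)
  tibble(
    contig = rep(as.character(GenomicRanges::seqnames(gr)), w),
    pos = as.integer(unlist(mapply(seq.int, BiocGenerics::start(gr),
                                   BiocGenerics::end(gr), SIMPLIFY = FALSE))),
    value = rep(gr$score, w)
  )
}

#' Write a per-base track as bedGraph
#'
#' Adjacent positions with equal values are merged into intervals;
#' coordinates are converted to the bedGraph 0-based half-open convention.
#'
#' @param track A track tibble (`contig`, `pos`, `value`).
#' @param path Output path.
#' @param digits Values are rounded to this many decimals before run
#'   merging, keeping files compact and regeneration byte-stable.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, digits = 3) {
  track <- arrange(track, .data$contig, .data$pos)
  val <- round(track$value, digits)
  # runs of consecutive positions with identical value, per contig
  brk <- c(TRUE, diff(track$pos) != 1L |
             track$contig[-1] != track$contig[-nrow(track)] |
             val[-1] != val[-length(val)])
  run <- cumsum(brk)
  start <- track$pos[brk]
  end <- track$pos[c(brk[-1], TRUE)]
  lines <- sprintf("%s\t%d\t%d\t%s", track$contig[brk], start - 1L, end,
                   formatC(val[brk], format = "fg", digits = 15))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# internal: fast per-contig lookup of track values at positions (NA if absent)
track_lookup <- function(track, contig, pos) {
  out <- rep(NA_real_, length(pos))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    sub <- track[track$contig == ctg, , drop = FALSE]
    out[sel] <- sub$value[match(pos[sel], sub$pos)]
  }
  out
}

#' Read a reference FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase contig sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  setNames(toupper(as.character(x)), names(x))
}

#' Write a reference FASTA
#'
#' @param reference Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read toy gene models from GFF3
#'
#' Understands feature types `gene`, `mRNA`, `exon`, `CDS`,
#' `five_prime_UTR` and `three_prime_UTR`; exons and CDS are attached to
#' their transcript via `Parent`.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble with columns `gene_id`, `transcript_id`,
#'   `contig`, `strand`, `type`, `start`, `end`, `phase`, `coding`
#'   (per-transcript flag).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  tx <- df[df$type %in% c("mRNA", "transcript", "ncRNA"), , drop = FALSE]
  parent_of <- setNames(vapply(tx$Parent, function(p) p[1] %||% NA_character_, ""),
                        tx$ID)
  parts <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), , drop = FALSE]
  tx_id <- vapply(parts$Parent, function(p) p[1] %||% NA_character_, "")
  out <- tibble(
    gene_id = unname(parent_of[tx_id]),
    transcript_id = tx_id,
    contig = as.character(parts$seqnames),
    strand = as.character(parts$strand),
    type = parts$type,
    start = parts$start, end = parts$end,
    phase = ifelse(is.na(parts$phase), 0L, as.integer(parts$phase))
  )
  coding_tx <- unique(out$transcript_id[out$type == "CDS"])
  out$coding <- out$transcript_id %in% coding_tx
  arrange(out, .data$contig, .data$transcript_id, .data$start)
}

#' Write gene models as GFF3
#'
#' @param genes A gene-model tibble (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  tx <- genes |>
    group_by(.data$gene_id, .data$transcript_id, .data$contig, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gene <- tx |>
    group_by(.data$gene_id, .data$contig, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  fmt <- function(contig, type, start, end, strand, phase, attr) {
    sprintf("%s\tproxyscore\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            contig, type, start, end, strand, phase, attr)
  }
  lines <- c("##gff-version 3",
    fmt(gene$contig, "gene", gene$start, gene$end, gene$strand, ".",
        sprintf("ID=%s", gene$gene_id)),
    fmt(tx$contig, "mRNA", tx$start, tx$end, tx$strand, ".",
        sprintf("ID=%s;Parent=%s", tx$transcript_id, tx$gene_id)),
    fmt(genes$contig, genes$type, genes$start, genes$end, genes$strand,
        ifelse(genes$type == "CDS", as.character(genes$phase), "."),
        sprintf("Parent=%s", genes$transcript_id)))
  writeLines(lines, path)
  invisible(path)
}
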