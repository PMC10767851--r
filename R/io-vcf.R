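#' Read variants from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzip/bgzip), splits multi-allelic records
#' into one row per alternative allele, and normalizes every variant
#' (left-aligned, parsimonious) when a reference is supplied. Symbolic
#' alleles (`<DEL>`, breakends) and alleles containing `N` are skipped with
#' a warning. Input order is preserved apart from allele splitting.
#'
#' @param path Path to a VCF file.
#' @param reference Optional reference (named character vector or
#'   `DNAStringSet`); when given, REF alleles are checked against it and
#'   variants are normalized.
#' @return A variant tibble (see [variant_tbl()]).
#' @export
read_vcf <- function(path, reference = NULL) {
  check_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record files come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  tbl <- tibble(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = toupper(fix$REF), alt = toupper(fix$ALT)
  )
  tbl <- tidyr::separate_rows(tbl, "alt", sep = ",")
  drop <- grepl("[^ACGT]", tbl$ref) | grepl("[^ACGT]", tbl$alt) |
    tbl$alt == "." | tbl$alt == "*"
  if (any(drop)) {
    warn(paste0("skipping ", sum(drop),
                " allele(s) with symbolic or non-ACGT sequence"))
    tbl <- tbl[!drop, , drop = FALSE]
  }
  if (nrow(tbl) == 0) abort("no usable alleles left after filtering")
  out <- variant_tbl(tbl$contig, tbl$pos, tbl$ref, tbl$alt)
  if (!is.null(reference)) {
    reference <- as_reference(reference)
    obs <- mapply(function(c, p, r) ref_slice(reference, c, p, p + nchar(r) - 1L),
                  out$contig, out$pos, out$ref)
    if (any(obs != out$ref)) {
      abort(paste0("REF allele mismatch with reference at ",
                   out$contig[obs != out$ref][1], ":", out$pos[obs != out$ref][1]))
    }
    out <- normalize_variants(out, reference)
  }
  out
}

# light pre-scan so malformed lines are reported with their line number
check_vcf_lines <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    lines <- readLines(con, n = 5000L)
    if (length(lines) == 0) break
    for (l in lines) {
      i <- i + 1L
      if (startsWith(l, "#") || !nzchar(l)) next
      if (length(strsplit(l, "\t", fixed = TRUE)[[1]]) < 8) {
        abort(paste0("malformed VCF line ", i, ": fewer than 8 columns"))
      }
    }
  }
  invisible(TRUE)
}

#' Write a sites-only VCF
#'
#' Minimal VCF 4.2 writer used for synthetic fixtures and for exchanging
#' variant sets between pipeline stages.
#'
#' @param variants A variant tibble.
#' @param path Output path (gzip-compressed when it ends in `.gz`).
#' @param contig_lengths Optional named integer vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contig_lengths = NULL) {
  header <- c("##fileformat=VCFv4.2",
              if (!is.null(contig_lengths)) {
                sprintf("##contig=<ID=%s,length=%d>",
                        names(contig_lengths), as.integer(contig_lengths))
              },
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  variants$contig, variants$pos, variants$ref, variants$alt)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write scored variants as tsv.gz
#'
#' Gzip-compressed tab-separated output with header
#' `#Chrom Pos Ref Alt RawScore PHRED`; raw scores are written with 6
#' decimals and PHRED-scaled scores with 3, so a round trip through
#' [read_scores()] restores values at that precision. With
#' `include_anno = TRUE` any additional numeric columns of `scores` are
#' appended after the six fixed columns.
#'
#' @param scores A tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `raw`, `phred` (and optional annotation columns).
#' @param path Output path, conventionally ending in `.tsv.gz`.
#' @param include_anno Append annotation columns beyond the fixed six?
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, include_anno = FALSE) {
  if (nrow(scores) == 0) abort("refusing to write an empty score set")
  need <- c("contig", "pos", "ref", "alt", "raw", "phred")
  miss <- setdiff(need, names(scores))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  anno <- if (include_anno) setdiff(names(scores), c(need, "vclass")) else character()
  header <- paste(c("#Chrom", "Pos", "Ref", "Alt", "RawScore", "PHRED", anno),
                  collapse = "\t")
  fields <- cbind(scores$contig, scores$pos, scores$ref, scores$alt,
                  sprintf("%.6f", scores$raw), sprintf("%.3f", scores$phred))
  for (a in anno) {
    v <- scores[[a]]
    fields <- cbind(fields, if (is.numeric(v)) sprintf("%.6g", v) else as.character(v))
  }
  body <- apply(fields, 1, paste, collapse = "\t")
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a score file written by [write_scores()]
#'
#' @param path Path to a `.tsv.gz` score file.
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`, `raw`,
#'   `phred` plus any annotation columns present.
#' @export
read_scores <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:6] <- c("contig", "pos", "ref", "alt", "raw", "phred")
  names(tbl)[1] <- sub("^#", "", names(tbl)[1])
  tbl$contig <- as.character(tbl$contig)
  tbl
}
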