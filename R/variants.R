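#' Variant tables
#'
#' Variants are plain tibbles with columns `contig`, `pos` (1-based, VCF
#' convention: for insertions and deletions `pos` is the anchor base), `ref`,
#' `alt` (uppercase DNA on the reference strand) and `vclass`, one of
#' `"SNV"`, `"MNV"`, `"INS"`, `"DEL"`. `variant_tbl()` validates alleles and
#' derives `vclass`.
#'
#' @param contig Character vector of contig names.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of reference / alternative alleles.
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt`, `vclass`.
#' @examples
#' variant_tbl("chr1", 100, "A", "G")
#' @export
variant_tbl <- function(contig, pos, ref, alt) {
  tbl <- tibble(
    contig = as.character(contig), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt))
  )
  bad <- !grepl("^[ACGT]+$", tbl$ref) | !grepl("^[ACGT]+$", tbl$alt)
  if (any(bad)) {
    abort(paste0("alleles must match ^[ACGT]+$ (offending rows: ",
                 paste(head(which(bad), 5), collapse = ", "), ")"))
  }
  if (any(tbl$ref == tbl$alt)) abort("ref and alt must differ")
  tbl$vclass <- variant_class(tbl$ref, tbl$alt)
  long <- nchar(tbl$ref) >= 50 | nchar(tbl$alt) >= 50
  if (any(long)) {
    warn(paste0(sum(long), " variant(s) with allele length >= 50 bp; ",
                "scores for such variants are outside the trained range"))
  }
  tbl
}

variant_class <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  dplyr::case_when(
    nr == 1 & na == 1 ~ "SNV",
    nr == na          ~ "MNV",
    nr > na           ~ "DEL",
    TRUE              ~ "INS"
  )
}

#' Normalize variants (left-align and make parsimonious)
#'
#' Trims shared leading/trailing bases, then left-shifts indels as far as the
#' reference allows, re-anchoring indels on the base before the event (VCF
#' convention). Normalization is idempotent and yields the representation
#' with the smallest possible position.
#'
#' @param variants A variant tibble (see [variant_tbl()]).
#' @param reference A named character vector or `Biostrings::DNAStringSet`
#'   of contig sequences.
#' @return The variant tibble with normalized `pos`, `ref`, `alt`, `vclass`.
#' @export
normalize_variants <- function(variants, reference) {
  reference <- as_reference(reference)
  snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1  # already minimal
  todo <- which(!snv)
  if (length(todo)) {
    out <- pmap(variants[todo, c("contig", "pos", "ref", "alt")],
                function(contig, pos, ref, alt) {
      normalize_one(contig, pos, ref, alt, reference)
    })
    res <- bind_rows(out)
    variants$pos[todo] <- res$pos
    variants$ref[todo] <- res$ref
    variants$alt[todo] <- res$alt
    variants$vclass <- variant_class(variants$ref, variants$alt)
  }
  variants
}

normalize_one <- function(contig, pos, ref, alt, reference) {
  seq <- reference[[contig]]
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # trim shared suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # trim shared prefix
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  if (length(r) == length(a)) {  # SNV/MNV, fully trimmed
    return(tibble(pos = pos, ref = paste(r, collapse = ""),
                  alt = paste(a, collapse = "")))
  }
  # indel: move to unanchored representation
  if (r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  if (length(r) > 0 && length(a) > 0) {
    # unanchored block substitution of unequal length; keep as-is, re-anchor
    pos <- pos - 1L
    anchor <- substr(seq, pos, pos)
    return(tibble(pos = pos,
                  ref = paste0(anchor, paste(r, collapse = "")),
                  alt = paste0(anchor, paste(a, collapse = ""))))
  }
  ins <- length(r) == 0
  s <- if (ins) a else r  # inserted or deleted bases, event at position pos
  # left-roll: deletion of s at pos can move to pos-1 iff base at pos-1 equals
  # last base of s; same rotation rule for an insertion before pos
  while (pos > 1) {
    prev <- substr(seq, pos - 1, pos - 1)
    if (prev != s[length(s)]) break
    s <- c(prev, s[-length(s)])
    pos <- pos - 1L
  }
  anchor_pos <- pos - 1L
  if (anchor_pos < 1) {
    # cannot anchor to the left; anchor on the base after the event
    anchor <- substr(seq, pos + length(s) * (!ins), pos + length(s) * (!ins))
    if (ins) {
      return(tibble(pos = pos, ref = substr(seq, pos, pos),
                    alt = paste0(paste(s, collapse = ""), substr(seq, pos, pos))))
    }
    return(tibble(pos = pos, ref = paste0(paste(s, collapse = ""), anchor),
                  alt = anchor))
  }
  anchor <- substr(seq, anchor_pos, anchor_pos)
  if (ins) {
    tibble(pos = anchor_pos, ref = anchor,
           alt = paste0(anchor, paste(s, collapse = "")))
  } else {
    tibble(pos = anchor_pos, ref = paste0(anchor, paste(s, collapse = "")),
           alt = anchor)
  }
}

#' Enumerate all possible SNVs of a reference
#'
#' One row per position and per non-reference base: the variant universe a
#' conversion table is built on.
#'
#' @inheritParams normalize_variants
#' @return A variant tibble with `3 * sum(contig lengths)` rows.
#' @export
enumerate_snvs <- function(reference) {
  reference <- as_reference(reference)
  bases <- c("A", "C", "G", "T")
  out <- imap(reference, function(seq, contig) {
    refb <- strsplit(seq, "")[[1]]
    keep <- refb %in% bases
    pos <- which(keep); refb <- refb[keep]
    alts <- lapply(bases, function(b) {
      i <- refb != b
      tibble(contig = contig, pos = pos[i], ref = refb[i], alt = b)
    })
    bind_rows(alts)
  })
  out <- arrange(bind_rows(out), .data$contig, .data$pos, .data$alt)
  out$vclass <- "SNV"
  out
}

# internal: coerce a reference to a named character vector of sequences,
# with contig lengths cached in an attribute (nchar rescans large strings)
as_reference <- function(reference) {
  if (is.character(reference)) {
    if (is.null(names(reference))) abort("reference must be named by contig")
    if (!is.null(attr(reference, "contig_lengths"))) return(reference)
    out <- toupper(reference)
  } else if (methods::is(reference, "DNAStringSet")) {
    out <- setNames(as.character(reference), names(reference))
  } else {
    abort("unsupported reference type")
  }
  attr(out, "contig_lengths") <- nchar(out)
  out
}

contig_len <- function(reference, contig) {
  lens <- attr(reference, "contig_lengths")
  if (is.null(lens)) lens <- nchar(reference)
  n <- unname(lens[contig])
  if (length(n) != 1 || is.na(n)) abort(paste0("contig not in reference: ", contig))
  n
}

ref_slice <- function(reference, contig, start, end) {
  if (!contig %in% names(reference)) abort(paste0("contig not in reference: ", contig))
  n <- contig_len(reference, contig)
  if (start < 1 || end > n) abort(paste0("positions ", start, "-", end,
                                         " outside contig ", contig, " (length ", n, ")"))
  substr(reference[[contig]], start, end)
}
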