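#' Protein likelihood ensembles
#'
#' Variant effects at the protein level are computed from per-residue amino
#' acid likelihood matrices: an ensemble of `M` members (default 5), each
#' an `L x 20` row-stochastic matrix, produced for a window around the edit
#' (350 residues for missense, 250 for indels; windowing is the provider's
#' contract, matrices arrive already restricted). A synthetic provider
#' stands in for a trained protein language model so the formulas are
#' testable offline; real per-residue likelihood files can be dropped in
#' via [read_aa_likelihood()].
#'
#' @name protein_lm
NULL

AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
P_FLOOR <- 1e-12

#' Construct an amino acid likelihood ensemble
#'
#' @param members List of `L x 20` numeric matrices (columns in the order
#'   of `AA_CODES`, i.e. alphabetical one-letter codes); rows must sum
#'   to 1.
#' @param seq The window's amino acid sequence (length `L`).
#' @param missense_window,indel_context Window parameters carried as
#'   metadata.
#' @return An object of class `aa_likelihood`.
#' @export
aa_likelihood <- function(members, seq, missense_window = 350L,
                          indel_context = 250L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  members <- lapply(members, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(L, 20))) abort("each member must be an L x 20 matrix")
    if (any(abs(rowSums(m) - 1) > 1e-6)) abort("member rows must sum to 1")
    colnames(m) <- AA_CODES
    pmax(m, P_FLOOR)
  })
  structure(list(members = members, seq = seq, L = L,
                 missense_window = as.integer(missense_window),
                 indel_context = as.integer(indel_context)),
            class = "aa_likelihood")
}

#' @export
print.aa_likelihood <- function(x, ...) {
  cat("<aa_likelihood> L=", x$L, ", ", length(x$members), " ensemble members\n",
      sep = "")
  invisible(x)
}

check_aa <- function(aa) {
  if (!all(aa %in% AA_CODES)) {
    abort(paste0("invalid amino acid code: ",
                 paste(setdiff(aa, AA_CODES), collapse = ", ")))
  }
  aa
}

#' Missense score: ensemble-average log odds of alternative vs reference
#'
#' For each ensemble member `m` the per-member score is
#' `log(p_m[pos, alt] / p_m[pos, ref])`; the reported score is the mean
#' over members. Negative values mean the alternative residue is
#' disfavored.
#'
#' @param mat An `aa_likelihood` covering the (windowed) protein.
#' @param pos 1-based residue index within the window.
#' @param ref_aa,alt_aa One-letter amino acid codes.
#' @return A single numeric score.
#' @export
missense_score <- function(mat, pos, ref_aa, alt_aa) {
  check_aa(c(ref_aa, alt_aa))
  if (pos < 1 || pos > mat$L) abort("pos outside the matrix")
  mean(vapply(mat$members, function(m) {
    log(max(m[pos, alt_aa], P_FLOOR) / max(m[pos, ref_aa], P_FLOOR))
  }, 0))
}

#' Per-member log-likelihood of a sequence under a likelihood ensemble
#'
#' @param mat An `aa_likelihood` with `L == nchar(seq)`.
#' @param seq Amino acid string.
#' @return Numeric vector, one log-likelihood per ensemble member.
#' @export
sequence_loglik <- function(mat, seq) {
  seq <- toupper(seq)
  if (nchar(seq) != mat$L) abort("sequence length does not match the matrix")
  aa <- check_aa(strsplit(seq, "")[[1]])
  idx <- cbind(seq_len(mat$L), match(aa, AA_CODES))
  vapply(mat$members, function(m) sum(log(pmax(m[idx], P_FLOOR))), 0)
}

#' Inframe indel score: length-normalized sequence log-odds
#'
#' Per member the score is
#' `loglik(alt)/len(alt) - loglik(ref)/len(ref)`; the report is the mean
#' over members. Length normalization keeps the score from being dominated
#' by the sequence-length difference itself. Negative values mean the
#' alternative sequence is disfavored.
#'
#' @param ref_mat,alt_mat `aa_likelihood` ensembles for the reference /
#'   alternative window (provider contract: 250-residue context around the
#'   edit).
#' @param ref_seq,alt_seq The corresponding amino acid strings, differing
#'   by one inframe insertion or deletion.
#' @return A single numeric score.
#' @export
inframe_indel_score <- function(ref_mat, ref_seq, alt_mat, alt_seq) {
  if (identical(toupper(ref_seq), toupper(alt_seq))) {
    abort("reference and alternative sequences are identical")
  }
  ll_ref <- sequence_loglik(ref_mat, ref_seq) / nchar(ref_seq)
  ll_alt <- sequence_loglik(alt_mat, alt_seq) / nchar(alt_seq)
  mean(ll_alt - ll_ref)
}

#' Truncation score for stop gains and frameshifts
#'
#' Each lost residue `i` contributes the ensemble-mean log ratio between a
#' worst-case substitute probability and the likelihood of the reference
#' residue; the score is the median over lost residues. Two substitute
#' strategies are provided: `"floor"` (default) uses each member's minimum
#' matrix probability as the worst-case substitute; `"uniform"` uses 1/20.
#'
#' @param mat An `aa_likelihood` whose `seq` covers the lost range.
#' @param lost_range Integer vector of length 2: first and last lost
#'   residue (1-based, inclusive).
#' @param strategy Substitute-probability strategy, `"floor"` or
#'   `"uniform"`.
#' @return A single numeric score (non-positive for the floor strategy).
#' @export
truncation_score <- function(mat, lost_range, strategy = c("floor", "uniform")) {
  strategy <- match.arg(strategy)
  lost <- seq.int(lost_range[1], lost_range[2])
  if (length(lost) == 0) abort("lost_range is empty")
  if (min(lost) < 1 || max(lost) > mat$L) abort("lost_range outside the matrix")
  aa <- check_aa(strsplit(mat$seq, "")[[1]])
  effects <- vapply(lost, function(i) {
    mean(vapply(mat$members, function(m) {
      p_sub <- if (strategy == "floor") max(min(m), P_FLOOR) else 1 / 20
      log(p_sub / max(m[i, aa[i]], P_FLOOR))
    }, 0))
  }, 0)
  median(effects)
}

#' Synthetic per-residue likelihood provider
#'
#' Stands in for a trained protein language model: each ensemble member's
#' row is a softmax over per-residue logits `conc * onehot(true residue) +
#' noise`, so high concentration residues are sharply peaked on the true
#' residue ("conserved") and zero-concentration residues are approximately
#' uniform. Deterministic per seed; members use consecutive derived seeds.
#'
#' @param seq Amino acid string.
#' @param seed Integer seed.
#' @param conservation_profile Per-residue non-negative concentration
#'   (recycled if scalar; default 2).
#' @param n_members Ensemble size (default 5).
#' @param noise_sd Logit noise standard deviation (default 0.25).
#' @return An `aa_likelihood`.
#' @export
synthetic_likelihood_provider <- function(seq, seed = 1L,
                                          conservation_profile = 2,
                                          n_members = 5L, noise_sd = 0.25) {
  seq <- toupper(seq)
  L <- nchar(seq)
  aa <- check_aa(strsplit(seq, "")[[1]])
  conc <- rep_len(conservation_profile, L)
  if (any(conc < 0)) abort("concentrations must be non-negative")
  onehot <- matrix(0, L, 20, dimnames = list(NULL, AA_CODES))
  onehot[cbind(seq_len(L), match(aa, AA_CODES))] <- 1
  members <- lapply(seq_len(n_members), function(m) {
    withr::with_seed(seed + m, {
      logits <- conc * onehot + matrix(rnorm(L * 20, sd = noise_sd), L, 20)
      e <- exp(logits - apply(logits, 1, max))
      e / rowSums(e)
    })
  })
  aa_likelihood(members, seq)
}

#' Read / write amino acid likelihood ensembles
#'
#' One tab-separated file per ensemble member: a header of the 20 one-letter
#' amino acid codes, then one row per residue. The window's sequence is
#' carried in a `#seq=` comment on the first line.
#'
#' @param paths Character vector of member file paths (in member order).
#' @return An `aa_likelihood`.
#' @export
read_aa_likelihood <- function(paths) {
  members <- list(); seqs <- character()
  for (p in paths) {
    lines <- readLines(p)
    seqs <- c(seqs, sub("^#seq=", "", lines[1]))
    hdr <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
    body <- do.call(rbind, lapply(strsplit(lines[-(1:2)], "\t", fixed = TRUE),
                                  as.numeric))
    colnames(body) <- hdr
    members <- c(members, list(body[, AA_CODES, drop = FALSE]))
  }
  if (length(unique(seqs)) != 1) abort("member files disagree on the sequence")
  aa_likelihood(members, seqs[1])
}

#' @rdname read_aa_likelihood
#' @param mat An `aa_likelihood` to write.
#' @param stem Output path stem; member `m` goes to `<stem>_m<m>.tsv`.
#' @export
write_aa_likelihood <- function(mat, stem) {
  paths <- character()
  for (m in seq_along(mat$members)) {
    p <- paste0(stem, "_m", m, ".tsv")
    body <- apply(mat$members[[m]], 1, function(r) {
      paste(sprintf("%.8g", r), collapse = "\t")
    })
    writeLines(c(paste0("#seq=", mat$seq),
                 paste(AA_CODES, collapse = "\t"), body), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
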