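# shared helpers: small random sequences, brute-force oracles

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

rand_seqs <- function(k, len) {
  vapply(seq_len(k), function(i) rand_dna(len), "")
}

plant_motif <- function(seq, motif) {
  p <- sample(nchar(seq) - nchar(motif), 1)
  paste0(substr(seq, 1, p - 1), motif, substr(seq, p + nchar(motif), nchar(seq)))
}

# a homotypic cluster: k copies of the motif at random positions
plant_cluster <- function(seq, motif, k = 10) {
  for (i in seq_len(k)) seq <- plant_motif(seq, motif)
  seq
}

# one random single-base mismatch in a motif (hard-negative material)
mutate_motif <- function(motif) {
  i <- sample(nchar(motif), 1)
  b <- sample(setdiff(c("A", "C", "G", "T"), substr(motif, i, i)), 1)
  paste0(substr(motif, 1, i - 1), b, substr(motif, i + 1, nchar(motif)))
}

# cluster of mutated copies (same composition statistics, broken motif)
plant_decoy_cluster <- function(seq, motif, k = 10) {
  for (i in seq_len(k)) seq <- plant_motif(seq, mutate_motif(motif))
  seq
}

# apply a variant to a contig sequence, returning the alternative haplotype
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1) == ref)
  paste0(substr(seq, 1, pos - 1), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}

# brute-force normalizer: enumerate every representation (pos, ref, alt) with
# allele lengths <= max_len that yields the same edited haplotype; pick the
# smallest position, then the shortest ref
brute_force_normalize <- function(seq, pos, ref, alt, max_len = 20) {
  target <- apply_variant(seq, pos, ref, alt)
  best <- NULL
  for (p in seq_len(nchar(seq))) {
    for (lr in 1:max_len) {
      if (p + lr - 1 > nchar(seq)) break
      r <- substr(seq, p, p + lr - 1)
      for (la in 1:max_len) {
        for (a in candidate_alts(target, p, la)) {
          if (r == a) next
          # only parsimonious representations: no trimmable shared suffix,
          # and a shared leading base only as a length-1 indel anchor
          if (nchar(r) > 1 && nchar(a) > 1 &&
              substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) next
          if (nchar(r) > 1 && nchar(a) > 1 &&
              substr(r, 1, 1) == substr(a, 1, 1)) next
          if (apply_variant(seq, p, r, a) == target) {
            cand <- list(pos = p, ref = r, alt = a)
            if (is.null(best) || cand$pos < best$pos ||
                (cand$pos == best$pos && nchar(cand$ref) < nchar(best$ref)) ||
                (cand$pos == best$pos && nchar(cand$ref) == nchar(best$ref) &&
                 nchar(cand$alt) < nchar(best$alt))) {
              best <- cand
            }
          }
        }
      }
    }
  }
  best
}

# the alt at position p of length la must be a substring of the target
candidate_alts <- function(target, p, la) {
  if (p + la - 1 > nchar(target)) return(character())
  substr(target, p, p + la - 1)
}

# a tiny two-gene world reused across consequence/feature tests
toy_world <- function(seed = 42) {
  withr::with_seed(seed, {
    left <- rand_dna(100)
    orf <- paste0("ATG", "GCA", "AAA", "TGC", "GAT", "TAA")  # M A K C D *
    right <- rand_dna(100)
    ref <- c(c1 = paste0(left, orf, right))
    genes <- tibble::tibble(
      gene_id = "g1", transcript_id = "g1.t1", contig = "c1", strand = "+",
      type = c("exon", "CDS"), start = c(101L, 101L), end = c(118L, 118L),
      phase = 0L, coding = TRUE
    )
    list(reference = ref, genes = genes, cds_start = 101L)
  })
}

small_fixture_config <- function(...) {
  fixture_config(contig_length = 30000L, n_contigs = 2L, n_genes = 4L,
                 n_neutral_snv = 500L, n_neutral_indel = 60L,
                 window_size = 10000L, n_mpra_elements = 4L,
                 mpra_variants_per_element = 30L, ...)
}
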