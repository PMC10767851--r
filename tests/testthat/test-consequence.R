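test_that("coding SNVs are classified by manual codon translation", {
  w <- toy_world()
  # CDS at 101..118: ATG GCA AAA TGC GAT TAA -> protein MAKCD
  s <- w$cds_start
  v <- variant_tbl("c1",
                   c(s + 4L,       # codon 2 GCA -> GAA (A2E missense)
                     s + 5L,       # codon 2 GCA -> GCG (synonymous)
                     s + 6L,       # codon 3 AAA -> TAA (nonsense K3*)
                     s + 16L),     # stop codon TAA -> TCA (stop loss)
                   c("C", "A", "A", "A"), c("A", "G", "T", "C"))
  ann <- annotate_consequence(v, w$genes, w$reference)
  expect_equal(ann$consequence, c("missense", "synonymous", "nonsense", "missense"))
  expect_equal(ann$protein_pos[1], 2L)
  expect_equal(ann$ref_aa[1], "A")
  expect_equal(ann$alt_aa[1], "E")
  # nonsense at K3: lost residues run to the final codon (stop included)
  expect_equal(ann$lost_from[3], 3L)
  expect_equal(ann$lost_to[3], 6L)
})

test_that("length-changing coding variants split by frame", {
  w <- toy_world()
  s <- w$cds_start
  ref3 <- substr(w$reference[["c1"]], s + 3L, s + 6L)  # anchored 3-bp deletion
  v <- variant_tbl("c1", c(s + 3L, s + 3L),
                   c(ref3, substr(ref3, 1, 2)),
                   c(substr(ref3, 1, 1), substr(ref3, 1, 1)))
  ann <- annotate_consequence(v, w$genes, w$reference)
  expect_equal(ann$consequence, c("inframe_indel", "frameshift"))
  expect_equal(ann$lost_to[2], 6L)  # frameshift loses through the last codon
})

test_that("protein context applies edits and re-translates", {
  w <- toy_world()
  s <- w$cds_start
  # inframe deletion of codon 2 (GCA): anchored at last base of codon 1
  v <- variant_tbl("c1", s + 2L,
                   substr(w$reference[["c1"]], s + 2L, s + 5L),
                   substr(w$reference[["c1"]], s + 2L, s + 2L))
  pc <- protein_context(v, w$genes, w$reference)
  expect_equal(pc$ref_protein, "MAKCD")
  expect_equal(pc$alt_protein, "MKCD")
  # frameshift re-translation equals naive translation of the mutated CDS
  v2 <- variant_tbl("c1", s + 6L,
                    substr(w$reference[["c1"]], s + 6L, s + 7L),
                    substr(w$reference[["c1"]], s + 6L, s + 6L))
  pc2 <- protein_context(v2, w$genes, w$reference)
  cds <- substr(w$reference[["c1"]], s, s + 17L)
  mutated <- paste0(substr(cds, 1, 7), substr(cds, 9, 18))
  expect_equal(pc2$alt_protein, proxyscore:::translate_to_stop(mutated))
  # synonymous change leaves the protein intact
  v3 <- variant_tbl("c1", s + 5L, "A", "G")
  pc3 <- protein_context(v3, w$genes, w$reference)
  expect_equal(pc3$alt_protein, pc3$ref_protein)
  # non-coding variant errors
  v4 <- variant_tbl("c1", 5L, substr(w$reference[["c1"]], 5, 5),
                    setdiff(c("A", "C", "G", "T"),
                            substr(w$reference[["c1"]], 5, 5))[1])
  expect_error(protein_context(v4, w$genes, w$reference), "CDS")
})

test_that("non-coding zones follow the documented precedence", {
  withr::with_seed(51, ref <- c(c1 = rand_dna(30000)))
  # gene: exons 10001-10500, 11001-11500; CDS 10101-10500, 11001-11300; plus
  genes <- tibble::tibble(
    gene_id = "g", transcript_id = "g.t1", contig = "c1", strand = "+",
    type = c("exon", "exon", "CDS", "CDS"),
    start = c(10001L, 11001L, 10101L, 11001L),
    end = c(10500L, 11500L, 10500L, 11300L),
    phase = 0L, coding = TRUE
  )
  at <- function(p) {
    b <- substr(ref[["c1"]], p, p)
    variant_tbl("c1", p, b, setdiff(c("A", "C", "G", "T"), b)[1])
  }
  cases <- list(
    list(pos = 10050L, want = "UTR5"),
    list(pos = 11400L, want = "UTR3"),
    list(pos = 10700L, want = "intronic"),
    list(pos = 10501L, want = "canonical_splice"),
    list(pos = 10999L, want = "canonical_splice"),
    list(pos = 9000L,  want = "upstream"),
    list(pos = 12000L, want = "downstream"),
    list(pos = 25000L, want = "intergenic")
  )
  for (cs in cases) {
    ann <- annotate_consequence(at(cs$pos), genes, ref, flank = 5000L)
    expect_equal(ann$consequence, cs$want, info = cs$pos)
  }
  # minus strand flips UTR and flank sides
  genes_m <- dplyr::mutate(genes, strand = "-")
  expect_equal(annotate_consequence(at(10050L), genes_m, ref)$consequence, "UTR3")
  expect_equal(annotate_consequence(at(9000L), genes_m, ref)$consequence,
               "downstream")
  # non-coding transcript collapses interior hits
  genes_nc <- genes[genes$type == "exon", ]
  genes_nc$coding <- FALSE
  expect_equal(annotate_consequence(at(10700L), genes_nc, ref)$consequence,
               "non_coding_transcript")
})

test_that("label choice is independent of gene-model row order", {
  fx <- make_fixtures(small_fixture_config(), seed = 3)
  withr::with_seed(52, {
    vpos <- sort(sample.int(29000, 150) + 500L)
    refb <- substring(fx$reference[["ctg1"]], vpos, vpos)
    v <- variant_tbl("ctg1", vpos, refb,
                     vapply(refb, function(b) setdiff(c("A", "C", "G", "T"), b)[1], ""))
  })
  a <- annotate_consequence(v, fx$genes, fx$reference)
  perm <- fx$genes[sample(nrow(fx$genes)), ]
  b <- annotate_consequence(v, perm, fx$reference)
  expect_equal(a$consequence, b$consequence)
})

test_that("fully intergenic mini-genome labels every SNV intergenic", {
  withr::with_seed(53, ref <- c(c1 = rand_dna(2000)))
  genes <- tibble::tibble(gene_id = character(), transcript_id = character(),
                          contig = character(), strand = character(),
                          type = character(), start = integer(),
                          end = integer(), phase = integer(),
                          coding = logical())
  pos <- seq(10, 1990, by = 20)
  refb <- substring(ref[["c1"]], pos, pos)
  v <- variant_tbl("c1", pos, refb,
                   vapply(refb, function(b) setdiff(c("A", "C", "G", "T"), b)[1], ""))
  ann <- annotate_consequence(v, genes, ref)
  expect_true(all(ann$consequence == "intergenic"))
})

test_that("minus-strand coding changes translate through reverse complement", {
  withr::with_seed(54, {
    left <- rand_dna(50)
    # minus-strand ORF: transcript M T W *; genomic = revcomp(ATGACCTGGTAA)
    orf <- "ATGACCTGGTAA"
    genomic <- proxyscore:::revcomp(orf)
    ref <- c(c1 = paste0(left, genomic, rand_dna(50)))
    genes <- tibble::tibble(
      gene_id = "g", transcript_id = "g.t1", contig = "c1", strand = "-",
      type = c("exon", "CDS"), start = 51L, end = 62L, phase = 0L,
      coding = TRUE
    )
    # genomic position of codon2 c2 (ACC, Thr): transcript pos 4..6 ->
    # genomic 59..57; change transcript A4->G means genomic 59 T->C
    v <- variant_tbl("c1", 59L, "T", "C")
    ann <- annotate_consequence(v, genes, ref)
    expect_equal(ann$consequence, "missense")
    expect_equal(ann$protein_pos, 2L)
    expect_equal(ann$ref_aa, "T")
    expect_equal(ann$alt_aa, "A")  # ACC -> GCC
  })
})
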