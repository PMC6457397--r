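two_exon_annotation <- function() {
  as_annotation_set(tibble::tibble(
    seqid = "scf1",
    type = c("gene", "mRNA", "exon", "exon"),
    start = c(1L, 1L, 1L, 201L), end = c(300L, 300L, 100L, 300L),
    strand = "+",
    id = c("g1", "g1.t1", "g1.t1.e1", "g1.t1.e2"),
    parent = c(NA, "g1", "g1.t1", "g1.t1")))
}

test_that("longest isoform selection maximizes exon sum with stable ties", {
  feats <- tibble::tibble(
    seqid = "scf1",
    type = c("gene", "mRNA", "exon", "mRNA", "exon", "exon"),
    start = c(1L, 1L, 1L, 1L, 1L, 700L),
    end = c(1300L, 900L, 900L, 1300L, 600L, 1299L),
    strand = "+",
    id = c("g1", "t_short", "e1", "t_long", "e2", "e3"),
    parent = c(NA, "g1", "t_short", "g1", "t_long", "t_long"))
  sel <- longest_isoform(as_annotation_set(feats))
  expect_equal(sel$transcript_id, "t_long") # 600 + 600 = 1200 > 900

  tie <- tibble::tibble(
    seqid = "scf1", type = c("gene", "mRNA", "exon", "mRNA", "exon"),
    start = c(1L, 1L, 1L, 1L, 1L), end = c(900L, 900L, 900L, 900L, 900L),
    strand = "+", id = c("g1", "t2", "e1", "t1", "e2"),
    parent = c(NA, "g1", "t2", "g1", "t1"))
  expect_equal(longest_isoform(as_annotation_set(tie))$transcript_id, "t1")
})

test_that("gene structure statistics follow the 1-based gap arithmetic", {
  gs <- gene_structure_stats(two_exon_annotation())
  expect_equal(gs$intron_count, 1L)
  expect_equal(gs$intron_span, 100L) # 201 - 100 - 1
  expect_equal(gs$exon_span, 200L)
  expect_equal(gs$extent, 300L)
  # conservation: intron span + exon span = transcript extent
  expect_equal(gs$intron_span + gs$exon_span, gs$extent)

  single <- as_annotation_set(tibble::tibble(
    seqid = "s", type = c("gene", "mRNA", "exon"),
    start = c(1L, 1L, 1L), end = c(500L, 500L, 500L), strand = "+",
    id = c("g", "t", "e"), parent = c(NA, "g", "t")))
  gs1 <- gene_structure_stats(single)
  expect_equal(gs1$intron_count, 0L)
  expect_equal(gs1$intron_span, 0L)
})

test_that("overlapping exons are rejected at construction", {
  expect_error(as_annotation_set(tibble::tibble(
    seqid = "s", type = c("gene", "mRNA", "exon", "exon"),
    start = c(1L, 1L, 1L, 50L), end = c(200L, 200L, 100L, 200L),
    strand = "+", id = c("g", "t", "e1", "e2"),
    parent = c(NA, "g", "t", "t"))), "overlapping")
})

test_that("structure statistics equal generator truth gene by gene", {
  sim <- sim_annotation_and_assembly(n_scaffolds = 2,
                                     genes_per_scaffold = 30,
                                     p_multi_isoform = 0.2, seed = 9)
  gs <- gene_structure_stats(sim$annotation)
  m <- dplyr::inner_join(gs, sim$gene_truth, by = "gene_id",
                         suffix = c("", ".true"))
  expect_equal(nrow(m), nrow(sim$gene_truth))
  expect_equal(m$intron_span, m$intron_span.true)
  expect_equal(m$intron_count, m$intron_count.true)
  expect_equal(m$exon_span, m$exon_span.true)
})

test_that("intergenic distances floor overlaps and skip scaffold flanks", {
  feats <- tibble::tibble(
    seqid = "s",
    type = rep(c("gene", "mRNA", "exon"), 2),
    start = c(1L, 1L, 1L, 201L, 201L, 201L),
    end = c(100L, 100L, 100L, 300L, 300L, 300L),
    strand = "+",
    id = c("gA", "tA", "eA", "gB", "tB", "eB"),
    parent = c(NA, "gA", "tA", NA, "gB", "tB"))
  res <- intergenic_distances(as_annotation_set(feats))
  expect_equal(res$pairs$distance, 100L)
  expect_equal(res$mean_distance, 100)

  overlapping <- feats
  overlapping$start[4:6] <- 50L
  overlapping$end[4:6] <- 150L
  res2 <- intergenic_distances(as_annotation_set(overlapping))
  expect_equal(res2$pairs$distance, 0L)

  lonely <- feats[1:3, ]
  res3 <- intergenic_distances(as_annotation_set(lonely))
  expect_equal(nrow(res3$pairs), 0)
  expect_true(is.na(res3$mean_distance))
})

test_that("intergenic distances match generator truth", {
  sim <- sim_annotation_and_assembly(n_scaffolds = 2,
                                     genes_per_scaffold = 20, seed = 17)
  res <- intergenic_distances(sim$annotation)
  expect_equal(res$mean_distance, mean(sim$intergenic_truth$distance))
})

test_that("assembly metrics follow the N50 definition", {
  sq <- Biostrings::DNAStringSet(c(a = strrep("A", 8), b = strrep("C", 5),
                                   c = strrep("G", 4), d = strrep("T", 3)))
  am <- assembly_metrics(sq)
  expect_equal(am$span, 20)
  expect_equal(am$scaffold_count, 4)
  expect_equal(am$n50, 5) # 8 + 5 = 13 >= 10
  # order invariance
  am2 <- assembly_metrics(sq[c(3, 1, 4, 2)])
  expect_equal(am2$n50, am$n50)

  one <- Biostrings::DNAStringSet(c(s = paste0(strrep("A", 96),
                                               strrep("N", 4))))
  m1 <- assembly_metrics(one)
  expect_equal(m1$n50, 100)
  expect_equal(m1$n_fraction, 4)

  eq <- Biostrings::DNAStringSet(c(a = strrep("A", 7), b = strrep("C", 7)))
  expect_equal(assembly_metrics(eq)$n50, 7)
  expect_error(assembly_metrics(Biostrings::DNAStringSet()), "empty")
})

test_that("log2 ratio tables are antisymmetric and drop zero denominators", {
  sA <- tibble::tibble(gene_id = c("a1", "a2", "a3"),
                       intron_span = c(200L, 100L, 0L),
                       intron_count = c(2L, 1L, 0L))
  sB <- tibble::tibble(gene_id = c("b1", "b2", "b3"),
                       intron_span = c(100L, 100L, 50L),
                       intron_count = c(1L, 1L, 1L))
  pairs <- tibble::tibble(gene_a = sA$gene_id, gene_b = sB$gene_id)
  ab <- ortholog_log2_ratios(sA, sB, pairs)
  expect_equal(ab$log2_span_ratio[1:2], c(1, 0))
  expect_true(is.na(ab$log2_span_ratio[3]))
  expect_equal(attr(ab, "dropped")[["span"]], 1)
  ba <- ortholog_log2_ratios(sB, sA,
                             tibble::tibble(gene_a = sB$gene_id,
                                            gene_b = sA$gene_id))
  expect_equal(ab$log2_span_ratio, -ba$log2_span_ratio)
  expect_equal(ab$log2_count_ratio, -ba$log2_count_ratio)
  expect_error(ortholog_log2_ratios(sA, sB,
                                    tibble::tibble(gene_a = "zz",
                                                   gene_b = "b1")),
               "unknown")
})

test_that("a planted intron contraction shows up in the median log2 ratio", {
  base_intron <- function(n) 40L + stats::rpois(n, 60)
  simA <- sim_annotation_and_assembly(n_scaffolds = 4,
                                      genes_per_scaffold = 60,
                                      intron_len_gen = base_intron,
                                      seed = 88)
  simB <- sim_annotation_and_assembly(
    n_scaffolds = 4, genes_per_scaffold = 60,
    intron_len_gen = function(n) {
      pmax(1L, as.integer(round(0.8 * base_intron(n))))
    },
    seed = 88)
  gsA <- gene_structure_stats(simA$annotation)
  gsB <- gene_structure_stats(simB$annotation)
  pairs <- tibble::tibble(gene_a = gsA$gene_id, gene_b = gsA$gene_id)
  ratios <- ortholog_log2_ratios(gsA, gsB, pairs)
  med <- stats::median(ratios$log2_span_ratio, na.rm = TRUE)
  expect_equal(med, log2(1 / 0.8), tolerance = 0.25)
})

test_that("annotations round-trip through GFF3", {
  sim <- sim_annotation_and_assembly(n_scaffolds = 1,
                                     genes_per_scaffold = 8, seed = 5)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(sim$annotation, path)
  back <- read_annotation(path)
  gs1 <- gene_structure_stats(sim$annotation)
  gs2 <- gene_structure_stats(back)
  expect_equal(gs2$intron_span, gs1$intron_span)
  expect_equal(gs2$intron_count, gs1$intron_count)
})
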