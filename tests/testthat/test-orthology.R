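make_og <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(orthogroup_id = r[[1]], species = r[[2]],
                   sequence_id = r[[3]], length_aa = as.integer(r[[4]]))
  }))
}

test_that("single-copy selection honours presence and copy-count rules", {
  species <- paste0("sp", sprintf("%02d", 1:33))
  # OG1: single copy in 27 species, absent from 6 -> selected
  og1 <- tibble::tibble(orthogroup_id = "OG1", species = species[1:27],
                        sequence_id = paste0("a", 1:27), length_aa = 100L)
  # OG2: only 26 species -> rejected
  og2 <- tibble::tibble(orthogroup_id = "OG2", species = species[1:26],
                        sequence_id = paste0("b", 1:26), length_aa = 100L)
  # OG3: double copy in an allowed species -> selected
  og3 <- tibble::tibble(orthogroup_id = "OG3",
                        species = c(species[1:27], "sp01"),
                        sequence_id = paste0("c", 1:28), length_aa = 100L)
  # OG4: double copy in a non-allowed species -> rejected
  og4 <- tibble::tibble(orthogroup_id = "OG4",
                        species = c(species[1:27], "sp05"),
                        sequence_id = paste0("d", 1:28), length_aa = 100L)
  tab <- dplyr::bind_rows(og1, og2, og3, og4)
  pol <- selection_policy(33, 27, double_allowed_species = "sp01")
  expect_equal(select_single_copy(tab, pol), c("OG1", "OG3"))
  expect_error(select_single_copy(
    tab, selection_policy(33, 27, double_allowed_species = "nosuch")),
    "absent")
})

test_that("selection is monotone in the presence threshold", {
  sim <- sim_orthogroup_table(paste0("s", 1:10), n_og = 80, p_present = 0.7,
                              seed = 44)
  pol_strict <- selection_policy(10, 8)
  pol_relaxed <- selection_policy(10, 6)
  sel_strict <- select_single_copy(sim$table, pol_strict)
  sel_relaxed <- select_single_copy(sim$table, pol_relaxed)
  expect_true(all(sel_strict %in% sel_relaxed))
})

test_that("paralogue screening keeps, discards and resolves as documented", {
  pol <- selection_policy(3, 2, support_threshold = 50)
  recs <- tibble::tibble(species = c("A", "A", "B", "C"),
                         sequence_id = c("A_1", "A_2", "B_1", "C_1"),
                         length_aa = c(300L, 250L, 200L, 200L))
  # in-paralogues form a clade: keep, retain the longer A sequence
  r1 <- screen_paralogs(read_newick("((A_1:1,A_2:1)95:1,(B_1:1,C_1:1)95:1);"),
                        recs, pol)
  expect_equal(r1$decision, "keep")
  expect_setequal(r1$retained$sequence_id, c("A_1", "B_1", "C_1"))
  expect_equal(nrow(r1$retained), length(unique(recs$species)))

  # A split across the tree with strong support: discard
  r2 <- screen_paralogs(read_newick("((A_1:1,B_1:1)95:1,(A_2:1,C_1:1)95:1);"),
                        recs, pol)
  expect_equal(r2$decision, "discard")

  # same topology but all supports < 50 collapse to a root polytomy, where
  # the A sequences are no longer separated by a supported edge: keep
  r3 <- screen_paralogs(read_newick("((A_1:1,B_1:1)30:1,(A_2:1,C_1:1)30:1);"),
                        recs, pol)
  expect_equal(r3$decision, "keep")
  expect_setequal(r3$retained$sequence_id, c("A_1", "B_1", "C_1"))
})

test_that("screening handles length ties, triples and unknown leaves", {
  pol <- selection_policy(3, 2)
  tie <- tibble::tibble(species = c("A", "A", "B"),
                        sequence_id = c("A_2", "A_1", "B_1"),
                        length_aa = c(300L, 300L, 100L))
  r <- screen_paralogs(read_newick("((A_1:1,A_2:1)90:1,B_1:1);"), tie, pol)
  expect_true("A_1" %in% r$retained$sequence_id) # lexicographic tie-break

  triple <- tibble::tibble(species = c("A", "A", "A", "B"),
                           sequence_id = c("A_1", "A_2", "A_3", "B_1"),
                           length_aa = c(1L, 2L, 3L, 4L))
  r2 <- screen_paralogs(
    read_newick("(((A_1:1,A_2:1)90:1,A_3:1)90:1,B_1:1);"), triple, pol)
  expect_equal(r2$decision, "discard")

  expect_error(screen_paralogs(read_newick("((A_1:1,A_2:1)90:1,X_9:1);"),
                               tie, pol), "without an orthogroup record")
})

test_that("kept orthogroups never retain two sequences of one species", {
  for (seed in 1:25) {
    sp <- sim_species_tree(6, seed = seed)$tree
    fam <- sim_gene_family(sp, dup_rate = 0.2, loss_rate = 0.05, seed = seed)
    if (fam$empty || is.null(fam$tree) ||
        length(fam$tree$tip.label) < 3) next
    recs <- tibble::tibble(species = fam$species_map$species,
                           sequence_id = fam$species_map$leaf,
                           length_aa = 100L + seq_len(nrow(fam$species_map)))
    tr <- fam$tree
    tr$node.label <- rep("90", tr$Nnode)
    res <- screen_paralogs(tr, recs, selection_policy(6, 4))
    if (res$decision == "keep") {
      expect_false(anyDuplicated(res$retained$species) > 0)
    }
  }
})

test_that("duplication ratio matches hand counts and errors when undefined", {
  tab <- dplyr::bind_rows(
    tibble::tibble(orthogroup_id = paste0("OG", 1:10), species = "X",
                   sequence_id = paste0("x", 1:10), length_aa = 10L),
    tibble::tibble(orthogroup_id = paste0("OG", 1:3), species = "X",
                   sequence_id = paste0("x", 11:13), length_aa = 10L),
    tibble::tibble(orthogroup_id = paste0("OG", 1:10), species = "Y",
                   sequence_id = paste0("y", 1:10), length_aa = 10L))
  ogs <- paste0("OG", 1:10)
  expect_equal(duplication_ratio(tab, ogs, "X"), 1.3) # 13 seqs / 10 OGs
  expect_equal(duplication_ratio(tab, ogs, "Y"), 1.0)
  expect_error(duplication_ratio(tab, ogs, "Z"), "Z")
  expect_error(duplication_ratio(tab, character(), "X"), "empty")
})

test_that("qc screen flags ratios strictly above the threshold", {
  sp <- paste0("sp", 1:8)
  sim <- sim_orthogroup_table(sp, n_og = 120, planted_dup_species = "sp3",
                              planted_dup_fraction = 0.6, seed = 50)
  qc <- qc_screen(sim$table, presence_min = 6, threshold = 1.2)
  expect_true(qc$excluded[qc$species == "sp3"])
  expect_false(any(qc$excluded[qc$species != "sp3"]))
  expect_equal(qc$duplication_ratio,
               sim$true_ratios$duplication_ratio[
                 match(qc$species, sim$true_ratios$species)])

  # a ratio of exactly the threshold is not excluded (strict >)
  tab <- dplyr::bind_rows(
    tibble::tibble(orthogroup_id = paste0("OG", 1:5), species = "X",
                   sequence_id = paste0("x", 1:5), length_aa = 10L),
    tibble::tibble(orthogroup_id = "OG1", species = "X",
                   sequence_id = "x6", length_aa = 10L),
    tibble::tibble(orthogroup_id = paste0("OG", 1:5), species = "Y",
                   sequence_id = paste0("y", 1:5), length_aa = 10L))
  qc2 <- qc_screen(tab, presence_min = 1, mean_count_max = 2, threshold = 1.2)
  expect_equal(qc2$duplication_ratio[qc2$species == "X"], 1.2)
  expect_false(qc2$excluded[qc2$species == "X"])

  expect_warning(qc_screen(tab, presence_min = 99), "no orthogroup")
})

test_that("wide orthogroup matrices ingest with FASTA-derived lengths", {
  wide <- "Orthogroup\tspA\tspB\nOG1\ta1, a2\tb1\nOG2\t\tb2\n"
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(wide, path)
  fasta <- Biostrings::AAStringSet(c(a1 = "MKV", a2 = "MKVL", b1 = "MK",
                                     b2 = "MKVLQ"))
  tab <- read_orthofinder_og(path, fasta)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$length_aa[tab$sequence_id == "a2"], 4L)
  expect_equal(sort(tab$species[tab$orthogroup_id == "OG1"]),
               c("spA", "spA", "spB"))
  expect_error(read_orthofinder_og(path, fasta[1:2]), "absent")
})

test_that("orthogroup tables round-trip through TSV", {
  sim <- sim_orthogroup_table(paste0("s", 1:4), n_og = 15, seed = 60)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_og_table(sim$table, path)
  back <- read_og_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$table))
})
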