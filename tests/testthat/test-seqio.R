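test_that("codon alignments read from FASTA, preserving order and frame", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">tx1", "ATGAAA", ">tx2", "ATGAAG"), f)
  aln <- read_codon_alignment(f)
  expect_s3_class(aln, "codon_alignment")
  expect_identical(aln$taxa, c("tx1", "tx2"))
  expect_identical(aln$n_codons, 2L)
  expect_identical(codon_matrix(aln)["tx2", ], c("ATG", "AAG"))
})

test_that("alignment validation: frame, stops, ambiguity policy", {
  expect_error(codon_alignment(c(A = "TTTT", B = "TTTT")),
               "frame error.*'A'.*4")
  expect_error(codon_alignment(c(A = "TTT", B = "TTTAAA")),
               "not aligned")
  # internal stop names the taxon and codon index
  expect_error(codon_alignment(c(A = "TTTTAATTT", B = "TTTTTTTTT")),
               "stop codon 'TAA'.*'A'.*codon 2")
  # a terminal stop is tolerated (treated as missing)
  expect_s3_class(codon_alignment(c(A = "TTTTAA", B = "TTTTTT")),
                  "codon_alignment")
  # ambiguity codes are accepted and become missing states
  aln <- codon_alignment(c(A = "NNNTTT", B = "TTRTTT", C = "---TTT"))
  st <- venomscan:::.codon_states(aln)
  expect_true(is.na(st["A", 1]) && is.na(st["B", 1]) && is.na(st["C", 1]))
  expect_false(anyNA(st[, 2]))
})

test_that("alignment FASTA round-trip is exact", {
  aln <- fixture_alignment(n_sites = 10)$alignment
  f <- withr::local_tempfile(fileext = ".fasta")
  write_codon_alignment(aln, f)
  aln2 <- read_codon_alignment(f)
  expect_identical(aln2$taxa, aln$taxa)
  expect_identical(aln2$sequences, aln$sequences)
})

test_that("foreground '#1' tags are parsed and round-tripped", {
  tr <- read_labeled_tree(text = "((A:0.1,B:0.1)#1:0.05,C:0.2);")
  expect_identical(n_foreground(tr), 1L)
  # the flagged edge is the stem of the AB clade
  ab <- ape::getMRCA(tr$phy, c("A", "B"))
  expect_identical(tr$phy$edge[tr$foreground, 2], ab)

  expect_identical(
    n_foreground(read_labeled_tree(text = "(A:0.1,(B:0.1,C:0.2):0.1);")),
    0L)

  # tip tags, and exact round-trip through write_labeled_tree
  tr2 <- read_labeled_tree(text = "((A#1:0.1,B:0.1)#1:0.05,C:0.2);")
  expect_identical(n_foreground(tr2), 2L)
  txt <- write_labeled_tree(tr2)
  tr3 <- read_labeled_tree(text = txt)
  expect_identical(sort(tr3$phy$tip.label), sort(tr2$phy$tip.label))
  expect_identical(n_foreground(tr3), 2L)
  expect_equal(sort(tr3$phy$edge.length), sort(tr2$phy$edge.length))
})

test_that("tree validation: negative lengths and malformed Newick", {
  expect_error(read_labeled_tree(text = "(A:-0.1,B:0.2);"),
               "negative branch length")
  expect_error(read_labeled_tree(text = "((A:0.1,B:0.2);"),
               "malformed Newick.*offset")
})

test_that("label_clade_foreground flags the stem and all descendants", {
  tr <- fixture_tree_8()
  # clade of A,B,C,D has 6 internal+tip edges plus the stem
  expect_identical(n_foreground(tr), 7L)
  tr_nostem <- label_clade_foreground(
    selection_tree(tr$phy), c("A", "B", "C", "D"), include_stem = FALSE)
  expect_identical(n_foreground(tr_nostem), 6L)
  expect_error(label_clade_foreground(tr, c("A", "ZZZ")),
               "not in tree")
})

test_that("coordinate map assigns consecutive reference positions", {
  aln <- amino_alignment(c(Mus = "MKLV", Opossum = "MKIV"))
  map <- build_coordinate_map(aln, "Mus", 524)
  expect_identical(map$ref_pos, 524:527)

  # reference gaps carry no position
  aln2 <- amino_alignment(c(Mus = "M-K", Opossum = "MKK"))
  map2 <- build_coordinate_map(aln2, "Mus", 524)
  expect_identical(map2$ref_pos, c(524L, NA, 525L))
  expect_identical(column_of(map2, 525), 3L)
  expect_error(column_of(map2, 628), "outside mapped range")
  expect_error(build_coordinate_map(aln2, "Rattus", 524), "not in")

  # injectivity on mapped columns
  mapped <- map2$ref_pos[!is.na(map2$ref_pos)]
  expect_identical(anyDuplicated(mapped), 0L)
  expect_true(all(diff(mapped) > 0))
})

test_that("binding sites and taxon groups validate their invariants", {
  b <- binding_sites()
  expect_length(b, 12L)
  expect_true(all(b >= A1_BOUNDS[1] & b <= A1_BOUNDS[2]))
  expect_error(binding_sites(c(628, 900)), "outside A1 bounds")

  expect_error(taxon_groups(c("A", "B"), c("B", "C")), "both groups")
  g <- taxon_groups(c("A", "B"), c("C"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxon_groups(g, f)
  g2 <- read_taxon_groups(f)
  expect_setequal(g2$resistant, g$resistant)
  expect_setequal(g2$non_resistant, g$non_resistant)
})

test_that("translation carries gaps and ambiguity to X/-", {
  aln <- codon_alignment(c(A = "ATGAAANNN---", B = "ATGAAGTTTTGG"))
  aa <- translate_alignment(aln)
  expect_identical(aa$sequences[["A"]], "MKX-")
  expect_identical(aa$sequences[["B"]], "MKFW")
})
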