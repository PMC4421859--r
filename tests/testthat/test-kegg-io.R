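test_that("parse_kgml splits multi-valued gene and reaction attributes", {
  kgml <- toy_kgml(gene_entry(1, c("g1", "g2"), "R00010"))
  out <- parse_kgml(kgml, "toy")
  expect_equal(out$gene, c("g1", "g2"))
  expect_equal(unique(out$reaction), "R00010")

  multi <- toy_kgml(gene_entry(1, "g1", c("R00010", "R00200")))
  out2 <- parse_kgml(multi, "toy")
  expect_setequal(out2$reaction, c("R00010", "R00200"))
})

test_that("parse_kgml returns an empty map for pathways without gene entries", {
  empty <- '<pathway name="path:toy00020" org="toy" number="00020"></pathway>'
  out <- parse_kgml(empty, "toy")
  expect_s3_class(out, "tbl_df")
  expect_equal(nrow(out), 0L)
})

test_that("merging pathway files unions reaction sets and is order-invariant", {
  p1 <- toy_kgml(gene_entry(1, "g1", "R00010"))
  p2 <- toy_kgml(gene_entry(1, "g1", "R00200"))
  ab <- parse_kgml(c(p1, p2), "toy")
  ba <- parse_kgml(c(p2, p1), "toy")
  expect_setequal(ab$reaction[ab$gene == "g1"], c("R00010", "R00200"))
  expect_identical(ab, ba)
})

test_that("parse_kgml reads the standalone <reaction> element dialect", {
  kgml <- paste0(
    '<pathway name="path:toy00030" org="toy" number="00030">',
    '<entry id="5" name="toy:g9" type="gene"/>',
    '<reaction id="5" name="rn:R00010" type="irreversible"/>',
    "</pathway>"
  )
  out <- parse_kgml(kgml, "toy")
  expect_equal(out$reaction[out$gene == "g9"], "R00010")
})

test_that("parse_kgml warns on unparseable reaction tokens and errors on bad XML", {
  kgml <- toy_kgml('<entry id="1" name="toy:g1" type="gene" reaction="rn:R00010 junk"/>')
  expect_warning(out <- parse_kgml(kgml, "toy"), "unparseable")
  expect_equal(out$reaction[out$gene == "g1"], "R00010")
  expect_error(parse_kgml("<pathway><entry", "toy"), "Malformed KGML")
})

test_that("genes without reactions are kept with an NA reaction", {
  kgml <- toy_kgml(paste0(gene_entry(1, "g1", "R00010"),
                          gene_entry(2, "g2")))
  out <- parse_kgml(kgml, "toy")
  expect_true(is.na(out$reaction[out$gene == "g2"]))
})

test_that("parse_brite_keg maps genes to level-2 headings with overlap", {
  keg <- toy_keg(list(
    "Energy metabolism" = c("g1", "g2"),
    "Cell motility" = "g2"
  ))
  out <- parse_brite_keg(keg, "toy")
  expect_setequal(out$gene[out$category == "Energy metabolism"], c("g1", "g2"))
  expect_equal(out$gene[out$category == "Cell motility"], "g2")
  expect_equal(dplyr::n_distinct(out$gene), 2L)
})

test_that("category sizes may sum above the distinct-gene total under overlap", {
  cats <- list(A = sprintf("g%d", 1:4), B = sprintf("g%d", 3:8),
               C = sprintf("g%d", 9:10))
  out <- parse_brite_keg(toy_keg(cats), "toy")
  sizes <- table(out$category)
  expect_equal(sum(sizes), 12)
  expect_equal(dplyr::n_distinct(out$gene), 10L)
})

test_that("parse_brite_keg rejects degenerate hierarchies", {
  no_b <- "A<b>Top</b>\nC    toy:g1  protein"
  expect_error(parse_brite_keg(no_b, "toy"), "No level-2")
  headings_only <- "A<b>Top</b>\nB  <b>Energy metabolism</b>"
  expect_error(parse_brite_keg(headings_only, "toy"), "zero|No gene")
})

test_that("gene lines outside any heading are skipped with a warning", {
  keg <- paste(c("A<b>Top</b>", "C      toy:g0  stray",
                 "B  <b>Energy metabolism</b>", "C      toy:g1  protein"),
               collapse = "\n")
  expect_warning(out <- parse_brite_keg(keg, "toy"), "outside")
  expect_equal(out$gene, "g1")
})

test_that("load_oxic_reactions normalizes, deduplicates and skips empty rows", {
  txt <- paste(
    "r_number\tec_number",
    "R00010\t3.2.1.20",
    "rn:R02558\t1.14.13.39",
    "R00010\t3.2.1.20",
    "junk\t",
    sep = "\n"
  )
  expect_warning(
    expect_warning(ox <- load_oxic_reactions(txt), "malformed"),
    "neither"
  )
  expect_setequal(ox$r_numbers, c("R00010", "R02558"))
  expect_setequal(ox$ec_numbers, c("3.2.1.20", "1.14.13.39"))
})

test_that("read_gene_lengths counts nucleotides across wrapped lines", {
  expect_equal(read_gene_lengths(">g1\nATGAAA\n", "toy")$length, 6L)
  wrapped <- paste0(">g2 desc\n", strrep(paste0(strrep("ACGT", 15), "\n"), 3))
  expect_equal(read_gene_lengths(wrapped, "toy")$length, 180L)
})

test_that("read_gene_lengths matches an independent character count", {
  set.seed(42)
  lens <- sample(50:400, 5)
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
  fasta <- paste(sprintf(">gene%d\n%s", 1:5, seqs), collapse = "\n")
  out <- read_gene_lengths(fasta, "toy")
  expect_equal(out$length[match(sprintf("gene%d", 1:5), out$gene)],
               vapply(seqs, nchar, integer(1), USE.NAMES = FALSE))
})

test_that("read_gene_lengths rejects duplicates and empty sequences", {
  expect_error(read_gene_lengths(">g1\nAC\n>g1\nGG\n", "toy"), "Duplicate")
  expect_error(read_gene_lengths(">g1\n\n>g2\nAC\n", "toy"), "Empty")
})

test_that("fixture round trip reproduces the generating maps exactly", {
  panel <- generate_panel(small_panel_config(), seed = 7)
  dir <- withr::local_tempdir()
  write_fixture_files(panel, dir, overwrite = TRUE)
  for (org in names(panel$annotations)[1:2]) {
    ann <- panel$annotations[[org]]
    grm <- parse_kgml(file.path(dir, paste0(org, ".xml")), org)
    expect_identical(
      dplyr::arrange(grm, gene, reaction),
      dplyr::arrange(ann$gene_reactions, gene, reaction)
    )
    cgm <- parse_brite_keg(file.path(dir, paste0(org, ".keg")), org)
    expect_identical(
      dplyr::arrange(cgm, category, gene),
      dplyr::arrange(ann$categories, category, gene)
    )
    lens <- read_gene_lengths(file.path(dir, paste0(org, ".fna")), org)
    expect_identical(
      dplyr::arrange(lens, gene),
      dplyr::arrange(dplyr::mutate(ann$lengths, length = as.integer(length)),
                     gene)
    )
  }
})
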