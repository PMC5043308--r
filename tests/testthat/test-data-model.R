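test_that("parse_newick handles well-formed trees and reports malformed input", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  # C sits at depth 2 from the root, A and B at depth 2 via one internal node
  depths <- ape::node.depth.edgelength(tr)[seq_len(3)]
  expect_equal(unname(depths[match("C", tr$tip.label)]), 2)

  expect_error(parse_newick("(A:1,B:1;"), "unclosed")
  expect_error(parse_newick("(A:1,B:1)"), "missing terminating")
  expect_error(parse_newick("(A:1,B:1)):1;"), "unmatched.*position")
  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate leaf")
})

test_that("newick round trip preserves topology, labels and branch lengths", {
  txt <- "((A:1.5,B:0.5):2,(C:1,D:1):2);"
  tr <- parse_newick(txt)
  expect_equal(ape::Ntip(tr), 4L)
  expect_equal(tr$Nnode, 3L)  # root + 2 internal
  tmp <- tempfile(fileext = ".nwk")
  write_tree(tr, tmp)
  tr2 <- read_tree(tmp)
  # patristic distances identify topology + branch lengths jointly
  d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(tr2)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-12)

  # property: random Yule trees survive the round trip
  for (seed in 1:5) {
    tr <- generate_tree(16, seed = seed)
    write_tree(tr, tmp)
    tr2 <- read_tree(tmp)
    d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(tr2)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-10)
  }
})

test_that("BRITE keg parsing counts distinct genes per third-level category", {
  keg <- "A<b>Metabolism</b>\nB  Carbohydrate\nC    00010 Glycolysis\nD      gene1\nD      gene2\n"
  expect_equal(count_genes_per_category(keg),
               c("00010 Glycolysis" = 2L))
  expect_equal(count_genes_per_category("C    00020 TCA\n"),
               c("00020 TCA" = 0L))
  # duplicate gene ids within one category count once
  dup <- "C 00030 PPP\nD gene1 description\nD gene1 other text\nD gene2\n"
  expect_equal(unname(count_genes_per_category(dup)["00030 PPP"]), 2L)
  # D before any C is a format error; so is D directly after a B heading
  expect_error(count_genes_per_category("D gene1\nC 00010 X\n"),
               "format error at line 1")
  expect_error(count_genes_per_category("C 00010 X\nD g1\nB next\nD g2\n"),
               "format error at line 4")
})

test_that("keg totals equal distinct gene tokens when genes are category-unique", {
  set.seed(3)
  for (rep in 1:10) {
    n_cat <- sample(2:6, 1)
    lines <- character(0)
    all_genes <- character(0)
    for (j in seq_len(n_cat)) {
      lines <- c(lines, sprintf("C %05d cat%d", j, j))
      genes <- sprintf("g%d_%d", j, seq_len(sample(0:8, 1)))
      all_genes <- c(all_genes, genes)
      if (length(genes) > 0) {
        lines <- c(lines, paste0("D ", genes, " some annotation"))
      }
    }
    counts <- count_genes_per_category(lines)
    expect_equal(sum(counts), length(unique(all_genes)))
    expect_length(counts, n_cat)
  }
})

test_that("build_function_matrix unions categories across species, filling zeros", {
  m <- build_function_matrix(list(
    spA = "C 00010 Gly\nD g1\nD g2\nC 00020 TCA\nD g3\n",
    spB = "C 00010 Gly\nD g1\n"
  ))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["spA", "00010 Gly"], 2L)
  expect_equal(m["spB", "00020 TCA"], 0L)
})

test_that("select_representatives keeps one species per genus by genome year", {
  tab <- make_species(4)
  tab$genus <- c("Mus", "Mus", "Rattus", "Pan")
  tab$genome_year <- c(2010L, 2005L, 2004L, 2007L)
  out <- select_representatives(tab)
  expect_equal(nrow(out), 3L)
  expect_true("sp002" %in% out$species_id)   # earliest Mus year wins
  expect_false("sp001" %in% out$species_id)

  out_late <- select_representatives(tab, prefer = "latest")
  expect_true("sp001" %in% out_late$species_id)

  # tie in year -> lexicographically smaller species_id
  tab$genome_year <- c(2005L, 2005L, 2004L, 2007L)
  expect_true("sp001" %in% select_representatives(tab)$species_id)

  # single-genus table is a no-op
  single <- make_species(3)
  expect_equal(select_representatives(single), single)

  # missing year for a contested genus is an error naming the genus
  tab$genome_year[1:2] <- NA
  expect_error(select_representatives(tab), "Mus")

  # property: output size equals number of distinct genera
  set.seed(9)
  big <- make_species(20)
  big$genus <- sample(c("A", "B", "C", "D"), 20, replace = TRUE)
  expect_equal(nrow(select_representatives(big)),
               length(unique(big$genus)))
})

test_that("species table validation enforces positivity, uniqueness and B_c = B/M", {
  tab <- make_species(5)
  expect_silent(validate_species_table(tab))
  bad <- tab; bad$body_mass_g[2] <- -1
  expect_error(validate_species_table(bad), "body_mass_g")
  bad <- tab; bad$species_id[2] <- bad$species_id[1]
  expect_error(validate_species_table(bad), "duplicate")
  bad <- tab; bad$mass_specific_rate_Wg[3] <- bad$mass_specific_rate_Wg[3] * 1.01
  expect_error(validate_species_table(bad), "inconsistent")
})

test_that("TSV readers and writers round-trip all three tabular formats", {
  dir <- tempfile(); dir.create(dir)
  tab <- make_species(5)
  write_species_table(tab, file.path(dir, "sp.tsv"))
  expect_equal(read_species_table(file.path(dir, "sp.tsv"))$species_id,
               tab$species_id)

  m <- matrix(0:5, nrow = 2, dimnames = list(c("s1", "s2"), c("c1", "c2", "c3")))
  write_function_matrix(m, file.path(dir, "m.tsv"))
  expect_equal(read_function_matrix(file.path(dir, "m.tsv")),
               validate_function_matrix(m))
  # species-as-rows orientation via the transpose flag
  write_function_matrix(m, file.path(dir, "m2.tsv"), transpose = FALSE)
  expect_equal(read_function_matrix(file.path(dir, "m2.tsv"), transpose = FALSE),
               validate_function_matrix(m))

  h <- c(c1 = "U1", c2 = "U1", c3 = "custom")
  write_hierarchy(h, file.path(dir, "h.tsv"))
  expect_equal(read_hierarchy(file.path(dir, "h.tsv")), h)
})
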