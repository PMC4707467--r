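test_that("dot-bracket parsing matches bracket structure and flags errors by position", {
  s <- parse_dotbracket("((..))")
  expect_equal(unname(s$pairs), cbind(c(1L, 2L), c(6L, 5L)))
  expect_false(any(s$pseudoknot))

  expect_equal(nrow(parse_dotbracket("......")$pairs), 0L)

  expect_error(parse_dotbracket("((("), "position 3")
  expect_error(parse_dotbracket("..)..."), "position 3")
  expect_error(parse_dotbracket("(.x..)"), "position 3")
  expect_error(parse_dotbracket("(...)",
                                rna_sequence("ACGUAC")), "length")
})

test_that("non-round bracket families are kept but flagged as pseudoknots", {
  s <- parse_dotbracket("((..[[..))..]]")
  expect_equal(sum(s$pseudoknot), 2L)
  expect_equal(sum(!s$pseudoknot), 2L)
  stripped <- suppressWarnings(strip_pseudoknots(s))
  expect_equal(nrow(stripped$pairs), 2L)
  expect_warning(strip_pseudoknots(s), "pseudoknot")
})

test_that("parse/render round-trips random nested structures", {
  set.seed(42)
  for (k in 1:50) {
    db <- random_nested_db(sample(10:60, 1))
    expect_identical(render_dotbracket(parse_dotbracket(db)), db)
  }
})

test_that("CT parsing reconstructs sequence and pairs, enforcing reciprocity", {
  ct <- c("4 toy", "1 G 0 2 4 1", "2 A 1 3 0 2", "3 C 2 4 0 3", "4 U 3 0 1 4")
  s <- parse_ct(paste(ct, collapse = "\n"))
  expect_equal(unname(s$pairs), cbind(1L, 4L))
  expect_equal(s$sequence$residues, "GACU")

  ct0 <- c("3 toy", "1 A 0 2 0 1", "2 C 1 3 0 2", "3 G 2 0 0 3")
  expect_equal(nrow(parse_ct(paste(ct0, collapse = "\n"))$pairs), 0L)

  bad <- c("5 toy", "1 A 0 2 0 1", "2 C 1 3 5 2", "3 G 2 4 0 3",
           "4 U 3 5 0 4", "5 A 4 0 0 5")
  expect_error(parse_ct(paste(bad, collapse = "\n")), "inconsistent")
})

test_that("CT and dot-bracket agree on pair sets for equivalent encodings", {
  db <- "((((...)))).."
  s1 <- parse_dotbracket(db)
  pt <- integer(nchar(db))
  for (k in seq_len(nrow(s1$pairs))) {
    pt[s1$pairs[k, 1]] <- s1$pairs[k, 2]
    pt[s1$pairs[k, 2]] <- s1$pairs[k, 1]
  }
  rows <- sprintf("%d N %d %d %d %d", 1:13, 0:12, c(2:13, 0), pt, 1:13)
  s2 <- parse_ct(paste(c("13 equiv", rows), collapse = "\n"))
  expect_equal(s2$pairs, s1$pairs)
})

test_that("PostScript coordinate reading handles both dialects and errors", {
  expect_equal(read_ps_coordinates("/coor [[0.0 0.0] [10.0 0.0]] def"),
               matrix(c(0, 10, 0, 0), 2, 2, dimnames = list(NULL, c("x", "y"))))

  strand <- paste(c("%!PS", "(G) 1.5 -2.5 a", "(C) 3e1 4.5 a", "7 8 lineto"),
                  collapse = "\n")
  expect_equal(unname(read_ps_coordinates(strand)),
               cbind(c(1.5, 30, 7), c(-2.5, 4.5, 8)))

  expect_error(read_ps_coordinates("%!PS\nshowpage\n"), "dialect")
  expect_error(read_ps_coordinates("/coor [] def"), "no \\[x y\\] rows")
})

test_that("PostScript writer round-trips arbitrary finite layouts exactly", {
  set.seed(7)
  for (n in c(2L, 76L)) {
    pts <- cbind(stats::rnorm(n) * 100, stats::rnorm(n) * 100)
    f <- withr::local_tempfile()
    write_ps_coordinates(pts, f, id = "rt")
    back <- read_ps_coordinates(f)
    expect_lt(max(abs(back - pts)), 1e-9)
    expect_equal(nrow(back), n)
  }
})

test_that("PDB reading: representative policies, chains, incompleteness", {
  toy <- paste(
    c("ATOM      1  C1'   A A   1       0.000   0.000   0.000  1.00  0.00           C",
      "ATOM      2  C1'   C A   2       3.000   0.000   0.000  1.00  0.00           C",
      "ATOM      3  C1'   G A   3       6.000   0.000   0.000  1.00  0.00           C"),
    collapse = "\n")
  s <- read_pdb_nucleotides(toy)
  expect_equal(nrow(s$points), 3L)
  expect_equal(s$chain_count, 1L)
  expect_equal(s$points[, "x"], c(0, 3, 6))
  expect_equal(s$sequence$residues, "ACG")

  two <- paste(
    c("ATOM      1  C1'   A A   1       0.000   0.000   0.000  1.00  0.00           C",
      "ATOM      2  C1'   A B   1       9.000   0.000   0.000  1.00  0.00           C"),
    collapse = "\n")
  expect_equal(read_pdb_nucleotides(two)$chain_count, 2L)

  multi <- paste(
    c("ATOM      1  C1'   U A   1       0.000   0.000   0.000  1.00  0.00           C",
      "ATOM      2  N1    U A   1       2.000   2.000   2.000  1.00  0.00           N"),
    collapse = "\n")
  expect_equal(unname(read_pdb_nucleotides(multi, "mean")$points[1, ]),
               c(1, 1, 1))
  expect_equal(unname(read_pdb_nucleotides(multi, "c1prime")$points[1, ]),
               c(0, 0, 0))
})

test_that("PDB reading keeps incomplete residues, reported not dropped", {
  txt <- make_toy_pdb(6, drop_atoms_of = c(2, 5))
  s <- read_pdb_nucleotides(txt)
  expect_equal(s$incomplete, c(2L, 5L))
  expect_equal(nrow(s$points), 6L)
  expect_true(all(is.na(s$points[2, ])))
  expect_true(all(is.finite(s$points[c(1, 3, 4, 6), ])))
})

test_that("only the first model of a multi-model PDB is read", {
  one <- "ATOM      1  C1'   A A   1       1.000   0.000   0.000  1.00  0.00           C"
  two <- "ATOM      1  C1'   A A   1       9.000   9.000   9.000  1.00  0.00           C"
  txt <- paste(c("MODEL     1", one, "ENDMDL", "MODEL     2", two, "ENDMDL"),
               collapse = "\n")
  expect_equal(unname(read_pdb_nucleotides(txt)$points[1, ]), c(1, 0, 0))
})

test_that("site TSV write/read round-trips, empty set writes header only", {
  ss <- merge_points(c(34L, 35L, 36L), n = 50, merge_gap = 2,
                     molecule_id = "m1")
  f <- withr::local_tempfile()
  write_sites(ss, f)
  back <- read_sites(f)
  expect_equal(back$start, 34L)
  expect_equal(back$end, 36L)
  expect_equal(back$molecule_id, "m1")

  f2 <- withr::local_tempfile()
  write_sites(merge_points(integer(0), n = 10), f2)
  expect_equal(nrow(read_sites(f2)), 0L)
  expect_equal(readLines(f2)[1],
               "molecule_id\tstart\tend\tpeak_position\tpeak_value")
})

test_that("FASTA reading normalizes the alphabet", {
  f <- withr::local_tempfile(lines = c(">m1 some description", "acgtACGT",
                                       ">m2", "AXGU"))
  seqs <- read_rna_fasta(f)
  expect_equal(names(seqs), c("m1", "m2"))
  expect_equal(seqs$m1$residues, "ACGUACGU")
  expect_equal(seqs$m2$residues, "ANGU")
})
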