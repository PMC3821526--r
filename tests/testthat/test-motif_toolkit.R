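test_that("find_motif returns 1-based lysine positions of exact matches", {
  expect_equal(find_motif(sequence_record("toy", "AAKVREIAA")), 3L)
  expect_equal(find_motif(sequence_record("toy", "KVREI")), 1L)
  expect_equal(find_motif(sequence_record("toy", "AAAAA")), integer(0))
  # two occurrences
  expect_equal(find_motif(sequence_record("toy", "KVREIXXKVREI")), c(1L, 8L))
  expect_error(find_motif(sequence_record("toy", "KVREI"), ""),
               class = "carbanm_parameter_error")
})

test_that("bundled connexin stand-ins carry the motif facts", {
  recs <- read_fasta(connexin_fixture_path())
  expect_equal(find_motif(recs$Cx26_synthetic), 125L)
  expect_equal(find_motif(recs$Cx30_synthetic), 125L)
  expect_equal(find_motif(recs$Cx32_synthetic), 125L)
  expect_equal(find_motif(recs$Cx31_synthetic), integer(0))
  # acceptor position 104: arginine in Cx26/30, lysine in Cx32/31
  pos104 <- function(r) substr(r$residues, 104, 104)
  expect_equal(pos104(recs$Cx26_synthetic), "R")
  expect_equal(pos104(recs$Cx30_synthetic), "R")
  expect_equal(pos104(recs$Cx32_synthetic), "K")
  expect_equal(pos104(recs$Cx31_synthetic), "K")
  expect_equal(substr(recs$Cx31_synthetic$residues, 123, 124), "KH")
})

test_that("motif insertion into the Cx31 stand-in creates/destroys the motif as designed", {
  recs <- read_fasta(connexin_fixture_path())
  cx31 <- recs$Cx31_synthetic
  len0 <- nchar(cx31$residues)

  m31 <- apply_edit(cx31, edit_spec("replace_range", 123, 124, "TQKVREI",
                                    label = "mCx31"))
  expect_equal(nchar(m31$residues), len0 + 5L)
  expect_equal(find_motif(m31), 125L)

  m31r <- apply_edit(cx31, edit_spec("replace_range", 123, 124, "TQRVREI",
                                     label = "mCx31_K125R"))
  expect_equal(nchar(m31r$residues), len0 + 5L)
  expect_equal(find_motif(m31r), integer(0))

  # K125R on the motif-bearing mutant removes the motif again
  k125r <- apply_edit(m31, "K125R")
  expect_equal(find_motif(k125r), integer(0))
  expect_match(k125r$identifier, "K125R")
})

test_that("mutation labels parse with wild-type guards; malformed labels rejected", {
  ed <- parse_mutation_label("K125E")
  expect_equal(ed$kind, "point_substitution")
  expect_equal(ed$start, 125L)
  expect_equal(ed$replacement, "E")
  expect_equal(ed$wt, "K")
  ed2 <- parse_mutation_label("R104E")
  expect_equal(ed2$start, 104L)
  expect_equal(ed2$wt, "R")

  expect_error(parse_mutation_label("125K"), class = "carbanm_parse_error")
  expect_error(parse_mutation_label("K125"), class = "carbanm_parse_error")
  expect_error(parse_mutation_label("B125Z"), class = "carbanm_parse_error")
})

test_that("wild-type guards catch off-by-one numbering", {
  recs <- read_fasta(connexin_fixture_path())
  # wild-type Cx31 stand-in has no lysine at 125 (background excludes K)
  expect_error(apply_edit(recs$Cx31_synthetic, "K125R"),
               class = "carbanm_consistency_error")
  expect_error(apply_edit(sequence_record("s", "AAA"),
                          edit_spec("replace_range", 2, 5, "GG")),
               class = "carbanm_bounds_error")
})

test_that("point substitutions invert exactly and length bookkeeping always holds", {
  recs <- read_fasta(connexin_fixture_path())
  m31 <- apply_edit(recs$Cx31_synthetic,
                    edit_spec("replace_range", 123, 124, "TQKVREI", label = "m"))
  ed <- parse_mutation_label("K125E")
  there <- apply_edit(m31, ed)
  back <- apply_edit(there, invert_edit(ed))
  expect_equal(back$residues, m31$residues)

  set.seed(99)
  seq0 <- recs$Cx26_synthetic
  for (i in 1:25) {
    len <- nchar(seq0$residues)
    start <- sample(len, 1L)
    end <- min(len, start + sample(0:6, 1L))
    repl <- paste(sample(c("A", "G", "S", "V"), sample(1:8, 1L), replace = TRUE),
                  collapse = "")
    out <- apply_edit(seq0, edit_spec("replace_range", start, end, repl))
    expect_equal(nchar(out$residues), len - (end - start + 1L) + nchar(repl))
  }
})

test_that("FASTA round-trips through Biostrings-backed I/O", {
  rec <- sequence_record("test_rec", "MKVREIAAX")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  back <- read_fasta(f)
  expect_equal(back[[1]]$identifier, "test_rec")
  expect_equal(back[[1]]$residues, "MKVREIAAX")
  expect_error(sequence_record("bad", "MK1"), class = "carbanm_format_error")
  expect_error(sequence_record("bad", ""), class = "carbanm_parameter_error")
})
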