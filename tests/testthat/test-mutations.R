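write_mut_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(paste(c("protein_id", "pdb_id", "chain", "position",
                       "wt_aa", "mut_aa", "region", "label"),
                     collapse = "\t"), lines), path)
  path
}

test_that("mutation rows map to validated records", {
  path <- write_mut_tsv(c("P02699\t1U19\tA\t135\tR\tW\tM\tdisease",
                          "P02699\t1U19\tA\t140\tArg\tTrp\tI\t-1",
                          "P02699\t1U19\tA\t150\tL\tV\tM\t"))
  rec <- read_mutation_table(path)
  expect_equal(nrow(rec), 3)
  expect_identical(rec$wt_aa, c("R", "R", "L"))
  expect_identical(rec$mut_aa, c("W", "W", "V"))
  expect_equal(rec$label, c(1, -1, NA))
  expect_equal(rec$position, c(135L, 140L, 150L))
})

test_that("malformed rows are rejected with their line numbers", {
  bad_region <- write_mut_tsv("P1\t1ABC\tA\t5\tR\tW\tX\tdisease")
  expect_error(read_mutation_table(bad_region), "region.*line 2")
  same_aa <- write_mut_tsv("P1\t1ABC\tA\t5\tR\tR\tM\tdisease")
  expect_error(read_mutation_table(same_aa), "wt_aa equals mut_aa")
  missing_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines("protein_id\tpdb_id\tchain\tposition\twt_aa\tmut_aa\tregion",
             missing_col)
  expect_error(read_mutation_table(missing_col), "missing required column")
})

test_that("header-only file yields an empty record set without error", {
  path <- write_mut_tsv(character(0))
  rec <- read_mutation_table(path)
  expect_equal(nrow(rec), 0)
})

test_that("mutation table write/read round-trips", {
  path <- write_mut_tsv(c("P1\t1ABC\tA\t5\tR\tW\tM\t+1",
                          "P2\t2XYZ\tB\t9\tL\tP\tL\t-1",
                          "P3\t3DEF\tC\t11\tG\tA\tM\t"))
  rec <- read_mutation_table(path)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_table(rec, out)
  expect_identical(read_mutation_table(out), rec)
})

test_that("region filtering preserves order and defaults to membrane only", {
  rec <- data.frame(protein_id = paste0("P", 1:4), pdb_id = "X",
                    chain = "A", position = 1:4,
                    wt_aa = c("R", "L", "G", "V"),
                    mut_aa = c("W", "P", "A", "I"),
                    region = c("M", "I", "M", "O"), label = 1,
                    stringsAsFactors = FALSE)
  kept <- filter_by_region(rec)
  expect_equal(kept$position, c(1L, 3L))
  expect_identical(filter_by_region(rec, keep = c("M", "L", "I", "O",
                                                  "S", "T")), rec)
  rec2 <- rec
  rec2$region <- c("L", "M", "T", "T")
  expect_equal(filter_by_region(rec2, keep = c("M", "L"))$position,
               c(1L, 2L))
  expect_error(filter_by_region(rec, keep = "X"))
})
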