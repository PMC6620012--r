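test_that("the three blocks have lengths 28, 44 and 24 and concatenate to 96", {
  lay <- descriptor_layout()
  expect_length(lay$names, 96)
  expect_length(lay$blocks$seq, 28)
  expect_length(lay$blocks$struct, 44)
  expect_length(lay$blocks$energy, 24)
  sb <- sequence_block("L", "I")
  expect_length(sb, 28)
  h <- fix_helix12()
  m <- mutate_side_chain(h, "A", 6, "V")
  expect_length(structure_block(h, m, "A", 6), 44)
  expect_length(energy_block(h, m, "A", 6), 24)
})

test_that("sequence block carries the substitution scores and swap symmetry", {
  sb <- sequence_block("L", "I")
  expect_equal(unname(sb["seq.sub.blosum62"]), 2)
  rev <- sequence_block("I", "L")
  # swapping wt/mut permutes the two property halves ...
  expect_equal(unname(rev[1:12]), unname(sb[13:24]))
  expect_equal(unname(rev[13:24]), unname(sb[1:12]))
  # ... swaps the directional scores, and fixes the symmetric ones
  expect_equal(unname(rev["seq.sub.slim_fwd"]), unname(sb["seq.sub.slim_rev"]))
  expect_equal(unname(rev["seq.sub.blosum62"]), unname(sb["seq.sub.blosum62"]))
  expect_equal(unname(rev["seq.sub.phat"]), unname(sb["seq.sub.phat"]))
  expect_error(sequence_block("L", "L"), "differ")
  expect_error(sequence_block("B", "L"), "standard")
})

test_that("model halves are exchangeable and one-hot sub-blocks sum to one", {
  h <- fix_helix12()
  ctx <- tmvarboost:::model_context(h)
  sb <- structure_block(h, h, "A", 6, ctx, ctx)
  expect_equal(unname(sb[1:22]), unname(sb[23:44]))
  eb <- energy_block(h, h, "A", 6, ctx, ctx)
  expect_equal(unname(eb[1:12]), unname(eb[13:24]))
  for (half in list(sb[1:22], sb[23:44])) {
    expect_equal(sum(half[1:6]), 1)    # secondary-structure one-hot
    expect_equal(sum(half[9:11]), 1)   # exposure one-hot
  }
})

test_that("full descriptor is 96 finite values and deterministic per seed", {
  h <- fix_helix15()
  rec <- data.frame(protein_id = "P", pdb_id = "X", chain = "A",
                    position = 8, wt_aa = "A", mut_aa = "W", region = "M",
                    label = 1, stringsAsFactors = FALSE)
  ctx <- tmvarboost:::model_context(h)
  v1 <- full_descriptor(rec, h, fast_repack(seed = 5), wt_ctx = ctx)
  v2 <- full_descriptor(rec, h, fast_repack(seed = 5), wt_ctx = ctx)
  expect_length(v1, 96)
  expect_true(all(is.finite(v1)))
  expect_identical(v1, v2)
  expect_identical(attr(v1, "layout_version"), descriptor_layout()$version)
  # wrong wild-type annotation is refused
  bad <- rec; bad$wt_aa <- "G"
  expect_error(full_descriptor(bad, h, fast_repack()), "does not match")
})

test_that("descriptor matrices round-trip through TSV at full precision", {
  h <- fix_helix12()
  recs <- toy_mutation_set(h, 3, seed = 2)
  ctx <- tmvarboost:::model_context(h)
  vecs <- lapply(seq_len(3), function(i) {
    full_descriptor(recs[i, ], h, fast_repack(), wt_ctx = ctx)
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_descriptor_matrix(vecs, recs, path)
  back <- read_descriptor_matrix(path)
  expect_equal(nrow(back$X), 3)
  expect_equal(ncol(back$X), 96)
  expect_equal(unname(back$X), unname(do.call(rbind, vecs)),
               tolerance = 1e-9)
  expect_identical(back$records$position, recs$position)
})

test_that("a layout version mismatch is refused on read", {
  h <- fix_helix12()
  recs <- toy_mutation_set(h, 1, seed = 3)
  v <- full_descriptor(recs[1, ], h, fast_repack())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_descriptor_matrix(list(v), recs, path)
  txt <- readLines(path)
  txt[1] <- "#layout=some-other-layout-v9"
  writeLines(txt, path)
  expect_error(read_descriptor_matrix(path), "version mismatch")
  # a missing feature column is also a layout error
  write_descriptor_matrix(list(v), recs, path)
  txt <- readLines(path)
  txt[2] <- sub("seq.wt.KUHL950101", "seq.wt.RENAMED", txt[2])
  writeLines(txt, path)
  expect_error(read_descriptor_matrix(path), "missing feature column")
})
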