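test_that("tokenization matches the token-level reading of SMILES", {
  expect_identical(smiles_tokenize("Cc1ccccc1"),
                   c("C", "c", "1", "c", "c", "c", "c", "c", "1"))
  expect_identical(smiles_tokenize("CCl"), c("C", "Cl"))
  expect_identical(smiles_tokenize("[nH]"), "[nH]")
  expect_identical(smiles_tokenize("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
})

test_that("tokenize is an exact partition of the input", {
  smi <- synth_smiles(synthetic_dataset_spec(100, seed = 2))
  for (s in smi) {
    expect_identical(paste(smiles_tokenize(s), collapse = ""), s)
  }
})

test_that("characters outside the SMILES alphabet are named in the error", {
  expect_error(smiles_tokenize("C!C"), "'!'")
  expect_error(smiles_tokenize("[nH"), "unterminated")
})

test_that("vocabulary is deterministic, contiguous, with distinct specials", {
  v1 <- build_vocab(c("CC", "CCO"))
  v2 <- build_vocab(c("CCO", "CC")) # order must not matter
  expect_identical(v1$token_to_id, v2$token_to_id)
  expect_identical(unname(sort(v1$token_to_id)), seq_len(v1$size) - 1L)
  expect_equal(length(unique(v1$specials)), 4)
  # 4 specials + 4 property slots + {C, O}
  expect_equal(v1$size, 10)
  expect_error(build_vocab(character(0)), "empty")
})

test_that("vocabulary JSON round trip is bit-exact", {
  v <- build_vocab(synth_smiles(synthetic_dataset_spec(50, seed = 3)))
  path <- withr::local_tempfile(fileext = ".json")
  save_vocab(v, path)
  v2 <- load_vocab(path)
  expect_identical(v$token_to_id, v2$token_to_id)
  expect_identical(v$specials, v2$specials)
})

test_that("encode produces the documented layout and decode inverts it", {
  v <- build_vocab(c("CCO", "c1ccccc1", "Cc1ccccc1"))
  # unconditional: [BOS, C, EOS, PAD...]
  s <- encode_sequence("CCO", generation_condition(), v, max_len = 16L)
  expect_length(s$ids, 16)
  expect_equal(s$bos_pos, 1)
  expect_identical(s$ids[1], unname(v$specials[["BOS"]]))
  expect_identical(s$ids[5], unname(v$specials[["EOS"]]))
  expect_true(all(s$ids[6:16] == v$specials[["PAD"]]))
  expect_identical(s$mask, seq_len(16) <= 5)
  # property + scaffold condition
  cond <- generation_condition(c(TPSA = 40, logP = 2), scaffold = "c1ccccc1")
  s2 <- encode_sequence("Cc1ccccc1", cond, v, max_len = 32L)
  expect_identical(s2$ids[1:2],
                   unname(v$prop_slots[c("logP", "TPSA")])) # canonical order
  expect_identical(s2$ids[3], unname(v$specials[["SEP"]]))
  expect_identical(s2$ids[12], unname(v$specials[["SEP"]]))
  expect_equal(s2$bos_pos, 13)
  expect_identical(as.character(decode_ids(s2$ids, v)), "Cc1ccccc1")
  # PAD only after EOS
  expect_true(all(which(s2$ids == v$specials[["PAD"]]) > s2$eos_pos))
})

test_that("round trip holds for every condition subset", {
  recs <- toy_records(40)
  v <- build_vocab(c(recs$smiles, recs$scaffold[nzchar(recs$scaffold)]))
  conds <- list(
    generation_condition(),
    generation_condition(c(TPSA = 50)),
    generation_condition(c(logP = 1, QED = 0.5, SAS = 2, TPSA = 30))
  )
  for (i in seq_len(20)) {
    scaf <- recs$scaffold[i]
    conds_i <- c(conds, if (nzchar(scaf)) {
      list(generation_condition(c(TPSA = 10), scaffold = scaf))
    })
    for (cond in conds_i) {
      s <- encode_sequence(recs$smiles[i], cond, v, max_len = 64L)
      dec <- decode_ids(s$ids, v)
      expect_identical(as.character(dec), recs$smiles[i])
      expect_true(attr(dec, "complete"))
    }
  }
})

test_that("over-length molecules raise a length error", {
  v <- build_vocab("CCO")
  long <- paste(rep("C", 120), collapse = "")
  expect_error(encode_sequence(long, generation_condition(), v, 100L),
               "exceeds max_len")
})

test_that("decode flags missing BOS or EOS as incomplete", {
  v <- build_vocab("CC")
  ids_no_bos <- rep(v$specials[["PAD"]], 5)
  out <- decode_ids(ids_no_bos, v)
  expect_identical(as.character(out), "")
  expect_false(attr(out, "complete"))
  c_id <- unname(v$token_to_id[["C"]])
  ids_no_eos <- c(v$specials[["BOS"]], c_id, c_id,
                  rep(v$specials[["PAD"]], 3))
  out2 <- decode_ids(ids_no_eos, v)
  expect_identical(as.character(out2), "CC")
  expect_false(attr(out2, "complete"))
  # trailing PAD after EOS is ignored
  ids_ok <- c(v$specials[["BOS"]], c_id, v$specials[["EOS"]],
              rep(v$specials[["PAD"]], 4))
  expect_identical(as.character(decode_ids(ids_ok, v)), "C")
})
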