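test_that("sequence composition frequencies match hand counts", {
  v <- seq_composition("ACGU")
  expect_equal(unname(v["miRNALen"]), 4)
  expect_equal(unname(v[paste0("MNC_", c("A", "C", "G", "U"))]), rep(0.25, 4))
  expect_equal(unname(v[c("DNC_AC", "DNC_CG", "DNC_GU")]), rep(1 / 3, 3))
  v <- seq_composition("AAAA")
  expect_equal(unname(v["MNC_A"]), 1)
  expect_equal(unname(v["DNC_AA"]), 1)
  v <- seq_composition("ACACA")
  expect_equal(unname(v["DNC_AC"]), 0.5)
  expect_equal(unname(v["DNC_CA"]), 0.5)
})

test_that("pairing statistics match enumerated windows and runs", {
  perfect <- rep(TRUE, 20)
  v <- pairing_stats(perfect)
  expect_equal(unname(v[c("bpNum", "mlBulge", "numBP_Win4")]), c(20, 20, 4))
  expect_equal(unname(v["perfectBP5_presence"]), 1)
  expect_equal(unname(v["perfectBP5_start"]), 0)
  expect_equal(unname(v["perfectBP20_presence"]), 1)
  alt <- rep(c(TRUE, FALSE), 10)           # strictly alternating
  v <- pairing_stats(alt)
  expect_equal(unname(v["numBP_Win4"]), 2)
  expect_equal(unname(v["perfectBP10_presence"]), 0)
  expect_equal(unname(v["perfectBP10_start"]), -1)
  # guide shorter than the window: the single full-guide window
  v <- pairing_stats(c(TRUE, TRUE, FALSE))
  expect_equal(unname(v["numBP_Win4"]), 2)
  expect_equal(unname(v["numBP_Win8"]), 2)
})

test_that("one-hot nucleotide context uses the documented bit codes", {
  pre <- fixture_perfect()                  # starts GCAUG...
  d <- derive_duplex(pre, c(1, 22))
  v <- featurize(pre, d, featurize_context(pre, quiet = TRUE))
  # guide = duplex 5p strand; its start anchor sits at position 1 (G -> 0100)
  expect_equal(unname(v["NT5p_start_0_G"]), 1)
  expect_equal(unname(v[c("NT5p_start_0_U", "NT5p_start_0_C", "NT5p_start_0_A")]),
               c(0, 0, 0))
  expect_equal(unname(v["NT5p_start_d1_C"]), 1)   # position 2 is C -> 0010
  # offsets before position 1 pad with all-zero codes
  up <- grep("NT5p_start_u", names(v), value = TRUE)
  expect_true(all(v[up] == 0))
})

test_that("entropy context pulls H(i) and pads out-of-bounds with 0", {
  pre <- fixture_perfect()
  suppressWarnings(ctx <- featurize_context(pre))  # degenerate bppm
  d <- derive_duplex(pre, c(1, 22))
  v <- featurize(pre, d, ctx)
  ent <- v[grep("posEntropy", names(v))]
  expect_length(ent, 22)
  expect_true(all(ent == 0))                # point-mass probabilities
  # uniform pairing over n partners injects log2(n) at the anchor slot
  n <- pre$n
  bp <- matrix(0, n, n)
  bp[1, 25:32] <- 1 / 8; bp[25:32, 1] <- 1 / 8
  pre2 <- premirna("u", pre$sequence, pre$structure, bppm = bp)
  ctx2 <- featurize_context(pre2, quiet = TRUE)
  v2 <- featurize(pre2, d, ctx2)
  expect_equal(unname(v2["posEntropyStart_0"]), 3)  # log2(8)
})

test_that("sequence-structure combination counts hit the documented classes", {
  v <- seq_struct_combos(c("A", "C", "G", "U"), c("(", "(", ".", "."))
  expect_equal(unname(v[c("monoSSq_A(", "monoSSq_C(", "monoSSq_G.", "monoSSq_U.")]),
               rep(1, 4))
  expect_equal(sum(v[grep("monoSSq", names(v))]), 4)
  expect_equal(unname(v["diSS_AC(("]), 1)
  expect_equal(unname(v["diSS_CG(."]), 1)   # paired C next to unpaired G
  # an unpaired A flanked by two paired neighbours
  v <- seq_struct_combos(c("G", "A", "C"), c("(", ".", ")"))
  expect_equal(unname(v["trip_A_(.("]), 1)
  # N routes to the undefined buckets
  v <- seq_struct_combos(c("A", "N", "C"), c("(", ".", ")"))
  expect_gte(unname(v["monoSSq_undef"]), 1)
  expect_equal(sum(v[grep("^diSS", names(v))]), 2)
  expect_equal(unname(v["diSS_undef"]), 2)
})

test_that("an all-A guide gives pure composition blocks", {
  pre <- premirna("pa", paste0(strrep("A", 20), "GGGG", strrep("U", 20)),
                  paste0(strrep("(", 20), "....", strrep(")", 20)))
  v <- featurize(pre, derive_duplex(pre, c(1, 20)),
                 featurize_context(pre, quiet = TRUE))
  expect_equal(unname(v["MNC_A"]), 1)
  expect_equal(unname(v["DNC_AA"]), 1)
  expect_equal(unname(v["monoSSq_A("]), 20)
})

test_that("featurize is deterministic and schema-complete", {
  sc <- small_corpus(5, seed = 23)
  ann <- sc$corpus$annotations[1, ]
  pre <- sc$pres[[ann$premirna_id]]
  d <- derive_duplex(pre, c(ann$start, ann$end))
  v1 <- featurize(pre, d)
  v2 <- featurize(pre, d)
  expect_identical(v1, v2)
  expect_length(v1, 440)
  expect_identical(names(v1), feature_schema()$name)
  expect_false(anyNA(v1))
  onehot <- grep("^NT", names(v1))
  expect_true(all(v1[onehot] %in% c(0, 1)))
  expect_equal(sum(v1[paste0("MNC_", c("A", "C", "G", "U"))]), 1)
})
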