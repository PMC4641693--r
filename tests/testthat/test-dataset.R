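test_that("one duplex per pre-miRNA even when both arms are annotated", {
  pre <- fixture_perfect()
  ann <- data.frame(premirna_id = c("perfect", "perfect"),
                    start = c(1, 29), end = c(22, 48))
  pos <- build_positive_set(list(perfect = pre), ann)
  expect_length(pos, 1)
  expect_equal(pos[[1]]$duplex$arm, "5p")
  expect_equal(pos[[1]]$sibling_arm, c(29, 48))
})

test_that("annotations are resolved by sequence with integrity checks", {
  pre <- fixture_perfect()
  ann <- data.frame(premirna_id = "perfect",
                    mirna_seq = substr(pre$sequence, 1, 22))
  pos <- build_positive_set(list(perfect = pre), ann)
  expect_equal(pos[[1]]$guide, c(1, 22))
  # T-spelled annotation still matches the U-normalized precursor
  ann$mirna_seq <- chartr("U", "T", ann$mirna_seq)
  expect_equal(build_positive_set(list(perfect = pre), ann)[[1]]$guide, c(1, 22))
  bad <- data.frame(premirna_id = "perfect", mirna_seq = strrep("ACGU", 5))
  expect_warning(
    expect_error(build_positive_set(list(perfect = pre), bad),
                 class = "mirlocate_empty_positive_set"))
})

test_that("negative intervals keep the true length and avoid the true start", {
  sc <- small_corpus(5, seed = 23)
  ann <- sc$corpus$annotations[1, ]
  pre <- sc$pres[[ann$premirna_id]]
  set.seed(9)
  negs <- sample_negatives(pre, c(ann$start, ann$end), 5)
  expect_length(negs, 5)
  for (ng in negs) {
    expect_equal(ng$guide[2] - ng$guide[1], ann$end - ann$start)
    expect_gt(abs(ng$guide[1] - ann$start), 2)
  }
})

test_that("a cramped precursor yields a logged shortfall, not an error", {
  pre <- fixture_perfect()                 # 48 nt
  set.seed(1)
  expect_warning(negs <- sample_negatives(pre, c(3, 42), 25),
                 class = "mirlocate_shortfall")
  expect_lt(length(negs), 25)
})

test_that("the hairpin generator is seed-deterministic and honors bulge_rate 0", {
  h1 <- generate_hairpin(seed = 77)
  h2 <- generate_hairpin(seed = 77)
  expect_identical(h1, h2)
  h0 <- generate_hairpin(bulge_rate = 0, seed = 3)
  arm5 <- substr(h0$sequence, 1, 45)
  arm3 <- substr(h0$sequence, 54, nchar(h0$sequence))
  expect_identical(arm3, revcomp(arm5))
  expect_error(generate_hairpin(guide_len = 10), class = "mirlocate_invalid_params")
  expect_error(generate_hairpin(bulge_rate = 0.5), class = "mirlocate_invalid_params")
  expect_error(generate_hairpin(loop_len = 2), class = "mirlocate_invalid_params")
})

test_that("folding recovers most planted guide pairs at bulge_rate 0.05", {
  frac <- vapply(1:25, function(s) {
    hp <- generate_hairpin(bulge_rate = 0.05, seed = 1000 + s)
    pre <- fold(stats::setNames(hp$sequence, hp$id))[[1]]
    gpos <- hp$guide_start:hp$guide_end
    mean(pre$pair_table[gpos] > 0)
  }, numeric(1))
  expect_gte(mean(frac), 0.8)
})

test_that("dataset construction is reproducible and respects the RPNS", {
  sc <- small_corpus(10, seed = 31)
  d1 <- build_training_set(sc$pres, sc$corpus$annotations, rpns = 5, seed = 4)
  d2 <- build_training_set(sc$pres, sc$corpus$annotations, rpns = 5, seed = 4)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$info, d2$info)
  expect_equal(sum(d1$y == "positive"), 10)
  expect_equal(sum(d1$y == "negative"), 50)
  # no negative interval duplicates the positive interval of its precursor
  for (id in unique(d1$info$premirna_id)) {
    sub <- d1$info[d1$info$premirna_id == id, ]
    pos <- sub[sub$label == "positive", ]
    neg <- sub[sub$label == "negative", ]
    expect_false(any(neg$start == pos$start & neg$end == pos$end))
  }
})

test_that("fold splitting is stratified, disjoint, and grouped by precursor", {
  # singleton groups: exact class balance
  toy <- list(y = factor(rep(c("positive", "negative"), 50),
                         levels = c("negative", "positive")),
              groups = sprintf("g%03d", 1:100))
  f <- split_folds(toy, k = 10, seed = 2)
  expect_equal(as.integer(table(f)), rep(10L, 10))
  per_class <- table(f, toy$y)
  expect_true(all(per_class == 5))
  # 101 samples: sizes differ by at most one
  toy2 <- list(y = factor(c(rep("positive", 50), rep("negative", 51)),
                          levels = c("negative", "positive")),
               groups = sprintf("h%03d", 1:101))
  f2 <- split_folds(toy2, k = 10, seed = 2)
  expect_lte(diff(range(table(f2))), 1)
  # grouped corpus: no precursor straddles folds; union is everything
  sc <- small_corpus(20, seed = 5)
  ds <- build_training_set(sc$pres, sc$corpus$annotations, rpns = 5, seed = 5)
  f3 <- split_folds(ds, k = 5, seed = 7)
  expect_length(f3, nrow(ds$x))
  straddle <- tapply(f3, ds$groups, function(v) length(unique(v)))
  expect_true(all(straddle == 1))
  expect_error(split_folds(ds, k = 21), class = "mirlocate_too_few_samples")
})
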