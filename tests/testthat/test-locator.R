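test_that("candidate enumeration covers exactly the admissible intervals", {
  expect_equal(nrow(enumerate_candidates(15)), 0)
  e16 <- enumerate_candidates(16)
  expect_equal(nrow(e16), 1)
  expect_equal(c(e16$start, e16$length), c(1, 16))
  e30 <- enumerate_candidates(30)
  expect_equal(nrow(e30), sum(31 - 16:30))           # 120
  expect_true(all(e30$start + e30$length - 1 <= 30))
  expect_true(all(e30$length >= 16 & e30$length <= 30))
  # deterministic order: start ascending, then length
  expect_false(is.unsorted(e30$start))
})

test_that("locate performs the two-stage argmax with smallest-first ties", {
  g <- data.frame(start = 5, length = 20, score = 0.7)
  expect_equal(locate(g)[c("start", "length")], list(start = 5, length = 20))
  # hand-built 5x3 grid: argmax of column sums, then the best length
  set.seed(8)
  g <- expand.grid(start = 1:5, length = 16:18)
  g$score <- stats::runif(15)
  loc <- locate(g)
  ora <- oracle_locate(g)
  expect_equal(loc$start, ora$start)
  expect_equal(loc$length, ora$length)
  expect_equal(loc$summed_score, sum(g$score[g$start == ora$start]))
  # equal summed scores: the smaller start wins
  g2 <- data.frame(start = c(2, 7), length = c(16, 16), score = c(0.4, 0.4))
  expect_equal(locate(g2)$start, 2)
  expect_error(locate(g2[0, ]), class = "mirlocate_empty_grid")
})

test_that("score grids contain exactly the derivable candidates, scored in [0,1]", {
  sc <- small_corpus(10, seed = 31)
  ds <- build_training_set(sc$pres, sc$corpus$annotations, rpns = 3, seed = 2)
  m <- train(ds, "rf", params = list(ntree = 100), seed = 2)
  pre <- sc$pres[[1]]
  grid <- score_candidates(pre, m)
  expect_true(all(grid$score >= 0 & grid$score <= 1))
  cands <- enumerate_candidates(pre$n)
  derivable <- vapply(seq_len(nrow(cands)), function(i) {
    !is.null(tryCatch(
      derive_duplex(pre, c(cands$start[i], cands$start[i] + cands$length[i] - 1)),
      mirlocate_error = function(e) NULL))
  }, logical(1))
  expect_equal(nrow(grid), sum(derivable))
  expect_equal(attr(grid, "n_skipped"), sum(!derivable))
  expect_equal(grid$start, cands$start[derivable])
  expect_equal(grid$length, cands$length[derivable])
})

test_that("an unpairable precursor yields no prediction, with a reason", {
  sc <- small_corpus(10, seed = 31)
  ds <- build_training_set(sc$pres, sc$corpus$annotations, rpns = 3, seed = 2)
  m <- train(ds, "rf", params = list(ntree = 100), seed = 2)
  flat <- premirna("flat", strrep("A", 60), strrep(".", 60))
  p <- predict_mature(flat, m)
  expect_equal(p$status, "no_prediction")
  expect_match(p$reason, "duplex")
})

test_that("predictions are self-consistent and deterministic", {
  sc <- small_corpus(10, seed = 31)
  ds <- build_training_set(sc$pres, sc$corpus$annotations, rpns = 3, seed = 2)
  m <- train(ds, "rf", params = list(ntree = 100), seed = 2)
  pre <- sc$pres[[3]]
  p1 <- predict_mature(pre, m)
  expect_equal(p1$status, "ok")
  expect_gte(p1$length, 16); expect_lte(p1$length, 30)
  expect_equal(p1$mirna_seq, substr(pre$sequence, p1$start, p1$end))
  expect_equal(p1$passenger_seq,
               substr(pre$sequence, p1$passenger_start, p1$passenger_end))
  expect_identical(p1, predict_mature(pre, m))
})

test_that("resolution curves match direct offset enumeration", {
  truths <- data.frame(premirna_id = sprintf("p%02d", 1:10),
                       start = seq(10, 28, 2), end = seq(30, 48, 2))
  exact <- data.frame(premirna_id = truths$premirna_id,
                      start = truths$start, end = truths$end)
  res <- evaluate_resolution(exact, truths)
  expect_true(all(res$start_freq == 1) && all(res$end_freq == 1))
  one <- data.frame(premirna_id = "p01", start = truths$start[1] + 3,
                    end = truths$end[1])
  res1 <- evaluate_resolution(one, truths)
  expect_equal(res1$start_freq, c(0, 0, 0, rep(1, 8)))
  set.seed(12)
  mixed <- data.frame(premirna_id = truths$premirna_id,
                      start = truths$start + sample(-6:6, 10, TRUE),
                      end = truths$end + sample(-6:6, 10, TRUE))
  res2 <- evaluate_resolution(mixed, truths)
  for (d in 0:10) {
    expect_equal(res2$start_freq[d + 1],
                 mean(abs(mixed$start - truths$start) <= d))
    expect_equal(res2$end_freq[d + 1],
                 mean(abs(mixed$end - truths$end) <= d))
  }
  expect_false(is.unsorted(res2$start_freq))
  expect_false(is.unsorted(res2$end_freq))
  expect_error(evaluate_resolution(
    data.frame(premirna_id = "zz", start = 1, end = 20), truths),
    class = "mirlocate_missing_truth")
})
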