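# Independent oracles and deterministic fixtures used across the suite.

# Recursive memoized maximum-pairing count (canonical pairs, min loop 3).
# Independent of the package's iterative folder + traceback.
oracle_max_pairs <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < 4L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - 4L)) {
      if (pairable(chars[k], chars[j])) {
        v <- 1L + (if (k > i) rec(i, k - 1L) else 0L) + rec(k + 1L, j - 1L)
        if (v > best) best <- v
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < 5L) return(0L)
  rec(1L, n)
}

# All-pairs AUC: mean over (positive, negative) pairs of win/tie credit.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == "positive"]
  sn <- scores[labels != "positive"]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Exhaustive two-stage argmax over a score grid (start by summed score,
# then length), ties toward the smaller value.
oracle_locate <- function(grid) {
  S <- sapply(sort(unique(grid$start)), function(p)
    sum(grid$score[grid$start == p]))
  names(S) <- sort(unique(grid$start))
  p <- min(as.integer(names(S)[S == max(S)]))
  sub <- grid[grid$start == p, ]
  L <- min(sub$length[sub$score == max(sub$score)])
  list(start = p, length = L)
}

# Uniformly-ish random balanced dot-bracket string of length n.
random_dotbracket <- function(n) {
  out <- character(n)
  open <- 0L
  for (i in seq_len(n)) {
    left <- n - i            # positions remaining after this one
    choices <- c(if (left > open) "(", if (left >= open) ".",
                 if (open > 0L) ")")
    out[i] <- sample(choices, 1L)
    if (out[i] == "(") open <- open + 1L
    if (out[i] == ")") open <- open - 1L
  }
  paste(out, collapse = "")
}

revcomp <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Perfect hairpin: 22-bp stem, 4-nt loop (48 nt). Guide = the whole 5' arm.
fixture_perfect <- function() {
  arm <- "GCAUGGCAUCGAUGCAAGGCAU"   # 22 nt
  premirna("perfect", paste0(arm, "GAAA", revcomp(arm)),
           paste0(strrep("(", 22), "....", strrep(")", 22)))
}

# 59-nt hairpin with a single 1-nt bulge on the 5' arm at position 11:
# 10 bp | bulge | 15 bp | 8-nt loop | 15 bp | 10 bp.
fixture_bulged <- function() {
  a1 <- "GCGCAUGGCA"                # 10 nt, pairs 1..10 <-> 59..50
  a2 <- "UGCAGUCAGGCAAGG"          # 15 nt, pairs 12..26 <-> 49..35
  premirna("bulged",
           paste0(a1, "A", a2, "AAAAUUUU", revcomp(a2), revcomp(a1)),
           paste0(strrep("(", 10), ".", strrep("(", 15), strrep(".", 8),
                  strrep(")", 15), strrep(")", 10)))
}

# small folded synthetic corpus shared by several tests (cached per session)
.tcache <- new.env(parent = emptyenv())
small_corpus <- function(n = 20, seed = 5) {
  key <- paste0("c", n, "_", seed)
  if (is.null(.tcache[[key]])) {
    corpus <- simulate_corpus(n, seed = seed)
    .tcache[[key]] <- list(corpus = corpus, pres = fold(corpus$sequences))
  }
  .tcache[[key]]
}
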