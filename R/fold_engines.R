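#' Folding engines
#'
#' A folding engine turns an RNA sequence into a secondary structure. Two
#' engines ship with the package:
#'
#' * `"rnafold"` — wraps the `RNAfold` program of the ViennaRNA package
#'   (thermodynamic MFE folding; with `partition = TRUE` it also yields the
#'   base-pair probability matrix used by the positional-entropy features).
#' * `"maxpair"` — a bundled Nussinov-style maximum-base-pairing folder
#'   (minimum hairpin loop of 3). It is *not* thermodynamic: it exists so the
#'   full pipeline can run and be tested without an external folder, and its
#'   "mfe" is the negated pair count.
#'
#' `"none"` is a placeholder that errors on use (for workflows that supply
#' precomputed structures).
#'
#' @param name one of `"rnafold"`, `"maxpair"`, `"none"`.
#' @return an object of class `fold_engine` with capability flags
#'   `mfe_structure`, `partition_function`, `two_strand`.
#' @export
fold_engine <- function(name = c("rnafold", "maxpair", "none")) {
  name <- match.arg(name)
  eng <- switch(name,
    rnafold = list(name = "rnafold", version = rnafold_version(),
                   mfe_structure = TRUE, partition_function = TRUE,
                   two_strand = TRUE),
    maxpair = list(name = "maxpair", version = "builtin-1 (non-thermodynamic)",
                   mfe_structure = TRUE, partition_function = FALSE,
                   two_strand = FALSE),
    none = list(name = "none", version = NA_character_,
                mfe_structure = FALSE, partition_function = FALSE,
                two_strand = FALSE))
  structure(eng, class = "fold_engine")
}

engine_label <- function(engine) paste0(engine$name, "/", engine$version)

rnafold_available <- function() nzchar(Sys.which("RNAfold"))

rnafold_version <- function() {
  if (!rnafold_available()) return(NA_character_)
  out <- tryCatch(system2("RNAfold", "--version", stdout = TRUE, stderr = TRUE),
                  error = function(e) NA_character_)
  sub("^RNAfold\\s+", "", out[1])
}

#' Pick the best available folding engine
#'
#' `rnafold` when the ViennaRNA executables are on the PATH, otherwise the
#' bundled maximum-pairing folder.
#' @return a `fold_engine`.
#' @export
default_engine <- function() {
  if (rnafold_available()) fold_engine("rnafold") else fold_engine("maxpair")
}

#' Fold pre-miRNA sequences into hairpin structures
#'
#' @param sequences named character vector (names are record ids) or a single
#'   unnamed sequence.
#' @param engine a [fold_engine()]; default picks `rnafold` if available.
#' @param partition also compute base-pair probabilities (engines with the
#'   `partition_function` capability only).
#' @return a named list of [premirna()] objects.
#' @export
fold <- function(sequences, engine = default_engine(), partition = TRUE) {
  if (is.null(names(sequences))) {
    if (length(sequences) > 1L)
      ml_stop("multiple sequences require names", "mirlocate_duplicate_id")
    names(sequences) <- "seq1"
  }
  if (anyDuplicated(names(sequences)))
    ml_stop("duplicate sequence ids", "mirlocate_duplicate_id")
  sequences <- vapply(sequences, normalize_rna, character(1))
  if (any(nchar(sequences) < 10L))
    ml_stop("sequences must be at least 10 nt to fold",
            "mirlocate_invalid_params")
  if (engine$name == "none" || !engine$mfe_structure)
    ml_stop("no folding engine configured and no precomputed structures supplied",
            "mirlocate_engine_unavailable")
  if (engine$name == "rnafold") {
    if (!rnafold_available())
      ml_stop("RNAfold executable not found on PATH",
              "mirlocate_engine_unavailable")
    fold_rnafold(sequences, engine, partition)
  } else {
    lapply_named(sequences, function(id, s) fold_maxpair(id, s, engine))
  }
}

lapply_named <- function(x, f) {
  out <- lapply(seq_along(x), function(i) f(names(x)[i], x[[i]]))
  names(out) <- names(x)
  out
}

# --- RNAfold wrapper -------------------------------------------------------

fold_rnafold <- function(sequences, engine, partition) {
  dir <- tempfile("rnafold")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  # sanitized ids keep RNAfold's derived dot-plot filenames predictable
  safe <- sprintf("q%06d", seq_along(sequences))
  fa <- file.path(dir, "in.fa")
  writeLines(paste0(">", safe, "\n", sequences), fa)
  args <- c("--noPS", if (partition) "-p", "--infile", fa)
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE)
  out <- suppressWarnings(system2("RNAfold", args, stdout = TRUE, stderr = FALSE))
  if (!is.null(attr(out, "status")) && attr(out, "status") != 0L)
    ml_stop("RNAfold failed", "mirlocate_engine_unavailable")
  recs <- parse_rnafold_output(out)
  if (length(recs) != length(sequences))
    ml_stop("RNAfold returned an unexpected number of records",
            "mirlocate_engine_unavailable")
  out <- lapply(seq_along(sequences), function(i) {
    r <- recs[[safe[i]]]
    bppm <- NULL
    if (partition) {
      dp <- file.path(dir, paste0(safe[i], "_dp.ps"))
      if (file.exists(dp)) bppm <- parse_dotplot(dp, nchar(sequences[[i]]))
    }
    premirna(names(sequences)[i], sequences[[i]], r$structure, r$mfe,
             bppm = bppm, engine = engine_label(engine))
  })
  names(out) <- names(sequences)
  out
}

parse_rnafold_output <- function(lines) {
  idx <- grep("^>", lines)
  recs <- list()
  for (k in seq_along(idx)) {
    id <- sub("^>\\s*", "", lines[idx[k]])
    id <- sub("\\s.*$", "", id)
    struct_line <- lines[idx[k] + 2L]
    m <- regmatches(struct_line,
                    regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\)", struct_line))[[1]]
    if (length(m) != 3L)
      ml_stop("could not parse RNAfold structure line",
              "mirlocate_engine_unavailable")
    recs[[id]] <- list(structure = m[2], mfe = as.numeric(m[3]))
  }
  recs
}

# "i j sqrt(p) ubox" entries of a ViennaRNA dot plot -> dense bppm
parse_dotplot <- function(path, n) {
  lines <- readLines(path, warn = FALSE)
  ub <- grep("^[0-9]+ [0-9]+ [0-9.Ee+-]+ ubox$", lines, value = TRUE)
  m <- matrix(0, n, n)
  if (length(ub)) {
    f <- do.call(rbind, strsplit(ub, " ", fixed = TRUE))
    i <- as.integer(f[, 1]); j <- as.integer(f[, 2])
    p <- as.numeric(f[, 3])^2
    p <- pmin(p, 1)
    m[cbind(i, j)] <- p
    m[cbind(j, i)] <- p
  }
  # tame tiny numerical overshoot of row sums from the PS text roundtrip
  rs <- rowSums(m)
  over <- rs > 1
  if (any(over)) m[over, ] <- m[over, ] / rs[over]
  (m + t(m)) / 2
}

# --- bundled maximum-pairing (Nussinov) folder -----------------------------

# dynamic program maximizing canonical pair count, minimum hairpin loop 3;
# traceback prefers leaving j unpaired, then the smallest pairing partner k,
# making the reported structure deterministic.
nussinov_fold <- function(chars) {
  n <- length(chars)
  pt <- integer(n)
  if (n < 5L) return(pt)
  M <- matrix(0L, n, n)
  for (span in 4:(n - 1)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      ks <- i:(j - 4L)
      ks <- ks[can_pair(chars[ks], chars[j])]
      for (k in ks) {
        v <- 1L + (if (k > i) M[i, k - 1L] else 0L) +
          (if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L)
        if (v > best) best <- v
      }
      M[i, j] <- best
    }
  }
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i < 4L) next
    if (M[i, j] == M[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - 4L)) {
      if (!can_pair(chars[k], chars[j])) next
      v <- 1L + (if (k > i) M[i, k - 1L] else 0L) +
        (if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L)
      if (v == M[i, j]) {
        pt[k] <- j; pt[j] <- k
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  pt
}

fold_maxpair <- function(id, s, engine) {
  pt <- nussinov_fold(seq_chars(s))
  premirna(id, s, serialize_pair_table(pt),
           mfe = -sum(pt > 0) / 2,
           engine = engine_label(engine))
}

# --- precomputed structures ------------------------------------------------

#' Read Vienna dot-bracket records
#'
#' Accepts the `RNAfold`-style format: `>id`, sequence line, structure line
#' with an optional trailing `(mfe)`.
#'
#' @param path file path.
#' @return named list of [premirna()] objects (no base-pair probabilities;
#'   entropy features fall back to the point-mass matrix).
#' @export
read_vienna <- function(path) {
  lines <- grep("^#", readLines(path, warn = FALSE), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  idx <- grep("^>", lines)
  if (!length(idx)) ml_stop("no records in structure file", "mirlocate_data_error")
  out <- list()
  for (k in idx) {
    id <- sub("\\s.*$", "", sub("^>\\s*", "", lines[k]))
    if (id %in% names(out)) ml_stop(paste("duplicate id", id), "mirlocate_duplicate_id")
    struct_line <- lines[k + 2L]
    m <- regmatches(struct_line,
                    regexec("^([().]+)(\\s+\\(\\s*(-?[0-9.]+)\\))?", struct_line))[[1]]
    mfe <- if (nzchar(m[4] %||% "")) as.numeric(m[4]) else NA_real_
    out[[id]] <- premirna(id, lines[k + 1L], m[2], mfe,
                          engine = "precomputed")
  }
  out
}
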