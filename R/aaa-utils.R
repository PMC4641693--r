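# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

RNA_BASES <- c("A", "C", "G", "U")

ml_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mirlocate_error")))
}

ml_warn <- function(msg, class = "mirlocate_warning") {
  warning(warningCondition(msg, class = c(class, "mirlocate_warning")))
}

#' Normalize a nucleotide sequence to uppercase RNA
#'
#' Uppercases, converts T to U, and validates the alphabet (A, C, G, U, N).
#'
#' @param x character scalar, DNA or RNA sequence.
#' @return character scalar over `{A,C,G,U,N}`.
#' @export
normalize_rna <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  if (grepl("[^ACGUN]", x))
    ml_stop(sprintf("invalid character in sequence (allowed A,C,G,T,U,N): %s",
                    substr(gsub("[ACGUN]", "", x), 1, 5)),
            "mirlocate_invalid_character")
  x
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

complement_rna <- function(chars) unname(RNA_COMPLEMENT[chars])

revcomp_rna <- function(x) paste(rev(complement_rna(seq_chars(x))), collapse = "")

# TRUE/FALSE: can bases a and b form a canonical pair (Watson-Crick or wobble)?
can_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G") |
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

# run-length starts/lengths of TRUE stretches in a logical vector
true_runs <- function(x) {
  if (!length(x)) return(list(start = integer(), length = integer()))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], length = r$lengths[keep])
}
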