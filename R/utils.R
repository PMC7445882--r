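DNA_BASES <- c("A", "C", "G", "T")

# pileup symbol order used everywhere: 4 bases + deletion
PILEUP_SYMBOLS <- c("A", "C", "G", "T", "-")

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

assert_dna <- function(x, what = "sequence") {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop(what, " must contain only A/C/G/T: ", x[which(bad)[1]], call. = FALSE)
  }
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`
# (global .Random.seed restored afterwards). seed = NULL runs as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Phred quality character for a per-base error probability.
phred_char <- function(e) {
  q <- round(-10 * log10(max(e, 1e-4)))
  intToUtf8(min(q, 41L) + 33L)
}

# Row-major 96-well labels A1..H12 (A1, A2, ..., A12, B1, ...).
well_labels <- function(n) {
  if (n > 96) stop("more than 96 well positions requested (", n, ")")
  row <- (seq_len(n) - 1L) %/% 12L + 1L
  col <- (seq_len(n) - 1L) %% 12L + 1L
  paste0(LETTERS[row], col)
}

sample_name <- function(plate, well) sprintf("plate%d_%s", as.integer(plate), well)
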