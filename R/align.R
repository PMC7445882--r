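#' Align a read to a target with a banded ends-free aligner
#'
#' Banded semi-global alignment with affine gap penalties and free end gaps
#' (leading/trailing gaps in either sequence are unpenalised), suited to
#' full-length amplicon reads against their template. A gap of length k
#' costs `gap_open + k * gap_ext`. If the optimal path touches the band
#' boundary the band is doubled automatically (up to 4x the initial value),
#' then an error is raised.
#'
#' @param read_seq read sequence, already in target orientation.
#' @param target target sequence.
#' @param band_width half-width of the band around the main diagonal;
#'   default `|len(read) - len(target)|` plus `max(30, 5%` of the target`)`.
#' @param strand strand label recorded in the alignment (`"forward"` or
#'   `"reverse"`); from demux orientation.
#' @param match,mismatch,gap_open,gap_ext scoring scheme (defaults +2/-3/-4/-2,
#'   a standard long-read-tolerant semi-global scheme).
#' @return object of class `amplicon_alignment`: list with `score`, `strand`,
#'   `read` and `ops` (data.frame `op` in `M`/`D`/`I`, 0-based `tpos`,
#'   `rpos`; insertions carry the preceding target position, -1 at the
#'   start). Target positions are strictly increasing across `M`/`D` ops.
#' @export
align_read <- function(read_seq, target, band_width = NULL,
                       strand = "forward", match = 2, mismatch = -3,
                       gap_open = -4, gap_ext = -2) {
  if (!nzchar(read_seq) || !nzchar(target)) {
    stop("read and target must be non-empty")
  }
  n1 <- nchar(target); n2 <- nchar(read_seq)
  if (is.null(band_width)) {
    band_width <- max(30L, ceiling(0.05 * max(n1, n2)))
  }
  band0 <- as.integer(band_width)
  band <- band0
  repeat {
    res <- .banded_align(target, read_seq, as.integer(match),
                         as.integer(mismatch), as.integer(gap_open),
                         as.integer(gap_ext), band)
    if (!res$touched) break
    if (band >= 4L * band0) {
      stop("alignment band too narrow even after widening to 4x (",
           band, " nt); raise band_width")
    }
    band <- min(band * 2L, 4L * band0)
  }
  structure(list(score = res$score, strand = strand, read = read_seq,
                 ops = data.frame(op = c("M", "D", "I")[res$op + 1L],
                                  tpos = res$ti, rpos = res$ri,
                                  stringsAsFactors = FALSE)),
            class = "amplicon_alignment")
}

#' Identify the target a read derives from
#'
#' Aligns the read against every supplied target in both orientations and
#' returns the best-scoring target with its score margin over the runner-up.
#' A single target yields margin `Inf`; a zero margin sets the ambiguous
#' flag.
#'
#' @param read_seq read sequence.
#' @param targets named character vector of target sequences.
#' @param ... passed to [align_read()].
#' @return list: `target_id`, `score`, `margin`, `ambiguous`, `orientation`.
#' @export
identify_target <- function(read_seq, targets, ...) {
  stopifnot(length(targets) >= 1)
  if (is.null(names(targets))) {
    names(targets) <- paste0("target", seq_along(targets))
  }
  rc <- revcomp(read_seq)
  scores <- vapply(targets, function(t) {
    c(forward = align_read(read_seq, t, ...)$score,
      reverse = align_read(rc, t, ...)$score)
  }, numeric(2))
  best_per_target <- apply(scores, 2, max)
  i <- which.max(best_per_target)
  margin <- if (length(targets) == 1) Inf else
    best_per_target[i] - max(best_per_target[-i])
  list(target_id = names(targets)[i],
       score = unname(best_per_target[i]),
       margin = unname(margin),
       ambiguous = is.finite(margin) && margin == 0,
       orientation = rownames(scores)[which.max(scores[, i])])
}

#' Empty strand-separated pileup for a target
#'
#' @param target target sequence.
#' @param target_id contig name.
#' @return object of class `strand_pileup`: list with `target_id`, `ref`
#'   (character vector of target bases), `counts` (array
#'   `length x {fwd,rev} x {A,C,G,T,-}`) and `insertions` (data.frame
#'   `tpos` 0-based preceding target position, `seq`, `strand`, `count`).
#' @export
new_strand_pileup <- function(target, target_id = "target") {
  ref <- strsplit(target, "", fixed = TRUE)[[1]]
  L <- length(ref)
  counts <- array(0L, dim = c(L, 2L, 5L),
                  dimnames = list(NULL, c("fwd", "rev"), PILEUP_SYMBOLS))
  structure(list(target_id = target_id, ref = ref, counts = counts,
                 insertions = data.frame(tpos = integer(0),
                                         seq = character(0),
                                         strand = character(0),
                                         count = integer(0),
                                         stringsAsFactors = FALSE)),
            class = "strand_pileup")
}

#' Accumulate alignments into a strand-separated pileup
#'
#' Each aligned read base increments the count of its base at its target
#' position on its read's strand; read deletions increment the `-` symbol;
#' read insertions are recorded separately, keyed by the preceding target
#' position. Input order of reads does not affect the result.
#'
#' @param alignments list of `amplicon_alignment` objects (all against this
#'   target).
#' @param target target sequence.
#' @param target_id contig name.
#' @return a `strand_pileup`.
#' @export
build_pileup <- function(alignments, target, target_id = "target") {
  pu <- new_strand_pileup(target, target_id)
  L <- length(pu$ref)
  ins_acc <- list()
  lin <- vector("list", length(alignments))  # linear indices into counts
  for (a in seq_along(alignments)) {
    aln <- alignments[[a]]
    ops <- aln$ops
    if (any(ops$tpos >= L | (ops$op != "I" & ops$tpos < 0))) {
      stop("alignment references positions outside the target")
    }
    si <- if (aln$strand == "forward") 1L else 2L
    rch <- strsplit(aln$read, "", fixed = TRUE)[[1]]
    m <- ops$op == "M"
    d <- ops$op == "D"
    bi <- integer(0)
    if (any(m)) bi <- match(rch[ops$rpos[m] + 1L], PILEUP_SYMBOLS)
    # counts array is L x 2 x 5: linear index pos + (s-1)*L + (b-1)*2L
    lin[[a]] <- c(ops$tpos[m] + 1L + (si - 1L) * L + (bi - 1L) * 2L * L,
                  ops$tpos[d] + 1L + (si - 1L) * L + 4L * 2L * L)
    # merge consecutive insertion ops into one inserted sequence
    iidx <- which(ops$op == "I")
    if (length(iidx)) {
      grp <- cumsum(c(TRUE, diff(iidx) != 1))
      for (g in split(iidx, grp)) {
        key <- paste(ops$tpos[g[1]],
                     paste(rch[ops$rpos[g] + 1L], collapse = ""),
                     aln$strand, sep = "\r")
        ins_acc[[key]] <- (ins_acc[[key]] %||% 0L) + 1L
      }
    }
  }
  if (length(alignments)) {
    tab <- tabulate(unlist(lin), nbins = 10L * L)
    pu$counts <- array(as.integer(tab), dim = dim(pu$counts),
                       dimnames = dimnames(pu$counts))
  }
  if (length(ins_acc)) {
    parts <- strsplit(names(ins_acc), "\r", fixed = TRUE)
    pu$insertions <- data.frame(
      tpos = as.integer(vapply(parts, `[`, character(1), 1)),
      seq = vapply(parts, `[`, character(1), 2),
      strand = vapply(parts, `[`, character(1), 3),
      count = as.integer(unlist(ins_acc)),
      stringsAsFactors = FALSE)
    pu$insertions <-
      pu$insertions[order(pu$insertions$tpos, pu$insertions$seq,
                          pu$insertions$strand), , drop = FALSE]
    rownames(pu$insertions) <- NULL
  }
  pu
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-position per-strand depth of a pileup
#'
#' @param pileup a `strand_pileup`.
#' @return matrix `length x 2` (`fwd`, `rev`) of depths (base counts plus
#'   deletions).
#' @export
pileup_depth <- function(pileup) {
  apply(pileup$counts, c(1, 2), sum)
}

#' Import alignments from a SAM file into a pileup
#'
#' Walks CIGAR strings of primary alignments (FLAG bits 0x4, 0x100, 0x800
#' skipped); FLAG bit 0x10 sets the reverse strand. Records with missing or
#' invalid CIGAR are skipped; their count is reported as a warning and in
#' the `n_skipped` attribute.
#'
#' @param sam_path SAM file path.
#' @param target target sequence (or a targets FASTA path with a single
#'   contig).
#' @param target_id reference name to import (default: first RNAME seen).
#' @return a `strand_pileup`.
#' @export
import_sam <- function(sam_path, target, target_id = NULL) {
  if (nchar(target) < 500 && !grepl("^[ACGT]+$", target) &&
      file.exists(target)) {
    tg <- read_targets(target)
    if (is.null(target_id)) target_id <- names(tg)[1]
    target <- unname(tg[target_id])
  }
  lines <- readLines(sam_path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  pu <- new_strand_pileup(target, target_id %||% "target")
  L <- length(pu$ref)
  skipped <- 0L
  ins_acc <- list()
  for (ln in lines) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) { skipped <- skipped + 1L; next }
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) { skipped <- skipped + 1L; next }
    if (bitwAnd(flag, 4L) > 0) next                     # unmapped
    if (bitwAnd(flag, 256L) > 0 || bitwAnd(flag, 2048L) > 0) next
    if (!is.null(target_id) && f[3] != target_id && f[3] != "*") next
    cigar <- f[6]; seq <- toupper(f[10])
    pos <- suppressWarnings(as.integer(f[4]))
    if (cigar == "*" || is.na(pos) ||
        !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
      skipped <- skipped + 1L
      next
    }
    si <- if (bitwAnd(flag, 16L) > 0) 2L else 1L
    strand <- c("fwd", "rev")[si]
    lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
    ti <- pos - 1L   # 0-based target cursor
    ri <- 0L         # 0-based read cursor
    bad <- FALSE
    for (k in seq_along(ops)) {
      n <- lens[k]
      if (ops[k] %in% c("M", "=", "X")) {
        if (ti + n > L) { bad <- TRUE; break }
        b <- match(substring(seq, ri + seq_len(n), ri + seq_len(n)),
                   PILEUP_SYMBOLS)
        for (t in seq_len(n)) {
          if (!is.na(b[t])) {
            pu$counts[ti + t, si, b[t]] <- pu$counts[ti + t, si, b[t]] + 1L
          }
        }
        ti <- ti + n; ri <- ri + n
      } else if (ops[k] %in% c("D", "N")) {
        if (ti + n > L) { bad <- TRUE; break }
        for (t in seq_len(n)) {
          pu$counts[ti + t, si, 5L] <- pu$counts[ti + t, si, 5L] + 1L
        }
        ti <- ti + n
      } else if (ops[k] == "I") {
        key <- paste(ti - 1L, substring(seq, ri + 1L, ri + n),
                     c("forward", "reverse")[si], sep = "\r")
        ins_acc[[key]] <- (ins_acc[[key]] %||% 0L) + 1L
        ri <- ri + n
      } else if (ops[k] == "S") {
        ri <- ri + n
      }                                               # H/P consume nothing
    }
    if (bad) skipped <- skipped + 1L
  }
  if (length(ins_acc)) {
    parts <- strsplit(names(ins_acc), "\r", fixed = TRUE)
    pu$insertions <- data.frame(
      tpos = as.integer(vapply(parts, `[`, character(1), 1)),
      seq = vapply(parts, `[`, character(1), 2),
      strand = vapply(parts, `[`, character(1), 3),
      count = as.integer(unlist(ins_acc)), stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    warning(skipped, " SAM record(s) skipped (missing/invalid fields)")
  }
  attr(pu, "n_skipped") <- skipped
  pu
}

#' Serialize / load a strand pileup as TSV
#'
#' Columns: `pos` (1-based), `ref`, then per-strand base counts
#' `A_f C_f G_f T_f DEL_f A_r C_r G_r T_r DEL_r`. Insertion records travel
#' in a companion TSV when `insertions_path` is given.
#'
#' @param pileup a `strand_pileup`.
#' @param path output TSV.
#' @param insertions_path optional TSV for insertion records.
#' @export
write_pileup <- function(pileup, path, insertions_path = NULL) {
  cn <- c(paste0(c("A", "C", "G", "T", "DEL"), "_f"),
          paste0(c("A", "C", "G", "T", "DEL"), "_r"))
  m <- cbind(pileup$counts[, 1, ], pileup$counts[, 2, ])
  colnames(m) <- cn
  df <- data.frame(pos = seq_along(pileup$ref), ref = pileup$ref, m,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(insertions_path)) {
    write.table(pileup$insertions, insertions_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_pileup
#' @param target_id contig name for the loaded pileup.
#' @export
read_pileup <- function(path, insertions_path = NULL, target_id = "target") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  pu <- new_strand_pileup(paste(df$ref, collapse = ""), target_id)
  for (i in 1:5) {
    pu$counts[, 1, i] <- df[[paste0(c("A", "C", "G", "T", "DEL")[i], "_f")]]
    pu$counts[, 2, i] <- df[[paste0(c("A", "C", "G", "T", "DEL")[i], "_r")]]
  }
  if (!is.null(insertions_path) && file.exists(insertions_path)) {
    ins <- read.delim(insertions_path, stringsAsFactors = FALSE)
    if (nrow(ins)) pu$insertions <- ins
  }
  pu
}
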