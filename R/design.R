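#' Generate candidate barcode sequences
#'
#' Draws random DNA barcodes of fixed length, keeping only sequences within
#' the GC bounds, until `n` distinct candidates are obtained. Each candidate
#' is scored for secondary-structure propensity with [score_structure()].
#'
#' @param n number of candidates (the reference workflow drew 500).
#' @param length barcode length in nt; must be >= 8 so that error-tolerant
#'   matching retains discriminative power. Default 24.
#' @param seed integer seed; fixed seed gives identical candidates.
#' @param gc_min,gc_max GC-content bounds applied to candidates (standard
#'   primer practice; default 0.30-0.70).
#' @return data.frame with columns `sequence`, `delta_g_score`, `role` (NA
#'   until selection), one row per candidate.
#' @export
generate_candidates <- function(n, length = 24, seed = NULL,
                                gc_min = 0.3, gc_max = 0.7) {
  n <- as.integer(n)
  length <- as.integer(length)
  if (n < 1) stop("n must be >= 1")
  if (length < 8) stop("barcode length must be >= 8 nt")
  if (length <= 15 && 4^length < n) {
    stop("cannot produce ", n, " distinct sequences of length ", length,
         " (only ", 4^length, " exist)")
  }
  seqs <- with_seed(seed, {
    out <- character(0)
    attempts <- 0L
    while (base::length(out) < n) {
      attempts <- attempts + 1L
      if (attempts > 2000L) {
        stop("failed to generate ", n, " distinct candidates of length ",
             length, " within GC bounds; got ", base::length(out))
      }
      m <- max(n - base::length(out), 16L)
      draw <- vapply(seq_len(m * 2L), function(i) {
        paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
      }, character(1))
      gc <- (nchar(gsub("[AT]", "", draw))) / length
      draw <- draw[gc >= gc_min & gc <= gc_max]
      out <- unique(c(out, draw))
    }
    out[seq_len(n)]
  })
  data.frame(sequence = seqs,
             delta_g_score = vapply(seqs, score_structure, numeric(1),
                                    USE.NAMES = FALSE),
             role = NA_character_,
             stringsAsFactors = FALSE)
}

#' Score secondary-structure propensity of a DNA sequence
#'
#' Proxy for a nearest-neighbour folding free energy: enumerates maximal
#' self-complementary stems (a pair of non-overlapping substrings, one the
#' reverse complement of the other) of length >= `min_stem` and scores
#' `-2 * stem_length` per stem, with an additional `-3` for any stem that
#' involves a terminal base of the sequence (terminal stems are the most
#' dangerous for primer dimers; the penalty is applied at either terminus so
#' that the score is invariant under reverse complement). A sequence with no
#' stem scores 0; more negative means more structure.
#'
#' @param sequence DNA string (A/C/G/T only).
#' @param min_stem minimum stem length counted (default 4).
#' @return numeric score, 0 or negative.
#' @export
#' @examples
#' score_structure(strrep("A", 24))   # 0: no self-complementarity
score_structure <- function(sequence, min_stem = 4) {
  if (length(sequence) != 1L) {
    return(vapply(sequence, score_structure, numeric(1),
                  min_stem = min_stem, USE.NAMES = FALSE))
  }
  assert_dna(sequence, "barcode")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(ch)
  comp <- chartr("ACGT", "TGCA", ch)
  score <- 0
  # pairs (u, v), u < v, on anti-diagonals c = u + v; a stem is a maximal
  # run of complementary pairs moving inward along one anti-diagonal.
  for (cc in 3:(2 * L - 1)) {
    u_min <- max(1L, cc - L)
    u_max <- (cc - 1L) %/% 2L        # enforces u < v
    if (u_max < u_min) next
    run <- 0L
    for (u in u_min:u_max) {
      v <- cc - u
      if (ch[u] == comp[v]) {
        run <- run + 1L
      } else {
        if (run >= min_stem) score <- score + stem_score(cc, u - 1L, run, L)
        run <- 0L
      }
    }
    if (run >= min_stem) score <- score + stem_score(cc, u_max, run, L)
  }
  score
}

# score one maximal stem: run of `k` pairs on anti-diagonal `cc` whose
# innermost pair has u = u_last (1-based); outermost pair (u_last-k+1, ...).
stem_score <- function(cc, u_last, k, L) {
  u0 <- u_last - k + 1L
  v0 <- cc - u0
  s <- -2 * k
  if (u0 == 1L || v0 == L) s <- s - 3
  s
}

#' Rank candidates and select forward/reverse barcode sets
#'
#' Candidates are ranked by descending structure score (least secondary
#' structure first; ties broken lexicographically by sequence) and selected
#' greedily under a pairwise Levenshtein-distance constraint: every selected
#' barcode must be at least `min_pairwise_edit` edits from every other
#' selected barcode (across both sets). Following the reference workflow the
#' best-ranked sequences fill the reverse (well) set first, then the forward
#' (plate) set.
#'
#' @param candidates data.frame from [generate_candidates()] (or a character
#'   vector of sequences).
#' @param n_forward,n_reverse set sizes (the reference design uses 6 plate
#'   and 96 well barcodes).
#' @param min_pairwise_edit minimum pairwise edit distance between any two
#'   selected barcodes (default 8 of 24; required for unambiguous
#'   error-tolerant demultiplexing at nanopore error rates).
#' @return list with data.frames `forward` and `reverse` (columns as in
#'   [generate_candidates()], `role` filled in).
#' @export
rank_and_select <- function(candidates, n_forward, n_reverse,
                            min_pairwise_edit = 8) {
  if (is.character(candidates)) {
    candidates <- data.frame(
      sequence = candidates,
      delta_g_score = vapply(candidates, score_structure, numeric(1),
                             USE.NAMES = FALSE),
      role = NA_character_, stringsAsFactors = FALSE)
  }
  ord <- order(-candidates$delta_g_score, candidates$sequence)
  ranked <- candidates[ord, , drop = FALSE]
  need <- n_forward + n_reverse
  kept <- character(0)
  for (s in ranked$sequence) {
    if (length(kept) == need) break
    if (length(kept) == 0 || all(adist(s, kept) >= min_pairwise_edit)) {
      kept <- c(kept, s)
    }
  }
  if (length(kept) < need) {
    stop("insufficient candidates after pairwise-distance filtering: ",
         "needed ", need, " barcodes, found ", length(kept),
         " (shortfall ", need - length(kept), "); supply more candidates ",
         "or lower min_pairwise_edit")
  }
  rev_seq <- kept[seq_len(n_reverse)]
  fwd_seq <- kept[n_reverse + seq_len(n_forward)]
  mk <- function(seqs, role) {
    i <- match(seqs, ranked$sequence)
    out <- ranked[i, , drop = FALSE]
    out$role <- role
    rownames(out) <- NULL
    out
  }
  list(forward = mk(fwd_seq, "forward"), reverse = mk(rev_seq, "reverse"))
}

#' Allocate forward x reverse primer pairs to plates and wells
#'
#' Every forward (plate) barcode is combined with every reverse (well)
#' barcode: the forward barcode is constant within a plate and the reverse
#' barcode is constant for a well position across plates, so 6 x 96 barcodes
#' give 576 unique pair combinations. Primer sequence = barcode followed by
#' the universal binding site. Well labels are row-major A1..H12.
#'
#' @param forward,reverse data.frames (or character vectors) of barcodes.
#' @param binding_fwd,binding_rev universal primer binding sites (non-empty
#'   DNA strings); user-supplied, vector-family specific.
#' @return data.frame with columns `plate_index`, `well_label`,
#'   `fwd_barcode`, `rev_barcode`, `fwd_primer`, `rev_primer`.
#' @export
allocate_pairs <- function(forward, reverse, binding_fwd, binding_rev) {
  fwd <- if (is.data.frame(forward)) forward$sequence else forward
  rev <- if (is.data.frame(reverse)) reverse$sequence else reverse
  if (!nzchar(binding_fwd) || !nzchar(binding_rev)) {
    stop("universal binding sites must be non-empty")
  }
  assert_dna(c(fwd, rev, binding_fwd, binding_rev), "primer component")
  if (anyDuplicated(c(fwd, rev))) stop("barcodes must be unique across sets")
  wl <- well_labels(length(rev))
  grid <- expand.grid(w = seq_along(rev), p = seq_along(fwd))
  data.frame(
    plate_index = grid$p,
    well_label = wl[grid$w],
    fwd_barcode = fwd[grid$p],
    rev_barcode = rev[grid$w],
    fwd_primer = paste0(fwd[grid$p], binding_fwd),
    rev_primer = paste0(rev[grid$w], binding_rev),
    stringsAsFactors = FALSE)
}

#' Write / read the primer sheet (barcode map)
#'
#' Tab-separated sheet with columns plate, well, fwd_barcode, rev_barcode,
#' fwd_primer, rev_primer; consumed by the demultiplexer.
#'
#' @param pairs data.frame from [allocate_pairs()].
#' @param path output TSV path.
#' @export
write_primer_sheet <- function(pairs, path) {
  out <- data.frame(plate = pairs$plate_index, well = pairs$well_label,
                    fwd_barcode = pairs$fwd_barcode,
                    rev_barcode = pairs$rev_barcode,
                    fwd_primer = pairs$fwd_primer,
                    rev_primer = pairs$rev_primer)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_primer_sheet
#' @export
read_barcode_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "plate"] <- "plate_index"
  names(df)[names(df) == "well"] <- "well_label"
  df
}

#' Export primers as FASTA
#'
#' @param pairs data.frame from [allocate_pairs()].
#' @param path output FASTA path.
#' @export
primers_to_fasta <- function(pairs, path) {
  seqs <- c(setNames(unique(pairs$fwd_primer),
                     paste0("plate", unique(pairs$plate_index), "_fwd")),
            setNames(pairs$rev_primer[!duplicated(pairs$well_label)],
                     paste0("well", unique(pairs$well_label), "_rev")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
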