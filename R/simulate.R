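#' Nanopore-like error model
#'
#' Flat per-base substitution/insertion/deletion rates. The total is capped
#' at 0.30, a sanity bound around the 5-15% single-pass error typical of
#' nanopore data.
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities in `[0, 1)`.
#' @param seed integer seed used by [simulate_reads()].
#' @return list of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.07, ins_rate = 0.015, del_rate = 0.015,
                        seed = NULL) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must be in [0, 1)")
  if (sum(rates) > 0.3) {
    stop("total error rate ", sum(rates), " exceeds sanity bound 0.3")
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, seed = seed),
            class = "error_model")
}

#' Strand-specific systematic error site
#'
#' Models a sequence-context miscall (indistinguishable conductance signal
#' or motor-enzyme processing error) that affects reads from one strand
#' only, at a fixed rate.
#'
#' @param position 0-based template coordinate.
#' @param strand `"forward"` or `"reverse"`: the strand whose reads carry
#'   the error.
#' @param alt_base miscalled base (A/C/G/T) or `"-"` for a deletion; stated
#'   in template (top-strand) coordinates.
#' @param rate probability in `(0, 1]` that an affected-strand read shows
#'   the error.
#' @return list of class `systematic_site`.
#' @export
systematic_site <- function(position, strand, alt_base, rate) {
  stopifnot(strand %in% c("forward", "reverse"),
            alt_base %in% PILEUP_SYMBOLS, rate > 0, rate <= 1, position >= 0)
  structure(list(position = as.integer(position), strand = strand,
                 alt_base = alt_base, rate = rate),
            class = "systematic_site")
}

#' True variant (ground-truth mutation) in a template
#'
#' @param position 0-based template coordinate.
#' @param alt_base variant base (A/C/G/T) or `"-"` for a deletion.
#' @return list of class `true_variant`.
#' @export
true_variant <- function(position, alt_base) {
  stopifnot(alt_base %in% PILEUP_SYMBOLS, position >= 0)
  structure(list(position = as.integer(position), alt_base = alt_base),
            class = "true_variant")
}

#' Build a barcoded amplicon from a template and a primer pair
#'
#' PCR with barcoded primers yields
#' `fwd_primer + template + reverse_complement(rev_primer)` on the top
#' strand.
#'
#' @param template insert DNA string.
#' @param pair a row of the primer sheet (needs `fwd_primer`/`rev_primer`),
#'   or `NULL` for a bare template.
#' @return amplicon top-strand DNA string.
#' @export
build_amplicon <- function(template, pair = NULL) {
  if (!nzchar(template)) stop("template must be non-empty")
  if (is.null(pair)) return(template)
  fp <- as.character(pair$fwd_primer)
  rp <- as.character(pair$rev_primer)
  paste0(fp, template, revcomp(rp))
}

#' Simulate nanopore-like reads from a barcoded amplicon
#'
#' True variants are applied to the template (hence to both strands) before
#' any error injection; systematic sites fire at their stated rate on reads
#' of their stated strand only; random substitutions/insertions/deletions
#' are applied i.i.d. per base. Reverse-strand reads are emitted as reverse
#' complements. Fully deterministic for a fixed seed.
#'
#' @param template insert DNA string (site/variant positions are 0-based
#'   template coordinates).
#' @param pair primer-sheet row used to build the amplicon, or `NULL`.
#' @param n_fwd,n_rev number of forward-/reverse-strand reads (exact counts,
#'   for depth control).
#' @param model an [error_model()].
#' @param sites list of [systematic_site()] objects.
#' @param variants list of [true_variant()] objects.
#' @param id_prefix prefix for read ids; ids encode the true strand for test
#'   assertions.
#' @return data.frame with columns `id`, `seq`, `qual` and attribute
#'   `truth` (data.frame: read id, true strand, sample prefix).
#' @export
simulate_reads <- function(template, pair = NULL, n_fwd = 1, n_rev = 1,
                           model = error_model(), sites = list(),
                           variants = list(), id_prefix = "read") {
  assert_dna(template, "template")
  L_t <- nchar(template)
  for (v in variants) {
    if (v$position >= L_t) stop("variant position ", v$position,
                                " outside template (length ", L_t, ")")
    if (substr(template, v$position + 1, v$position + 1) == v$alt_base) {
      stop("variant alt_base equals template base at ", v$position)
    }
  }
  for (s in sites) {
    if (s$position >= L_t) stop("systematic site position ", s$position,
                                " outside template (length ", L_t, ")")
    if (substr(template, s$position + 1, s$position + 1) == s$alt_base) {
      stop("site alt_base equals template base at ", s$position)
    }
  }
  # template with true variants applied (deletions marked for removal)
  tch <- strsplit(template, "", fixed = TRUE)[[1]]
  tdel <- rep(FALSE, L_t)
  for (v in variants) {
    if (v$alt_base == "-") tdel[v$position + 1] <- TRUE
    else tch[v$position + 1] <- v$alt_base
  }
  offset <- if (is.null(pair)) 0L else nchar(as.character(pair$fwd_primer))
  amp_pre <- if (is.null(pair)) character(0) else
    strsplit(as.character(pair$fwd_primer), "", fixed = TRUE)[[1]]
  amp_post <- if (is.null(pair)) character(0) else
    strsplit(revcomp(as.character(pair$rev_primer)), "", fixed = TRUE)[[1]]
  base_ch <- c(amp_pre, tch, amp_post)
  base_del <- c(rep(FALSE, length(amp_pre)), tdel, rep(FALSE, length(amp_post)))
  L <- length(base_ch)
  qch <- phred_char(model$sub_rate + model$ins_rate + model$del_rate)

  others <- lapply(setNames(DNA_BASES, DNA_BASES),
                   function(b) setdiff(DNA_BASES, b))

  one_read <- function(strand) {
    ch <- base_ch
    del <- base_del
    for (s in sites) {
      if (s$strand == strand && runif(1) < s$rate) {
        p <- s$position + offset + 1L
        if (s$alt_base == "-") del[p] <- TRUE else ch[p] <- s$alt_base
      }
    }
    u <- runif(L)
    sub_i <- which(u < model$sub_rate & !del)
    if (length(sub_i)) {
      pick <- sample.int(3L, length(sub_i), replace = TRUE)
      ch[sub_i] <- vapply(seq_along(sub_i),
                          function(k) others[[ch[sub_i[k]]]][pick[k]],
                          character(1))
    }
    del <- del | (runif(L) < model$del_rate)
    ins_i <- which(runif(L) < model$ins_rate)
    piece <- ch
    piece[del] <- ""
    if (length(ins_i)) {
      piece[ins_i] <- paste0(piece[ins_i],
                             DNA_BASES[sample.int(4L, length(ins_i),
                                                  replace = TRUE)])
    }
    s <- paste(piece, collapse = "")
    if (strand == "reverse") s <- revcomp(s)
    s
  }

  with_seed(model$seed, {
    strands <- c(rep("forward", n_fwd), rep("reverse", n_rev))
    seqs <- vapply(strands, one_read, character(1), USE.NAMES = FALSE)
    ids <- sprintf("%s_%05d_%s", id_prefix, seq_along(strands),
                   ifelse(strands == "forward", "fwd", "rev"))
    reads <- data.frame(id = ids, seq = seqs,
                        qual = vapply(seqs, function(s)
                          strrep(qch, nchar(s)), character(1),
                          USE.NAMES = FALSE),
                        stringsAsFactors = FALSE)
    attr(reads, "truth") <- data.frame(id = ids, strand = strands,
                                       sample = id_prefix,
                                       stringsAsFactors = FALSE)
    reads
  })
}

#' Write ground-truth sidecar JSON for a simulated read set
#'
#' @param reads data.frame from [simulate_reads()] (or several rbind-ed,
#'   with `truth` supplied explicitly).
#' @param path output JSON path.
#' @param variants,sites the ground-truth variant/site lists.
#' @param truth optional truth data.frame overriding `attr(reads, "truth")`.
#' @export
write_truth_sidecar <- function(reads, path, variants = list(),
                                sites = list(), truth = NULL) {
  if (is.null(truth)) truth <- attr(reads, "truth")
  jsonlite::write_json(
    list(reads = truth,
         variants = lapply(variants, unclass),
         sites = lapply(sites, unclass)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
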