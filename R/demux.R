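#' Locate a barcode near one end of a read
#'
#' Semi-global (infix) alignment of the barcode against a terminal window of
#' the read: the minimal Levenshtein distance over all placements within the
#' window, plus the placement offset. Windows longer than the read are
#' truncated to the read (documented behaviour, not an error).
#'
#' @param read_seq read sequence.
#' @param barcode barcode sequence to locate (pass the reverse complement
#'   yourself when searching for the reverse barcode at the 3' end of a
#'   top-strand read).
#' @param window window size in nt at the chosen end.
#' @param end `"five_prime"` or `"three_prime"`.
#' @return list with `distance`, `offset` (0-based start of best placement
#'   in the read) and `match_end` (0-based exclusive end).
#' @export
locate_barcode <- function(read_seq, barcode, window = 60,
                           end = c("five_prime", "three_prime")) {
  end <- match.arg(end)
  if (window < nchar(barcode)) stop("window must be >= barcode length")
  n <- nchar(read_seq)
  w <- min(window, n)
  shift <- if (end == "five_prime") 0L else n - w
  text <- substr(read_seq, shift + 1L, shift + w)
  hit <- .infix_levenshtein(barcode, text)
  list(distance = hit$distance, offset = hit$offset + shift,
       match_end = hit$match_end + shift)
}

# distances of each barcode in `bcs` against the window at one end
.end_distances <- function(read_seq, bcs, window, end) {
  lapply(bcs, function(b) locate_barcode(read_seq, b, window, end))
}

#' Classify a read to a (plate, well) sample
#'
#' Tests both read orientations. For each orientation the best forward
#' (plate) barcode is sought in the 5' window and the best reverse (well)
#' barcode — as its reverse complement — in the 3' window. The read is
#' assigned to the sample with minimal combined distance iff both individual
#' distances are `<= max_dist` and the best combined distance beats the
#' runner-up combination (including the other orientation) by at least
#' `min_margin`; anything else, including ties, is unassigned. Reads too
#' short to contain both primers plus a 50 nt insert are unassigned by rule.
#'
#' @param read_seq read sequence.
#' @param barcode_map primer sheet data.frame ([allocate_pairs()] /
#'   [read_barcode_map()]).
#' @param max_dist maximum edit distance per barcode (default 6 for
#'   24-mers, ~25%).
#' @param window terminal search window in nt (default 60).
#' @param min_margin required gap to the runner-up combination (default 2).
#' @return one-row data.frame: `plate_index`, `well_label`, `orientation`
#'   (`"forward"`/`"reverse"`/`"unassigned"`), `fwd_dist`, `rev_dist`, and
#'   trim coordinates `trim_start`/`trim_end` (0-based, half-open, in the
#'   oriented read) for downstream primer removal.
#' @export
classify_read <- function(read_seq, barcode_map, max_dist = 6, window = 60,
                          min_margin = 2) {
  unassigned <- data.frame(plate_index = NA_integer_,
                           well_label = NA_character_,
                           orientation = "unassigned",
                           fwd_dist = NA_integer_, rev_dist = NA_integer_,
                           trim_start = NA_integer_, trim_end = NA_integer_,
                           stringsAsFactors = FALSE)
  fwd_bc <- unique(barcode_map$fwd_barcode)
  rev_bc <- unique(barcode_map$rev_barcode)
  has_primers <- all(c("fwd_primer", "rev_primer") %in% names(barcode_map))
  min_len <- if (has_primers) {
    nchar(barcode_map$fwd_primer[1]) + nchar(barcode_map$rev_primer[1]) + 50L
  } else nchar(fwd_bc[1]) + nchar(rev_bc[1]) + 50L
  if (nchar(read_seq) < min_len) return(unassigned)

  rev_bc_rc <- revcomp(rev_bc)
  orient <- list(forward = read_seq, reverse = revcomp(read_seq))
  res <- lapply(orient, function(s) {
    df <- vapply(.end_distances(s, fwd_bc, window, "five_prime"),
                 `[[`, numeric(1), "distance")
    dr <- vapply(.end_distances(s, rev_bc_rc, window, "three_prime"),
                 `[[`, numeric(1), "distance")
    list(df = df, dr = dr)
  })
  combined_best <- vapply(res, function(r) min(r$df) + min(r$dr), numeric(1))
  o <- names(which.min(combined_best))
  r <- res[[o]]
  fi <- which.min(r$df); ri <- which.min(r$dr)
  best <- r$df[fi] + r$dr[ri]
  # runner-up: swap either barcode within the best orientation, or take the
  # other orientation's best combination
  second <- function(x, i) if (length(x) > 1) min(x[-i]) else Inf
  runner <- min(second(r$df, fi) + r$dr[ri],
                r$df[fi] + second(r$dr, ri),
                combined_best[setdiff(names(combined_best), o)])
  if (r$df[fi] > max_dist || r$dr[ri] > max_dist || runner - best < min_margin) {
    return(unassigned)
  }
  hit <- barcode_map[barcode_map$fwd_barcode == fwd_bc[fi] &
                       barcode_map$rev_barcode == rev_bc[ri], , drop = FALSE]
  if (nrow(hit) != 1) return(unassigned)
  # trim coordinates in the oriented read: end of forward primer .. start of
  # the reverse-complemented reverse primer
  s <- orient[[o]]
  floc <- locate_barcode(s, fwd_bc[fi], window, "five_prime")
  rloc <- locate_barcode(s, rev_bc_rc[ri], window, "three_prime")
  bind_f <- if (has_primers)
    nchar(hit$fwd_primer) - nchar(hit$fwd_barcode) else 0L
  bind_r <- if (has_primers)
    nchar(hit$rev_primer) - nchar(hit$rev_barcode) else 0L
  trim_start <- min(floc$match_end + bind_f, nchar(s))
  trim_end <- max(rloc$offset - bind_r, trim_start)
  data.frame(plate_index = hit$plate_index, well_label = hit$well_label,
             orientation = o,
             fwd_dist = as.integer(r$df[fi]), rev_dist = as.integer(r$dr[ri]),
             trim_start = as.integer(trim_start),
             trim_end = as.integer(trim_end),
             stringsAsFactors = FALSE)
}

#' Demultiplex a batch of reads
#'
#' Partitions reads into per-sample bins plus an unassigned bin; bin sizes
#' always sum to the input read count.
#'
#' @param reads FASTQ path or a reads data.frame (`id`, `seq`, `qual`).
#' @param barcode_map primer sheet data.frame.
#' @param max_dist,window,min_margin see [classify_read()].
#' @param out_dir optional directory: writes `plate{P}_{well}.fastq` per
#'   sample, `unassigned.fastq`, and `demux_report.tsv`.
#' @return list with `assignments` (one row per read), `report`
#'   (sample, n_reads, n_fwd, n_rev), and `bins` (named list of row indices
#'   into the reads, including `"unassigned"`).
#' @export
demux_batch <- function(reads, barcode_map, max_dist = 6, window = 60,
                        min_margin = 2, out_dir = NULL) {
  if (is.character(reads)) reads <- read_fastq(reads)
  asg <- if (nrow(reads) == 0) {
    data.frame(plate_index = integer(0), well_label = character(0),
               orientation = character(0), fwd_dist = integer(0),
               rev_dist = integer(0), trim_start = integer(0),
               trim_end = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(reads$seq, classify_read, barcode_map = barcode_map,
                          max_dist = max_dist, window = window,
                          min_margin = min_margin))
  }
  asg <- cbind(data.frame(read_id = reads$id, stringsAsFactors = FALSE), asg)
  sample_of <- ifelse(asg$orientation == "unassigned", "unassigned",
                      sample_name(asg$plate_index, asg$well_label))
  all_samples <- sample_name(barcode_map$plate_index, barcode_map$well_label)
  bins <- c(lapply(setNames(all_samples, all_samples),
                   function(s) which(sample_of == s)),
            list(unassigned = which(sample_of == "unassigned")))
  report <- data.frame(
    sample = names(bins),
    n_reads = vapply(bins, length, integer(1)),
    n_fwd = vapply(bins, function(i)
      sum(asg$orientation[i] == "forward"), integer(1)),
    n_rev = vapply(bins, function(i)
      sum(asg$orientation[i] == "reverse"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in names(bins)) {
      write_fastq(reads[bins[[s]], , drop = FALSE],
                  file.path(out_dir, paste0(s, ".fastq")))
    }
    write.table(report, file.path(out_dir, "demux_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(assignments = asg, report = report, bins = bins)
}
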