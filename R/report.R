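#' Summarize a sample: identity, mutations, indels, coverage, depth
#'
#' Identity is the fraction of target positions verified free of
#' mutations/indels:
#' `identity = (L - mutated_positions - indel_positions) / L`, clipped to
#' `[0, 1]`, where deletion records count their full span and an insertion
#' counts one position (its anchor). Positions lacking coverage on either
#' strand count against `coverage` but not against identity; both numbers
#' are reported.
#'
#' @param calls result of [call_sample()] (list with `calls` and `indels`).
#' @param pileup the sample's `strand_pileup`.
#' @param target target sequence.
#' @param sample_id sample label (e.g. `"plate1_B1"`).
#' @param target_id target label.
#' @param n_reads_fwd,n_reads_rev demultiplexed read counts per strand.
#' @return one-row data.frame of class `sample_summary`: `sample`,
#'   `target`, `identity`, `n_mutations`, `n_indels`, `coverage`,
#'   `max_depth`, `n_fwd`, `n_rev`.
#' @export
summarize_sample <- function(calls, pileup, target, sample_id = "sample",
                             target_id = "target", n_reads_fwd = NA_integer_,
                             n_reads_rev = NA_integer_) {
  L <- nchar(target)
  snv <- calls$calls[calls$calls$status == "SNV" &
                       calls$calls$called_base != "-", , drop = FALSE]
  n_mut <- nrow(snv)
  ind <- calls$indels
  n_indels <- nrow(ind)
  indel_positions <- sum(ifelse(ind$type == "deletion", ind$length, 1L))
  depth <- pileup_depth(pileup)
  coverage <- if (L == 0) 0 else mean(depth[, 1] > 0 & depth[, 2] > 0)
  identity <- min(max((L - n_mut - indel_positions) / L, 0), 1)
  out <- data.frame(sample = sample_id, target = target_id,
                    identity = identity, n_mutations = n_mut,
                    n_indels = n_indels, coverage = coverage,
                    max_depth = if (L) max(rowSums(depth)) else 0L,
                    n_fwd = n_reads_fwd, n_rev = n_reads_rev,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_summary", class(out))
  out
}

#' Write calls as a minimal VCFv4.2 file
#'
#' Emits only SNV and indel records, with 1-based positions. Substitutions
#' are written directly; deletions and insertions are left-anchored on the
#' preceding reference base in the usual VCF convention. INFO carries
#' `DP` (forward+reverse depth at the site) and `P` (combined posterior for
#' SNVs). The header documents the identity definition and records the
#' number of strand-biased positions detected (`SB` INFO field on records
#' is reserved; the per-sample count travels in the
#' `##strand_biased_positions` header line).
#'
#' @param calls result of [call_sample()].
#' @param target target sequence.
#' @param sample_id sample label (written in the header).
#' @param path output path.
#' @param target_id contig name.
#' @return the path, invisibly.
#' @export
write_vcf <- function(calls, target, sample_id, path, target_id = "target") {
  L <- nchar(target)
  ref <- strsplit(target, "", fixed = TRUE)[[1]]
  cl <- calls$calls
  n_sb <- sum(cl$status == "STRAND_BIASED")
  dp_at <- function(pos0) {
    i <- cl$position == pos0
    if (!any(i)) return(0L)
    sum(cl$depth_fwd[i], cl$depth_rev[i])
  }
  recs <- character(0)
  snv <- cl[cl$status == "SNV" & cl$called_base != "-", , drop = FALSE]
  if (nrow(snv)) {
    recs <- c(recs, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;P=%.6g", target_id,
      snv$position + 1L, snv$ref_base, snv$called_base,
      snv$depth_fwd + snv$depth_rev, snv$posterior))
  }
  ind <- calls$indels
  for (k in seq_len(nrow(ind))) {
    s <- ind$start[k]
    if (ind$type[k] == "deletion") {
      if (s > 0) {
        pos <- s               # 1-based anchor = s (0-based s-1)
        refa <- paste0(ref[s], ind$seq[k])
        alta <- ref[s]
      } else {                 # deletion at position 0: anchor on the right
        pos <- 1L
        nxt <- if (s + ind$length[k] < L) ref[s + ind$length[k] + 1] else ""
        refa <- paste0(ind$seq[k], nxt)
        alta <- if (nzchar(nxt)) nxt else "."
      }
      recs <- c(recs, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d",
                              target_id, pos, refa, alta, dp_at(s)))
    } else {
      anchor0 <- min(max(s, 0L), L - 1L)   # 0-based preceding base
      recs <- c(recs, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d",
                              target_id, anchor0 + 1L, ref[anchor0 + 1],
                              paste0(ref[anchor0 + 1], ind$seq[k]),
                              dp_at(anchor0)))
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=nanoverify",
    sprintf("##contig=<ID=%s,length=%d>", target_id, L),
    sprintf("##sample=%s", sample_id),
    sprintf("##strand_biased_positions=%d", n_sb),
    paste0("##INFO=<ID=DP,Number=1,Type=Integer,",
           "Description=\"Total read depth (fwd+rev) at the site\">"),
    paste0("##INFO=<ID=P,Number=1,Type=Float,",
           "Description=\"Combined strand-concordant posterior\">"),
    paste0("##INFO=<ID=SB,Number=0,Type=Flag,",
           "Description=\"Position rejected as strand-biased (not emitted;",
           " see strand_biased_positions)\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Cost per kilobase of sequence
#'
#' @param cost_per_sample total per-sample workflow cost (currency units).
#' @param amplicon_length_kb amplicon length in kb; must be positive.
#' @return cost per kb, rounded to 2 decimals.
#' @export
#' @examples
#' cost_per_kb(2.20, 6.6)   # 0.33
cost_per_kb <- function(cost_per_sample, amplicon_length_kb) {
  if (!is.numeric(amplicon_length_kb) || amplicon_length_kb <= 0) {
    stop("amplicon length must be positive")
  }
  round(cost_per_sample / amplicon_length_kb, 2)
}

#' Run the full verification pipeline
#'
#' demultiplex -> per-sample align -> strand-concordant call -> summarize.
#' In verification mode each sample is aligned to its known target (from
#' `sample_targets`, or the single supplied target); in identification mode
#' (`identify = TRUE`) each sample's target is chosen by total alignment
#' score over its reads against the whole panel.
#'
#' @param reads FASTQ path or reads data.frame.
#' @param barcode_map primer sheet data.frame or TSV path.
#' @param targets named character vector of targets, or FASTA path.
#' @param sample_targets optional data.frame (`sample`, `target_id`)
#'   mapping samples (`plate{P}_{well}`) to targets.
#' @param identify logical: identification mode.
#' @param params list of tuning parameters: `error_rate` (0.1), `tau`
#'   (0.99), `min_depth_per_strand` (5), `max_dist` (6), `window` (60),
#'   `min_margin` (2), `band_width` (NULL = automatic).
#' @param out_dir optional output directory: per-sample VCFs, summary TSV,
#'   demux report and a JSON run manifest recording every parameter.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return list: `summary` (one row per sample in the barcode map; samples
#'   without reads flagged `NO_READS`), `demux`, `samples` (per-sample
#'   calls/pileups).
#' @export
run_pipeline <- function(reads, barcode_map, targets, sample_targets = NULL,
                         identify = FALSE, params = list(), out_dir = NULL,
                         seed = NULL) {
  p <- modifyList(list(error_rate = 0.1, tau = 0.99,
                       min_depth_per_strand = 5, max_dist = 6, window = 60,
                       min_margin = 2, band_width = NULL), params)
  if (is.character(barcode_map)) barcode_map <- read_barcode_map(barcode_map)
  if (is.character(targets) && length(targets) == 1 &&
      file.exists(targets)) {
    targets <- read_targets(targets)
  }
  if (is.null(names(targets))) {
    names(targets) <- paste0("target", seq_along(targets))
  }
  if (is.character(reads)) reads <- read_fastq(reads)
  dm <- demux_batch(reads, barcode_map, max_dist = p$max_dist,
                    window = p$window, min_margin = p$min_margin,
                    out_dir = if (is.null(out_dir)) NULL else
                      file.path(out_dir, "demux"))
  samples <- setdiff(dm$report$sample, "unassigned")
  results <- list()
  rows <- list()
  for (s in samples) {
    idx <- dm$bins[[s]]
    tid <- if (!is.null(sample_targets) && s %in% sample_targets$sample) {
      sample_targets$target_id[match(s, sample_targets$sample)]
    } else names(targets)[1]
    if (length(idx) == 0) {
      rows[[s]] <- data.frame(sample = s, target = tid, identity = NA_real_,
                              n_mutations = NA_integer_,
                              n_indels = NA_integer_, coverage = NA_real_,
                              max_depth = 0L, n_fwd = 0L, n_rev = 0L,
                              status = "NO_READS", stringsAsFactors = FALSE)
      next
    }
    asg <- dm$assignments[idx, , drop = FALSE]
    oriented <- ifelse(asg$orientation == "forward", reads$seq[idx],
                       revcomp(reads$seq[idx]))
    trimmed <- substr(oriented, asg$trim_start + 1L, asg$trim_end)
    keep <- nchar(trimmed) > 0
    trimmed <- trimmed[keep]
    strands <- asg$orientation[keep]
    if (identify) {
      score_tot <- setNames(numeric(length(targets)), names(targets))
      for (r in trimmed) {
        sc <- vapply(targets, function(t)
          align_read(r, t, band_width = p$band_width)$score, numeric(1))
        score_tot <- score_tot + sc
      }
      tid <- names(which.max(score_tot))
    }
    tg <- unname(targets[tid])
    alns <- lapply(seq_along(trimmed), function(k) {
      align_read(trimmed[k], tg, band_width = p$band_width,
                 strand = strands[k])
    })
    pu <- build_pileup(alns, tg, tid)
    cs <- call_sample(pu, tg, e = p$error_rate, tau = p$tau,
                      min_depth = p$min_depth_per_strand)
    sm <- summarize_sample(cs, pu, tg, sample_id = s, target_id = tid,
                           n_reads_fwd = sum(strands == "forward"),
                           n_reads_rev = sum(strands == "reverse"))
    sm$status <- "OK"
    rows[[s]] <- as.data.frame(sm)
    results[[s]] <- list(pileup = pu, calls = cs, summary = sm)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_vcf(cs, tg, s, file.path(out_dir, paste0(s, ".vcf")), tid)
    }
  }
  summary <- do.call(rbind, rows[samples])
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(parameters = p[!vapply(p, is.null, logical(1))],
           seed = seed, n_reads = nrow(reads),
           n_samples = length(samples),
           identify = identify,
           targets = names(targets)),
      file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  }
  list(summary = summary, demux = dm, samples = results)
}
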