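# Independent oracles and fixture builders. Everything here reimplements
# the checked quantity by a different route (full-matrix DP, exhaustive
# enumeration, term-by-term arithmetic) and must stay independent of the
# package code paths it verifies.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- full-matrix (unbanded) ends-free affine-gap DP, score only ----------
oracle_align_score <- function(target, read, match = 2, mismatch = -3,
                               gap_open = -4, gap_ext = -2) {
  x <- strsplit(target, "")[[1]]; y <- strsplit(read, "")[[1]]
  n1 <- length(x); n2 <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n1 + 1, n2 + 1)
  X <- matrix(NEG, n1 + 1, n2 + 1)
  Y <- matrix(NEG, n1 + 1, n2 + 1)
  go <- gap_open + gap_ext
  for (i in 1:n1) {
    for (j in 1:n2) {
      h <- if (i - 1 == 0 || j - 1 == 0) 0 else max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- h + (if (x[i] == y[j]) match else mismatch)
      xo <- if (i - 1 == 0) 0 else max(M[i, j + 1], Y[i, j + 1])
      X[i + 1, j + 1] <- max(xo + go, X[i, j + 1] + gap_ext)
      yo <- if (j - 1 == 0) 0 else max(M[i + 1, j], X[i + 1, j])
      Y[i + 1, j + 1] <- max(yo + go, Y[i + 1, j] + gap_ext)
    }
  }
  max(M[n1 + 1, -1], X[n1 + 1, -1], Y[n1 + 1, -1],
      M[-1, n2 + 1], X[-1, n2 + 1], Y[-1, n2 + 1])
}

# --- exhaustive sliding Levenshtein: min over all substrings of the text --
oracle_infix_distance <- function(pattern, text) {
  m <- nchar(pattern); n <- nchar(text)
  subs <- character(0)
  for (start in 1:max(n, 1)) {
    ends <- start:n
    if (start > n) break
    subs <- c(subs, substring(text, start, ends))
  }
  subs <- unique(c(subs, ""))
  min(adist(pattern, subs))
}

# --- brute-force enumeration of maximal self-complementary stems ----------
oracle_structure_score <- function(s, min_stem = 4) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  comp <- chartr("ACGT", "TGCA", ch)
  score <- 0
  for (i in 1:L) {
    for (k in min_stem:L) {
      if (i + k - 1 > L) break
      jmax <- L - k + 1
      if (i + k > jmax) next
      for (j in (i + k):jmax) {
        # stem: ch[i..i+k-1] pairs ch[j+k-1..j] (a == revcomp(b))
        ok <- all(ch[i:(i + k - 1)] == comp[(j + k - 1):j])
        if (!ok) next
        ext_out <- (i - 1 >= 1) && (j + k <= L) && (ch[i - 1] == comp[j + k])
        ext_in <- (j - 1 > i + k) && (ch[i + k] == comp[j - 1])
        if (ext_out || ext_in) next
        score <- score - 2 * k
        if (i == 1 || j + k - 1 == L) score <- score - 3
      }
    }
  }
  score
}

# --- term-by-term posterior arithmetic (no log-space tricks) --------------
oracle_posterior <- function(counts, e, prior = rep(0.2, 5)) {
  syms <- c("A", "C", "G", "T", "-")
  k <- setNames(numeric(5), syms)
  k[names(counts)] <- counts
  n <- sum(k)
  lik <- vapply(syms, function(b) (1 - e)^k[b] * (e / 4)^(n - k[b]),
                numeric(1))
  p <- prior * lik
  p / sum(p)
}

# --- fixtures -------------------------------------------------------------
BIND_FWD <- "ACGGTCTCAAGGA"
BIND_REV <- "TGGAGCTCTTACC"

fixture_map <- function(n_fwd = 2, n_rev = 2, seed = 7, n_cand = 150) {
  cand <- generate_candidates(n_cand, 24, seed = seed)
  sel <- rank_and_select(cand, n_forward = n_fwd, n_reverse = n_rev,
                         min_pairwise_edit = 8)
  allocate_pairs(sel$forward, sel$reverse, BIND_FWD, BIND_REV)
}

# alt base (or deletion) different from the reference base
pick_alt <- function(ref, include_del = TRUE) {
  pool <- setdiff(if (include_del) c("A", "C", "G", "T", "-")
                  else c("A", "C", "G", "T"), ref)
  sample(pool, 1)
}

# place n single-strand systematic sites at distinct positions such that
# no concordant evidence can arise by construction: two opposite-strand
# deletion sites inside one homopolymer run would align to the same
# canonical gap position and merge into genuinely double-strand evidence,
# so such deletion alts are re-drawn as substitutions
place_single_strand_sites <- function(ref_ch, n_sites,
                                      rate_range = c(0.85, 1)) {
  L <- length(ref_ch)
  run_id <- cumsum(c(TRUE, ref_ch[-1] != ref_ch[-L]))
  pos <- sample(0:(L - 1), n_sites)
  strand <- sample(c("forward", "reverse"), n_sites, replace = TRUE)
  alt <- vapply(pos, function(p) pick_alt(ref_ch[p + 1]), character(1))
  for (i in seq_len(n_sites)) {
    if (alt[i] != "-") next
    same_run <- run_id[pos + 1] == run_id[pos[i] + 1]
    clash <- same_run & alt == "-" & strand != strand[i]
    if (any(clash)) alt[i] <- pick_alt(ref_ch[pos[i] + 1], include_del = FALSE)
  }
  lapply(seq_len(n_sites), function(i) {
    systematic_site(pos[i], strand[i], alt[i],
                    runif(1, rate_range[1], rate_range[2]))
  })
}

# simulate -> align -> pileup for one sample, without demux
sim_pileup <- function(template, n_fwd, n_rev, model, sites = list(),
                       variants = list(), band_width = NULL) {
  reads <- simulate_reads(template, NULL, n_fwd = n_fwd, n_rev = n_rev,
                          model = model, sites = sites, variants = variants)
  truth <- attr(reads, "truth")
  alns <- lapply(seq_len(nrow(reads)), function(i) {
    s <- reads$seq[i]
    if (truth$strand[i] == "reverse") s <- revcomp(s)
    align_read(s, template, band_width = band_width,
               strand = truth$strand[i])
  })
  build_pileup(alns, template)
}
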