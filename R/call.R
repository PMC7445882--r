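#' Per-strand log-likelihood of a base hypothesis
#'
#' Binomial collapse of the per-strand counts: under hypothesis `b`, each of
#' the `n_s` observations on the strand is correct (probability `1 - e`) or
#' one of the four other symbols (error mass `e` split uniformly), so
#'
#'   `log L(b) = k_b log(1 - e) + (n_s - k_b) log(e / 4)`
#'
#' with `k_b` the count of `b` and `n_s` the strand depth. The multinomial
#' coefficient is constant across hypotheses and omitted. Depth enters the
#' likelihood directly, so deeper strands carry proportionally more weight.
#'
#' @param counts named counts over (a subset of) `A, C, G, T, -`.
#' @param e per-base error rate, in `(0, 0.5)`.
#' @param b base hypothesis, one of `A, C, G, T, -`.
#' @return log-likelihood (0 at depth 0: no information).
#' @export
strand_likelihood <- function(counts, e, b) {
  if (e <= 0 || e >= 0.5) stop("error rate e must be in (0, 0.5)")
  stopifnot(b %in% PILEUP_SYMBOLS)
  k <- full_counts(counts)
  if (any(k < 0)) stop("counts must be >= 0")
  n <- sum(k)
  unname(k[b] * log(1 - e) + (n - k[b]) * log(e / 4))
}

full_counts <- function(counts) {
  k <- setNames(numeric(5), PILEUP_SYMBOLS)
  if (is.null(names(counts))) {
    if (length(counts) != 5) stop("unnamed counts must have length 5")
    k[] <- counts
  } else {
    bad <- setdiff(names(counts), PILEUP_SYMBOLS)
    if (length(bad)) stop("unknown symbol in counts: ", bad[1])
    k[names(counts)] <- counts
  }
  k
}

#' Per-strand posterior over bases
#'
#' `P(b) proportional to prior(b) * L(b)`, normalised over the five symbols.
#' At depth 0 the posterior equals the prior.
#'
#' @param counts named counts over `A, C, G, T, -` (one strand).
#' @param e per-base error rate in `(0, 0.5)`.
#' @param prior named prior over the five symbols (default uniform); must
#'   not be all zero.
#' @return list of class `strand_posterior`: `probs` (named, sums to 1) and
#'   `depth`.
#' @export
strand_posterior <- function(counts, e, prior = NULL) {
  if (is.null(prior)) prior <- setNames(rep(0.2, 5), PILEUP_SYMBOLS)
  p <- full_counts(prior)
  if (all(p == 0)) stop("prior must not be all zero")
  if (any(p < 0)) stop("prior must be non-negative")
  p <- p / sum(p)
  ll <- vapply(PILEUP_SYMBOLS, function(b) strand_likelihood(counts, e, b),
               numeric(1))
  lp <- log(p) + ll
  lp <- lp - max(lp[is.finite(lp)])
  probs <- exp(lp)
  probs[!is.finite(probs)] <- 0
  probs <- probs / sum(probs)
  structure(list(probs = probs, depth = sum(full_counts(counts))),
            class = "strand_posterior")
}

#' Call one pileup position with strand-concordance gating
#'
#' Computes the per-strand posteriors and applies the categorical rules:
#' insufficient depth on either strand gives `LOW_DEPTH` (template base
#' retained); disagreement between the strand argmax bases — including ties
#' within a strand — indicates strand bias and gives `STRAND_BIASED`
#' (template base retained); concordant strands are combined,
#' `P(b) proportional to P_fwd(b) P_rev(b)`, and a non-reference base with
#' combined posterior `>= tau` is reported as an `SNV`. A concordant
#' non-reference base below `tau` stays `REFERENCE` with a `subthreshold`
#' flag.
#'
#' @param fwd_counts,rev_counts named per-strand counts over `A,C,G,T,-`.
#' @param ref_base template base at the position.
#' @param e per-base error rate in `(0, 0.5)`.
#' @param tau posterior threshold for reporting an SNV, in `(0.5, 1)`.
#' @param min_depth minimum reads per strand (default 5).
#' @param prior per-strand prior (default uniform).
#' @return list of class `variant_call`: `ref_base`, `called_base`,
#'   `status` (`SNV`/`REFERENCE`/`STRAND_BIASED`/`LOW_DEPTH`), `posterior`
#'   (combined, for the called base), `fwd_probs`, `rev_probs`, `depth_fwd`,
#'   `depth_rev`, `flag`.
#' @export
call_position <- function(fwd_counts, rev_counts, ref_base, e = 0.1,
                          tau = 0.99, min_depth = 5, prior = NULL) {
  if (tau <= 0.5 || tau >= 1) stop("tau must be in (0.5, 1)")
  if (min_depth < 1) stop("min_depth must be >= 1")
  pf <- strand_posterior(fwd_counts, e, prior)
  pr <- strand_posterior(rev_counts, e, prior)
  out <- function(called, status, post, flag = "") {
    structure(list(ref_base = ref_base, called_base = called,
                   status = status, posterior = post,
                   fwd_probs = pf$probs, rev_probs = pr$probs,
                   depth_fwd = pf$depth, depth_rev = pr$depth, flag = flag),
              class = "variant_call")
  }
  if (pf$depth < min_depth || pr$depth < min_depth) {
    return(out(ref_base, "LOW_DEPTH", NA_real_))
  }
  amax <- function(p) {
    i <- which(p >= max(p) - 1e-12)
    if (length(i) > 1) NA_character_ else PILEUP_SYMBOLS[i]
  }
  bf <- amax(pf$probs); br <- amax(pr$probs)
  if (is.na(bf) || is.na(br) || bf != br) {
    return(out(ref_base, "STRAND_BIASED", NA_real_))
  }
  comb <- pf$probs * pr$probs
  comb <- comb / sum(comb)
  b <- bf
  if (b == ref_base) return(out(ref_base, "REFERENCE", comb[b]))
  if (comb[b] >= tau) return(out(b, "SNV", comb[b]))
  out(ref_base, "REFERENCE", comb[b], flag = "subthreshold")
}

#' Call every position of a sample's pileup
#'
#' Runs [call_position()] along the target. Deletions participate as a
#' fifth symbol, so concordant deletions surface as deletion variants;
#' consecutive deletion calls are merged into single indel records.
#' Insertions are handled by a separate concordance rule outside the
#' binomial model: an inserted sequence is reported when it is observed on
#' both strands at `>= 50%` of the respective strand depth at its anchor
#' position.
#'
#' @param pileup a `strand_pileup` for the target.
#' @param target target sequence (must match the pileup length).
#' @param e,tau,min_depth,prior see [call_position()].
#' @return list with `calls` (data.frame: 0-based `position`, `ref_base`,
#'   `called_base`, `status`, `posterior`, `flag`, `depth_fwd`,
#'   `depth_rev`) and `indels` (data.frame: `type` deletion/insertion,
#'   0-based `start`, `length`, `seq`).
#' @export
call_sample <- function(pileup, target, e = 0.1, tau = 0.99, min_depth = 5,
                        prior = NULL) {
  if (tau <= 0.5 || tau >= 1) stop("tau must be in (0.5, 1)")
  if (e <= 0 || e >= 0.5) stop("error rate e must be in (0, 0.5)")
  ref <- strsplit(target, "", fixed = TRUE)[[1]]
  L <- length(ref)
  if (L != length(pileup$ref)) stop("pileup length does not match target")
  if (is.null(prior)) prior <- setNames(rep(0.2, 5), PILEUP_SYMBOLS)
  p0 <- full_counts(prior); p0 <- p0 / sum(p0)
  # vectorised across positions; call_position() is the scalar reference
  # implementation and the two are asserted equivalent in the test suite
  post_mat <- function(K) {
    n <- rowSums(K)
    lp <- K * log(1 - e) + (n - K) * log(e / 4)
    lp <- sweep(lp, 2, log(p0), "+")
    lp[!is.finite(lp)] <- -Inf
    m <- do.call(pmax, as.data.frame(lp))
    P <- exp(lp - m)
    P[!is.finite(P)] <- 0
    P / rowSums(P)
  }
  Kf <- pileup$counts[, 1, , drop = TRUE]
  Kr <- pileup$counts[, 2, , drop = TRUE]
  if (L == 1) { Kf <- matrix(Kf, 1); Kr <- matrix(Kr, 1) }
  nf <- rowSums(Kf); nr <- rowSums(Kr)
  Pf <- post_mat(Kf); Pr <- post_mat(Kr)
  mf <- do.call(pmax, as.data.frame(Pf))
  mr <- do.call(pmax, as.data.frame(Pr))
  tie_f <- rowSums(Pf >= mf - 1e-12) > 1
  tie_r <- rowSums(Pr >= mr - 1e-12) > 1
  bf <- max.col(Pf, ties.method = "first")
  br <- max.col(Pr, ties.method = "first")
  comb <- Pf * Pr
  comb <- comb / rowSums(comb)
  post_b <- comb[cbind(seq_len(L), bf)]
  low <- nf < min_depth | nr < min_depth
  disc <- !low & (tie_f | tie_r | bf != br)
  b <- PILEUP_SYMBOLS[bf]
  conc <- !low & !disc
  snv <- conc & b != ref & post_b >= tau
  subth <- conc & b != ref & post_b < tau
  status <- ifelse(low, "LOW_DEPTH",
                   ifelse(disc, "STRAND_BIASED",
                          ifelse(snv, "SNV", "REFERENCE")))
  calls <- data.frame(position = 0:(L - 1L), ref_base = ref,
                      called_base = ifelse(snv, b, ref), status = status,
                      posterior = ifelse(conc, post_b, NA_real_),
                      flag = ifelse(subth, "subthreshold", ""),
                      depth_fwd = nf, depth_rev = nr,
                      stringsAsFactors = FALSE)
  # merge consecutive concordant-deletion calls into indel records
  delpos <- calls$position[calls$status == "SNV" & calls$called_base == "-"]
  indels <- if (length(delpos)) {
    grp <- cumsum(c(TRUE, diff(delpos) != 1))
    do.call(rbind, lapply(split(delpos, grp), function(g) {
      data.frame(type = "deletion", start = g[1], length = length(g),
                 seq = paste(ref[g + 1], collapse = ""),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(type = character(0), start = integer(0), length = integer(0),
               seq = character(0), stringsAsFactors = FALSE)
  }
  # insertion concordance: both strands, >= 50% of strand depth at anchor
  ins <- pileup$insertions
  if (nrow(ins)) {
    depth <- pileup_depth(pileup)
    keys <- unique(ins[, c("tpos", "seq")])
    for (k in seq_len(nrow(keys))) {
      sel <- ins$tpos == keys$tpos[k] & ins$seq == keys$seq[k]
      cf <- sum(ins$count[sel & ins$strand == "forward"])
      cr <- sum(ins$count[sel & ins$strand == "reverse"])
      anchor <- min(max(keys$tpos[k] + 1L, 1L), nrow(depth))
      nf <- depth[anchor, 1]; nr <- depth[anchor, 2]
      if (nf >= min_depth && nr >= min_depth &&
          cf >= 0.5 * nf && cr >= 0.5 * nr) {
        indels <- rbind(indels,
                        data.frame(type = "insertion", start = keys$tpos[k],
                                   length = nchar(keys$seq[k]),
                                   seq = keys$seq[k],
                                   stringsAsFactors = FALSE))
      }
    }
  }
  rownames(indels) <- NULL
  list(calls = calls, indels = indels)
}

#' Naive pooled-strand majority consensus (baseline comparator)
#'
#' Ignores strand information: the consensus at each position is the
#' plurality symbol of the pooled forward+reverse counts. Returns positions
#' where the consensus differs from the reference. This is the baseline the
#' strand-concordance caller improves on: a systematic error confined to an
#' overrepresented strand flips the pooled majority and produces a false
#' SNV here.
#'
#' @param pileup a `strand_pileup`.
#' @param target target sequence.
#' @return data.frame: 0-based `position`, `ref_base`, `called_base`.
#' @export
naive_consensus <- function(pileup, target) {
  ref <- strsplit(target, "", fixed = TRUE)[[1]]
  pooled <- pileup$counts[, 1, ] + pileup$counts[, 2, ]
  out <- lapply(seq_along(ref), function(i) {
    k <- pooled[i, ]
    if (sum(k) == 0) return(NULL)
    top <- which(k == max(k))
    if (length(top) > 1) return(NULL)       # tie: keep reference
    b <- PILEUP_SYMBOLS[top]
    if (b == ref[i]) return(NULL)
    data.frame(position = i - 1L, ref_base = ref[i], called_base = b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(position = integer(0), ref_base = character(0),
                      called_base = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Estimate the per-base error rate from a pileup
#'
#' Median per-position minor-symbol fraction at concordant-reference
#' positions (both strand majorities equal the reference): a run-internal
#' calibration of `e` that needs no external truth.
#'
#' @param pileup a `strand_pileup`.
#' @param min_depth positions with pooled depth below this are ignored.
#' @return estimated error rate (clamped to `[0.01, 0.49]`), or `NA` if no
#'   usable position exists.
#' @export
estimate_error_rate <- function(pileup, min_depth = 10) {
  ref_i <- match(pileup$ref, PILEUP_SYMBOLS)
  fr <- pileup$counts[, 1, , drop = FALSE]
  rv <- pileup$counts[, 2, , drop = FALSE]
  minor <- rep(NA_real_, length(ref_i))
  for (i in seq_along(ref_i)) {
    kf <- fr[i, 1, ]; kr <- rv[i, 1, ]
    n <- sum(kf) + sum(kr)
    if (n < min_depth) next
    if (which.max(kf) != ref_i[i] || which.max(kr) != ref_i[i]) next
    minor[i] <- 1 - (kf[ref_i[i]] + kr[ref_i[i]]) / n
  }
  if (all(is.na(minor))) return(NA_real_)
  min(max(median(minor, na.rm = TRUE), 0.01), 0.49)
}
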