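test_that("strand likelihood matches its closed form", {
  expect_equal(strand_likelihood(c(A = 10), e = 0.1, b = "A"),
               10 * log(0.9))
  # term-by-term arithmetic: counts {A:8, G:2}
  k <- c(A = 8, G = 2)
  lA <- 8 * log(0.9) + 2 * log(0.1 / 4)
  lG <- 2 * log(0.9) + 8 * log(0.1 / 4)
  expect_equal(strand_likelihood(k, 0.1, "A"), lA)
  expect_equal(strand_likelihood(k, 0.1, "G"), lG)
  expect_equal(strand_likelihood(k, 0.1, "A") - strand_likelihood(k, 0.1, "G"),
               lA - lG)
  # zero depth: identical (zero) log-likelihood for every hypothesis
  ll0 <- vapply(c("A", "C", "G", "T", "-"),
                function(b) strand_likelihood(c(A = 0), 0.1, b), numeric(1))
  expect_true(all(ll0 == 0))
  expect_error(strand_likelihood(c(A = 1), 0.6, "A"), "0.5")
  expect_error(strand_likelihood(c(A = 1), 0, "A"), "0.5")
})

test_that("strand posterior normalizes, honours prior, matches arithmetic", {
  sp <- strand_posterior(c(A = 30), e = 0.1)
  expect_equal(sum(sp$probs), 1, tolerance = 1e-9)
  expect_gt(sp$probs[["A"]], 0.999)
  # depth 0 -> posterior equals the prior
  pr <- c(A = 0.5, C = 0.2, G = 0.1, T = 0.1, "-" = 0.1)
  sp0 <- strand_posterior(c(A = 0), e = 0.1, prior = pr)
  expect_equal(sp0$probs, pr)
  expect_equal(sp0$depth, 0)
  # term-by-term oracle on random counts
  set.seed(51)
  for (i in 1:25) {
    k <- setNames(sample(0:20, 5, replace = TRUE), c("A", "C", "G", "T", "-"))
    e <- runif(1, 0.02, 0.45)
    expect_equal(strand_posterior(k, e)$probs, oracle_posterior(k, e),
                 tolerance = 1e-9)
  }
  expect_error(strand_posterior(c(A = 1), 0.1, prior = rep(0, 5)), "zero")
})

test_that("posterior is equivariant under relabeling of the 5 symbols", {
  set.seed(52)
  syms <- c("A", "C", "G", "T", "-")
  k <- setNames(c(12, 3, 0, 7, 1), syms)
  base <- strand_posterior(k, 0.1)$probs
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) all(sort(p) == 1:5)), ]
  expect_equal(nrow(perms), 120)
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    kp <- setNames(unname(k[p]), syms)
    got <- strand_posterior(kp, 0.1)$probs
    expect_equal(unname(got), unname(base[p]), tolerance = 1e-12)
  }
})

test_that("call_position implements the concordance gates", {
  # no variant signal
  rc <- call_position(c(A = 30), c(A = 28), "A")
  expect_equal(rc$status, "REFERENCE")
  expect_equal(rc$called_base, "A")
  # strand bias: fwd majority G, rev majority A -> template retained
  sb <- call_position(c(G = 27, A = 3), c(A = 28), "A")
  expect_equal(sb$status, "STRAND_BIASED")
  expect_equal(sb$called_base, "A")
  expect_equal(unname(which.max(sb$fwd_probs)), 3)  # G
  expect_equal(unname(which.max(sb$rev_probs)), 1)  # A
  # concordant SNV with posteriors cross-checked by the arithmetic oracle
  snv <- call_position(c(G = 28, A = 2), c(G = 25, A = 3), "A")
  expect_equal(snv$status, "SNV")
  expect_equal(snv$called_base, "G")
  pf <- oracle_posterior(c(G = 28, A = 2), 0.1)
  pr <- oracle_posterior(c(G = 25, A = 3), 0.1)
  comb <- pf * pr / sum(pf * pr)
  expect_equal(unname(snv$posterior), unname(comb[["G"]]), tolerance = 1e-9)
  expect_gte(snv$posterior, 0.99)
  # low depth on either strand -> LOW_DEPTH, template retained
  ld <- call_position(c(G = 3), c(G = 25), "A", min_depth = 5)
  expect_equal(ld$status, "LOW_DEPTH")
  expect_equal(ld$called_base, "A")
  # within-strand argmax tie -> treated as discordant
  tie <- call_position(c(G = 10, T = 10), c(G = 10, T = 10), "A")
  expect_equal(tie$status, "STRAND_BIASED")
  # concordant deletions are callable (5th symbol)
  del <- call_position(c("-" = 18, A = 2), c("-" = 16, A = 1), "A")
  expect_equal(del$status, "SNV")
  expect_equal(del$called_base, "-")
  # subthreshold concordant alt stays REFERENCE with a flag
  sub <- call_position(c(G = 4, A = 3), c(G = 4, A = 3), "A", min_depth = 3,
                       tau = 0.999999999)
  expect_equal(sub$status, "REFERENCE")
  expect_equal(sub$flag, "subthreshold")
  expect_error(call_position(c(A = 1), c(A = 1), "A", tau = 0.4), "tau")
})

test_that("combined posterior rises monotonically with per-strand depth", {
  # fixed 90% alt fraction, depth grid 5..100
  post <- vapply(5:100, function(n) {
    ka <- round(0.9 * n); kr <- n - ka
    call_position(setNames(c(ka, kr), c("G", "A")),
                  setNames(c(ka, kr), c("G", "A")), "A",
                  min_depth = 1)$posterior
  }, numeric(1))
  expect_true(all(diff(post) > -1e-12))
  expect_gt(post[length(post)], post[1])
})

test_that("degenerate parameters behave safely", {
  # tau -> 1: any call with numerically resolvable uncertainty is
  # suppressed (a posterior saturating double precision is genuinely
  # above any representable tau < 1, so moderate evidence is the test)
  hi <- call_position(c(G = 3, A = 1), c(G = 3, A = 1), "A",
                      min_depth = 4, tau = 1 - 1e-12)
  expect_equal(hi$status, "REFERENCE")
  expect_equal(hi$flag, "subthreshold")
  lo <- call_position(c(G = 3, A = 1), c(G = 3, A = 1), "A",
                      min_depth = 4, tau = 0.99)
  expect_equal(lo$status, "SNV")
  # e -> 0.5 flattens the likelihood contrast monotonically
  contrast <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.49), function(e) {
    p <- strand_posterior(c(G = 18, A = 2), e)$probs
    p[["G"]] / p[["A"]]
  }, numeric(1))
  expect_true(all(diff(contrast) < 0))
})

test_that("call_sample finds a true SNV and nothing else", {
  set.seed(54)
  t <- random_dna(400)
  ref_ch <- strsplit(t, "")[[1]]
  alt <- pick_alt(ref_ch[201], include_del = FALSE)
  pu <- sim_pileup(t, 23, 23, error_model(0.07, 0.015, 0.015, seed = 7),
                   variants = list(true_variant(200, alt)))
  cs <- call_sample(pu, t)
  snv <- cs$calls[cs$calls$status == "SNV", ]
  expect_equal(nrow(snv), 1)
  expect_equal(snv$position, 200)
  expect_equal(snv$called_base, alt)
  expect_equal(nrow(cs$indels), 0)
  # noiseless, variant-free sample: zero SNVs, zero indels
  pu0 <- sim_pileup(t, 10, 10, error_model(0, 0, 0, seed = 1))
  cs0 <- call_sample(pu0, t)
  expect_equal(sum(cs0$calls$status == "SNV"), 0)
  expect_equal(nrow(cs0$indels), 0)
  expect_true(all(cs0$calls$status == "REFERENCE"))
})

test_that("single-strand systematic sites never become SNVs (naive does)", {
  # scaled-down version of the strand-bias rejection property; the full
  # 1000-replicate version runs in test-acceptance.R
  set.seed(55)
  n_rep <- 30
  n_package_false <- 0
  n_naive_hit <- 0
  for (r in 1:n_rep) {
    t <- random_dna(120)
    ref_ch <- strsplit(t, "")[[1]]
    sites <- place_single_strand_sites(ref_ch, 4, rate_range = c(0.85, 1))
    nf <- sample(10:50, 1); nr <- sample(10:50, 1)
    pu <- sim_pileup(t, nf, nr, error_model(0, 0, 0, seed = 7000 + r),
                     sites = sites, band_width = 12)
    cs <- call_sample(pu, t)
    n_package_false <- n_package_false + sum(cs$calls$status == "SNV")
    n_naive_hit <- n_naive_hit + (nrow(naive_consensus(pu, t)) >= 1)
  }
  expect_equal(n_package_false, 0)
  expect_gt(n_naive_hit, 0)   # the baseline comparator is fooled
})

test_that("concordant deletions merge into indel records", {
  set.seed(56)
  t <- random_dna(300)
  vars <- lapply(100:102, function(p) true_variant(p, "-"))
  pu <- sim_pileup(t, 20, 20, error_model(0, 0, 0, seed = 5),
                   variants = vars, band_width = 15)
  cs <- call_sample(pu, t)
  expect_equal(nrow(cs$indels), 1)
  expect_equal(cs$indels$type, "deletion")
  expect_equal(cs$indels$start, 100)
  expect_equal(cs$indels$length, 3)
})

test_that("vectorised call_sample equals scalar call_position everywhere", {
  set.seed(58)
  t <- random_dna(150)
  ref_ch <- strsplit(t, "")[[1]]
  pu <- sim_pileup(t, 8, 8, error_model(0.15, 0.05, 0.05, seed = 4),
                   sites = list(systematic_site(10, "forward",
                                                pick_alt(ref_ch[11]), 0.95)),
                   variants = list(true_variant(75, pick_alt(ref_ch[76],
                                                             FALSE))))
  cs <- call_sample(pu, t, e = 0.12, tau = 0.95, min_depth = 4)
  for (i in seq_len(150)) {
    vc <- call_position(pu$counts[i, 1, ], pu$counts[i, 2, ], ref_ch[i],
                        e = 0.12, tau = 0.95, min_depth = 4)
    row <- cs$calls[i, ]
    expect_equal(row$status, vc$status, info = paste("pos", i))
    expect_equal(row$called_base, vc$called_base, info = paste("pos", i))
    if (!is.na(vc$posterior)) {
      expect_equal(row$posterior, unname(vc$posterior), tolerance = 1e-9)
    } else {
      expect_true(is.na(row$posterior))
    }
  }
})

test_that("error-rate self-calibration recovers the simulated rate", {
  set.seed(57)
  t <- random_dna(500)
  pu <- sim_pileup(t, 30, 30, error_model(0.07, 0.015, 0.015, seed = 2))
  e_hat <- estimate_error_rate(pu)
  expect_gt(e_hat, 0.03)
  expect_lt(e_hat, 0.2)
})
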