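test_that("identical sequences align gap-free with full match score", {
  t <- random_dna(150)
  a <- align_read(t, t)
  expect_equal(a$score, 2 * 150)
  expect_true(all(a$ops$op == "M"))
  expect_equal(a$ops$tpos, 0:149)
  expect_equal(a$ops$rpos, 0:149)
})

test_that("a single deletion yields one gap at the right position", {
  set.seed(41)
  t <- random_dna(120)
  read <- paste0(substr(t, 1, 60), substr(t, 62, 120))  # drop 0-based 60
  a <- align_read(read, t)
  expect_equal(sum(a$ops$op == "D"), 1)
  expect_equal(a$ops$tpos[a$ops$op == "D"], 60)
  expect_equal(a$score, oracle_align_score(t, read))
})

test_that("banded score equals the unbanded full-DP oracle", {
  set.seed(42)
  for (i in 1:50) {
    n1 <- sample(40:200, 1)
    t <- random_dna(n1)
    # mutate a copy of the target into the read
    ch <- strsplit(t, "")[[1]]
    nmut <- sample(0:12, 1)
    for (m in seq_len(nmut)) {
      p <- sample(length(ch), 1)
      ch[p] <- switch(sample(3, 1),
                      sample(c("A", "C", "G", "T"), 1),     # substitution
                      paste0(ch[p], sample(c("A", "C", "G", "T"), 1)), # ins
                      "")                                   # deletion
    }
    read <- paste(ch, collapse = "")
    if (!nzchar(read)) next
    band <- abs(nchar(read) - n1) + 30
    a <- align_read(read, t, band_width = band)
    expect_equal(a$score, oracle_align_score(t, read),
                 info = paste("case", i))
    # target positions strictly increasing over M/D ops
    tp <- a$ops$tpos[a$ops$op != "I"]
    expect_true(all(diff(tp) > 0))
  }
})

test_that("band auto-widens and errors when hopeless", {
  t <- random_dna(200)
  # read with a 40 nt deletion: band 5 is too narrow but doubling to 20
  # still fails; 4x cap -> error
  read <- paste0(substr(t, 1, 80), substr(t, 121, 200))
  expect_equal(align_read(read, t, band_width = 45)$score,
               oracle_align_score(t, read))
  a_narrow <- align_read(read, t, band_width = 15)  # doubles to 60, succeeds
  expect_equal(a_narrow$score, oracle_align_score(t, read))
  expect_error(align_read("A", "", band_width = 10), "non-empty")
})

test_that("identify_target picks the source target with a margin", {
  set.seed(43)
  targets <- c(tA = random_dna(150), tB = random_dna(150),
               tC = random_dna(150))
  reads <- simulate_reads(targets[["tB"]], NULL, 1, 1,
                          model = error_model(0.07, 0.015, 0.015, seed = 3))
  hit <- identify_target(reads$seq[1], targets)
  expect_equal(hit$target_id, "tB")
  expect_gt(hit$margin, 0)
  expect_false(hit$ambiguous)
  # reverse-strand read identified via its orientation
  hit2 <- identify_target(reads$seq[2], targets)
  expect_equal(hit2$target_id, "tB")
  expect_equal(hit2$orientation, "reverse")
  # single target -> infinite margin; identical targets -> ambiguous
  one <- identify_target(reads$seq[1], targets["tB"])
  expect_equal(one$margin, Inf)
  dup <- identify_target(reads$seq[1], c(x = targets[["tB"]],
                                         y = targets[["tB"]]))
  expect_true(dup$ambiguous)
})

test_that("pileup counts one perfect read correctly and conserves counts", {
  t <- random_dna(80)
  ref_ch <- strsplit(t, "")[[1]]
  a <- align_read(t, t, strand = "forward")
  pu <- build_pileup(list(a), t)
  for (i in seq_len(80)) {
    expect_equal(unname(pu$counts[i, "fwd", ref_ch[i]]), 1L)
  }
  expect_equal(sum(pu$counts), 80L)
  expect_equal(sum(pu$counts[, "rev", ]), 0L)
  # conservation on noisy alignments: total pileup mass equals the total
  # M + D ops across alignments
  set.seed(44)
  reads <- simulate_reads(t, NULL, 6, 6,
                          model = error_model(0.08, 0.02, 0.02, seed = 8))
  truth <- attr(reads, "truth")
  alns <- lapply(seq_len(nrow(reads)), function(i) {
    s <- if (truth$strand[i] == "reverse") revcomp(reads$seq[i]) else
      reads$seq[i]
    align_read(s, t, strand = truth$strand[i])
  })
  pu2 <- build_pileup(alns, t)
  expect_equal(sum(pu2$counts),
               sum(vapply(alns, function(a) sum(a$ops$op != "I"),
                          numeric(1))))
  # permuting read order leaves the pileup unchanged
  pu3 <- build_pileup(rev(alns), t)
  expect_identical(pu2$counts, pu3$counts)
  expect_equal(pu2$insertions, pu3$insertions)
})

test_that("systematic sites show up on one strand of the pileup only", {
  set.seed(45)
  t <- random_dna(150)
  ref_ch <- strsplit(t, "")[[1]]
  alt <- pick_alt(ref_ch[71], include_del = FALSE)
  pu <- sim_pileup(t, 30, 30, error_model(0, 0, 0, seed = 10),
                   sites = list(systematic_site(70, "forward", alt, 0.9)))
  kf <- unname(pu$counts[71, "fwd", alt])
  expect_gt(kf, 30 * 0.9 - 3 * sqrt(30 * 0.9 * 0.1))   # ~27
  expect_equal(unname(pu$counts[71, "rev", alt]), 0L)
  expect_equal(unname(pu$counts[71, "rev", ref_ch[71]]), 30L)
})

test_that("import_sam walks CIGARs and skips unusable records", {
  t <- "ACGTACGTACGTACGTACGT"                # 20 nt
  r1 <- "ACGTTCGTACGTACGTACGT"               # mismatch at pos 5 (A->T)
  r2 <- paste0(substr(t, 1, 10), substr(t, 13, 20))  # 2 nt deletion at 11-12
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:target\tLN:20",
    paste("r1", 0, "target", 1, 60, "20M", "*", 0, 0, r1,
          strrep("I", 20), sep = "\t"),
    paste("r2", 16, "target", 1, 60, "10M2D8M", "*", 0, 0, r2,
          strrep("I", 18), sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, "ACGT", "IIII", sep = "\t"),
    paste("r4", 0, "target", 1, 60, "*", "*", 0, 0, "ACGT", "IIII",
          sep = "\t"))
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  expect_warning(pu <- import_sam(path, t, "target"), "skipped")
  expect_equal(attr(pu, "n_skipped"), 1L)    # r4 only; r3 is unmapped
  expect_equal(unname(pu$counts[5, "fwd", "T"]), 1L)  # the r1 mismatch
  expect_equal(unname(pu$counts[5, "fwd", "A"]), 0L)
  expect_equal(unname(pu$counts[11, "rev", "-"]), 1L) # r2 deletion
  expect_equal(unname(pu$counts[12, "rev", "-"]), 1L)
  expect_equal(unname(pu$counts[1, "fwd", "A"]), 1L)
  expect_equal(unname(pu$counts[1, "rev", "A"]), 1L)
  expect_equal(sum(pu$counts), 20L + 18L + 2L)
  # empty SAM -> empty pileup
  writeLines(c("@HD\tVN:1.6"), path)
  pu0 <- import_sam(path, t, "target")
  expect_equal(sum(pu0$counts), 0L)
})

test_that("import_sam matches build_pileup on equivalent alignments", {
  set.seed(47)
  t <- random_dna(60)
  # pin distinct bases around the deletion so the gap placement is unique
  substr(t, 30, 32) <- "ACG"
  read <- paste0(substr(t, 1, 30), substr(t, 32, 60))  # deletion at 0-based 30
  a <- align_read(read, t, strand = "forward")
  pu_int <- build_pileup(list(a), t)
  sam <- c("@SQ\tSN:target\tLN:60",
           paste("r1", 0, "target", 1, 60, "30M1D29M", "*", 0, 0, read,
                 strrep("I", 59), sep = "\t"))
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  pu_sam <- import_sam(path, t, "target")
  expect_identical(pu_int$counts, pu_sam$counts)
})

test_that("pileup serialization round-trips through TSV", {
  set.seed(46)
  t <- random_dna(90)
  pu <- sim_pileup(t, 8, 8, error_model(0.08, 0.02, 0.02, seed = 17))
  path <- withr::local_tempfile(fileext = ".tsv")
  ipath <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(pu, path, ipath)
  back <- read_pileup(path, ipath)
  expect_identical(back$counts, pu$counts)
  expect_equal(paste(back$ref, collapse = ""), t)
  if (nrow(pu$insertions)) {
    expect_equal(back$insertions$tpos, pu$insertions$tpos)
    expect_equal(back$insertions$count, pu$insertions$count)
  }
})
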