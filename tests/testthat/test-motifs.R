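consensus_pwm <- function(word, id = "M") {
  m <- t(vapply(strsplit(word, "")[[1]], function(b) {
    v <- rep(0, 4)
    v[match(b, c("A", "C", "G", "T"))] <- 1
    v
  }, numeric(4)))
  rownames(m) <- NULL
  pwm(id, m)
}

test_that("PWM scanning scores log-odds windows on both strands", {
  p <- consensus_pwm("ACGT")
  r <- scan_sequence("AAACGTAA", p, score_min = 0)
  expect_true(r$has_hit)
  # forward hit at 0-based position 2; ACGT is its own reverse complement,
  # so the same window also matches on the minus strand
  expect_equal(r$hits$pos, c(2, 2))
  expect_setequal(r$hits$strand, c("+", "-"))

  expect_false(scan_sequence("TTTTTTTT", p, score_min = 0)$has_hit)
  expect_error(scan_sequence("ACG", p), "shorter")
  # windows containing ambiguous bases never match
  expect_false(scan_sequence("AANCGTAA", p, score_min = 0)$has_hit)
  expect_true(scan_sequence("ANACGTAA", p, score_min = 0)$has_hit)

  # presence is invariant under reverse-complementing the sequence
  set.seed(55)
  p6 <- consensus_pwm("ACGTTG")
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
  }
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    expect_equal(scan_sequence(s, p6)$has_hit,
                 scan_sequence(rc(s), p6)$has_hit)
  }
})

test_that("scanning agrees with brute-force window scoring", {
  set.seed(66)
  p <- consensus_pwm("ACGTAC")
  smin <- 0.6 * pwm_max_score(p)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    expect_equal(scan_sequence(s, p, smin)$has_hit,
                 oracle_scan_hit(s, p, smin))
  }
})

test_that("PWM construction validates and converts counts", {
  cm <- matrix(c(8, 0, 0, 2,
                 0, 10, 0, 0), 2, 4, byrow = TRUE)
  p <- pwm("x", cm)
  expect_equal(unname(rowSums(p$mat)), c(1, 1))
  expect_equal(unname(p$mat[1, "A"]), 0.8)
  expect_error(pwm("x", cm[, 1:3]), "4 columns")
  expect_error(pwm("x", -cm), "non-negative")
  expect_error(pwm("x", cm, background = c(1, 1, 1, 1)), "sum to 1")
  expect_gt(pwm_max_score(p), 0)
})

test_that("JASPAR and MEME-minimal parsers read matrices faithfully", {
  tmp <- withr::local_tempdir()
  jp <- file.path(tmp, "m.jaspar")
  writeLines(c(
    ">MA0001.1 TEST",
    "A [ 4  0 19 ]",
    "C [12  0  1 ]",
    "G [ 0 20  0 ]",
    "T [ 4  0  0 ]"), jp)
  pj <- read_jaspar(jp)
  expect_named(pj, "MA0001.1")
  expect_equal(unname(pj[[1]]$mat[, "A"]), c(4, 0, 19) / 20)
  expect_equal(unname(pj[[1]]$mat[2, "G"]), 1)

  mm <- file.path(tmp, "m.meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF motif_1", "",
    "letter-probability matrix: alength= 4 w= 2 nsites= 10",
    " 0.5 0.1 0.2 0.2",
    " 0.0 0.0 1.0 0.0"), mm)
  pm <- read_meme(mm)
  expect_named(pm, "motif_1")
  expect_equal(unname(pm[[1]]$background), c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(pm[[1]]$mat[1, ]), c(0.5, 0.1, 0.2, 0.2))
})

test_that("motif enrichment applies the upper-tail binomial with per-signature
           BH adjustment", {
  p <- consensus_pwm("ACGTAC")
  with_hit <- function(n) {
    vapply(seq_len(n), function(i) {
      paste0(paste(rep("T", 10), collapse = ""), "ACGTAC",
             paste(rep("T", 10), collapse = ""))
    }, character(1))
  }
  without_hit <- function(n) rep(paste(rep("T", 26), collapse = ""), n)
  fg <- list(sigA = c(with_hit(8), without_hit(2)))
  bg <- c(with_hit(20), without_hit(80))
  rec <- motif_enrichment(fg, bg, list(p))
  expect_equal(rec$k_fg, 8)
  expect_equal(rec$k_bg, 20)
  expect_equal(rec$p_value,
               stats::pbinom(7, 10, 0.2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(rec$p_value, 7.79e-5, tolerance = 1e-2)
  expect_true(rec$enriched)

  # at the background rate the test is not significant
  fg2 <- list(sigA = c(with_hit(2), without_hit(8)))
  rec2 <- motif_enrichment(fg2, bg, list(p))
  expect_gt(rec2$p_value, 0.4)
  # zero foreground hits: upper tail is 1
  rec3 <- motif_enrichment(list(sigA = without_hit(5)), bg, list(p))
  expect_equal(rec3$p_value, 1)
  expect_false(rec3$enriched)

  # exact hypergeometric alternative matches phyper directly
  rec4 <- motif_enrichment(fg, bg, list(p), method = "hypergeometric")
  expect_equal(rec4$p_value,
               stats::phyper(7, 28, 82, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(motif_enrichment(fg, character(), list(p)), "non-empty")
})

test_that("selective motifs are enriched in at most the allowed number of
           signatures", {
  rec <- data.frame(
    motif = rep(c("m1", "m2", "m3", "m4"), each = 3),
    signature = rep(c("s1", "s2", "s3"), 4),
    enriched = c(TRUE, FALSE, FALSE,   # m1: 1 signature
                 TRUE, TRUE, FALSE,    # m2: 2
                 TRUE, TRUE, TRUE,     # m3: 3
                 FALSE, FALSE, FALSE)) # m4: 0
  sel <- selective_motifs(rec, max_signatures = 2)
  expect_setequal(names(sel), c("m1", "m2"))
  expect_equal(sel$m2, c("s1", "s2"))

  # random flag tables against a direct per-motif count filter
  set.seed(70)
  for (i in 1:5) {
    r2 <- data.frame(motif = rep(paste0("m", 1:6), each = 4),
                     signature = rep(paste0("s", 1:4), 6),
                     enriched = sample(c(TRUE, FALSE), 24, replace = TRUE))
    sel2 <- selective_motifs(r2, max_signatures = 2)
    cnt <- tapply(r2$enriched, r2$motif, sum)
    expect_setequal(names(sel2), names(cnt)[cnt >= 1 & cnt <= 2])
  }
})

test_that("sequence shuffles preserve the intended composition", {
  set.seed(81)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                    prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  dinucs <- function(x) {
    ch <- strsplit(x, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  sh <- shuffle_sequences(s, method = "dinucleotide")
  expect_false(sh == s) # astronomically unlikely to be identical
  expect_equal(dinucs(sh), dinucs(s))
  sh2 <- shuffle_sequences(s, method = "mononucleotide")
  expect_equal(table(strsplit(sh2, "")[[1]]), table(strsplit(s, "")[[1]]))
})

test_that("FASTA round-trips through Biostrings wrappers", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(one = "ACGTACGT", two = "TTTTAAAA")
  write_fasta(seqs, tmp)
  expect_equal(read_fasta(tmp), seqs)
})
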