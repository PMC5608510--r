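test_that("peak-to-TSS assignment follows the midpoint distance rule", {
  ann <- gene_annotation("g1", "chr1", "+", 400000,
                         400000, 400600)
  pk <- peak_set("chr1", 140000, 160000)
  asg <- assign_peaks_to_tss(pk, ann, window = 300000)
  expect_equal(nrow(asg), 1)
  expect_equal(asg$distance, -250000)
  expect_equal(asg$tss, 400000)

  # boundary is inclusive: midpoint exactly `window` away still assigns
  pk2 <- peak_set("chr1", 99999, 100001) # midpoint 100000
  expect_equal(nrow(assign_peaks_to_tss(pk2, ann, window = 300000)), 1)
  pk3 <- peak_set("chr1", 99997, 99999) # midpoint 99998, 2 bp too far
  expect_equal(nrow(assign_peaks_to_tss(pk3, ann, window = 300000)), 0)

  # strand orientation flips the reported distance sign
  ann_m <- gene_annotation("g1", "chr1", "-", 400000, 399400, 400000)
  expect_equal(assign_peaks_to_tss(pk, ann_m, window = 300000)$distance,
               250000)

  # peaks on chromosomes missing from the annotation are skipped + warned
  pk4 <- peak_set(c("chr1", "chrX"), c(140000, 10), c(160000, 400))
  expect_warning(asg4 <- assign_peaks_to_tss(pk4, ann, window = 300000),
                 "chrX")
  expect_equal(nrow(asg4), 1)
})

test_that("assignment equals the all-pairs oracle, including multi-TSS genes", {
  set.seed(101)
  for (rep in 1:3) {
    pk <- random_peaks(60, max_pos = 5e4)
    ann <- random_annotation(12, max_pos = 5e4, multi_tss = TRUE)
    got <- assign_peaks_to_tss(pk, ann, window = 8000)
    want <- oracle_assign(pk, ann, window = 8000)
    key <- function(d) {
      if (nrow(d) == 0) return(character())
      sort(paste(d$peak, d$gene_id, d$tss, d$distance))
    }
    expect_identical(key(got), key(want))
  }
  # and it is invariant under input reordering
  set.seed(5)
  pk <- random_peaks(40, max_pos = 5e4)
  ann <- random_annotation(8, max_pos = 5e4)
  a1 <- assign_peaks_to_tss(pk, ann, window = 8000)
  a2 <- assign_peaks_to_tss(pk[rev(seq_len(nrow(pk))), ], ann, window = 8000)
  srt <- function(d) d[order(d$peak, d$gene_id, d$tss), ]
  expect_equal(srt(a1)$distance, srt(a2)$distance)
})

test_that("target nomination is the cross-match of assignments and lists", {
  asg <- data.frame(peak = c("p1", "p2", "p3"),
                    gene_id = c("g1", "g2", "g3"),
                    tss = 0, distance = 0)
  lists <- list(c("g2", "g3"), "g3")
  expect_equal(nominate_targets(asg, lists, min_lists = 1), c("g2", "g3"))
  expect_equal(nominate_targets(asg, lists, min_lists = 2), "g3")
  expect_error(nominate_targets(asg, list()), "non-empty")

  # random instance vs brute-force membership counting
  set.seed(7)
  genes <- paste0("g", 1:100)
  asg2 <- data.frame(peak = paste0("p", 1:70),
                     gene_id = sample(genes, 70, replace = TRUE),
                     tss = 0, distance = 0)
  ls <- replicate(5, sample(genes, 40), simplify = FALSE)
  for (ml in 1:4) {
    brute <- sort(Filter(function(g) {
      g %in% asg2$gene_id && sum(vapply(ls, function(l) g %in% l, TRUE)) >= ml
    }, genes))
    expect_equal(nominate_targets(asg2, ls, min_lists = ml), brute)
  }
})

test_that("peak location categories partition peaks with stated precedence", {
  ann <- gene_annotation("g1", "chr1", "+", 10000,
                         "10000,12000", "10500,12400")
  # midpoint in exon 2, outside promoter [7000, 10500]
  expect_equal(categorize_peak_locations(peak_set("chr1", 12100, 12300), ann),
               c(promoter = 0L, exon = 1L, intron = 0L, intergenic = 0L))
  # intron: inside gene span, no exon, no promoter
  expect_equal(
    categorize_peak_locations(peak_set("chr1", 11000, 11200), ann)[["intron"]],
    1L)
  # far upstream of every TSS and outside gene bodies -> intergenic
  expect_equal(
    categorize_peak_locations(peak_set("chr1", 100, 300), ann)[["intergenic"]],
    1L)
  # promoter wins over exon (exon starting at the TSS)
  expect_equal(
    categorize_peak_locations(peak_set("chr1", 10050, 10150), ann)[["promoter"]],
    1L)

  # randomized instances against the per-peak membership oracle
  set.seed(31)
  for (rep in 1:3) {
    pk <- random_peaks(40, max_pos = 4e4)
    ann2 <- random_annotation(5, max_pos = 4e4)
    got <- categorize_peak_locations(pk, ann2)
    expect_equal(got, oracle_categorize(pk, ann2))
    expect_equal(sum(got), nrow(pk))
  }
})

test_that("overlap fraction counts peaks in A hitting any peak in B", {
  A <- peak_set("chr1", c(0, 200, 500), c(100, 300, 600))
  B <- peak_set("chr1", c(250, 590), c(260, 700))
  expect_equal(overlap_fraction(A, B), 2 / 3)
  expect_equal(overlap_fraction(A, A), 1.0)
  expect_equal(overlap_fraction(A, peak_set("chr2", 0, 100)), 0.0)
  expect_warning(z <- overlap_fraction(peak_set(character(), numeric(),
                                                numeric()), A), "empty")
  expect_equal(z, 0)

  # invariant under record shuffling and under splitting a B interval
  set.seed(13)
  for (rep in 1:3) {
    A2 <- random_peaks(50)
    B2 <- random_peaks(50)
    f <- overlap_fraction(A2, B2)
    expect_equal(f, oracle_overlap_fraction(A2, B2))
    expect_equal(overlap_fraction(A2[sample(nrow(A2)), ],
                                  B2[sample(nrow(B2)), ]), f)
    # split the first B interval into two adjacent halves
    b1 <- B2[1, ]
    mid <- floor((b1$start + b1$end) / 2)
    if (mid > b1$start && mid < b1$end) {
      Bs <- rbind(data.frame(chrom = b1$chrom, start = b1$start, end = mid,
                             name = "x1", score = 0, strand = "."),
                  data.frame(chrom = b1$chrom, start = mid, end = b1$end,
                             name = "x2", score = 0, strand = "."),
                  B2[-1, ])
      expect_equal(overlap_fraction(A2, Bs), f)
    }
  }
})

test_that("peak extension pads symmetrically and clips at bounds", {
  sizes <- c(chr1 = 1e6)
  p <- extend_peaks(peak_set("chr1", 5000, 6000), 1000, sizes)
  expect_equal(c(p$start, p$end), c(4000, 7000))
  p2 <- extend_peaks(peak_set("chr1", 300, 500), 1000, sizes)
  expect_equal(c(p2$start, p2$end), c(0, 1500))
  p3 <- extend_peaks(peak_set("chr1", 999500, 999900), 1000, sizes)
  expect_equal(p3$end, 1e6)
  pk <- peak_set("chr1", c(10, 50), c(20, 80))
  expect_identical(extend_peaks(pk, 0, sizes), pk)
  expect_error(extend_peaks(peak_set("chr9", 10, 20), 100, sizes), "chr9")
})

test_that("BED and annotation tables round-trip through disk", {
  tmp <- withr::local_tempdir()
  pk <- peak_set(c("chr1", "chr2"), c(100, 0), c(900, 50),
                 name = c("a", "b"), score = c(1, 2), strand = c("+", "."))
  bed <- file.path(tmp, "x.bed")
  write_bed(pk, bed)
  back <- read_bed(bed)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$name, pk$name)

  ann <- random_annotation(4)
  tsv <- file.path(tmp, "ann.tsv")
  write_gene_annotation(ann, tsv)
  expect_equal(read_gene_annotation(tsv), ann)

  writeLines(c("chr1\t1000", "chr2\t2000"), file.path(tmp, "c.sizes"))
  expect_equal(read_chrom_sizes(file.path(tmp, "c.sizes")),
               c(chr1 = 1000, chr2 = 2000))
})
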