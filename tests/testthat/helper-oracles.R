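# Brute-force reference implementations used to validate the package's
# interval, overlap and statistical operations. These deliberately use
# naive loops / exhaustive enumeration, independent of the code under test.

# all-pairs peak-to-TSS assignment by direct distance arithmetic
oracle_assign <- function(peaks, annotation, window) {
  tss <- tss_table(annotation)
  out <- data.frame(peak = character(), gene_id = character(),
                    tss = numeric(), distance = numeric())
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    for (j in seq_len(nrow(tss))) {
      if (peaks$chrom[i] != tss$chrom[j]) next
      raw <- mid - tss$tss[j]
      if (abs(raw) <= window) {
        out <- rbind(out, data.frame(
          peak = peaks$name[i], gene_id = tss$gene_id[j], tss = tss$tss[j],
          distance = if (tss$strand[j] == "-") -raw else raw))
      }
    }
  }
  out
}

# per-interval pairwise intersection check
oracle_overlap_fraction <- function(A, B) {
  if (nrow(A) == 0) return(0)
  hit <- vapply(seq_len(nrow(A)), function(i) {
    any(B$chrom == A$chrom[i] & B$start < A$end[i] & B$end > A$start[i])
  }, logical(1))
  mean(hit)
}

# per-peak membership check with promoter > exon > intron > intergenic
oracle_categorize <- function(peaks, annotation, up = 3000, dn = 500) {
  tss <- tss_table(annotation)
  ex <- coregdep:::exon_table(annotation)
  span <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
    data.frame(chrom = e$chrom[1], start = min(e$start), end = max(e$end))
  }))
  cats <- vapply(seq_len(nrow(peaks)), function(i) {
    m <- floor((peaks$start[i] + peaks$end[i]) / 2)
    ch <- peaks$chrom[i]
    in_prom <- FALSE
    for (j in seq_len(nrow(tss))) {
      if (tss$chrom[j] != ch) next
      u <- if (tss$strand[j] == "-") dn else up
      d <- if (tss$strand[j] == "-") up else dn
      if (m >= tss$tss[j] - u && m <= tss$tss[j] + d) in_prom <- TRUE
    }
    if (in_prom) return("promoter")
    if (nrow(ex) && any(ex$chrom == ch & m >= ex$start & m < ex$end))
      return("exon")
    if (!is.null(span) && nrow(span) &&
        any(span$chrom == ch & m >= span$start & m < span$end))
      return("intron")
    "intergenic"
  }, character(1))
  out <- table(factor(cats, levels = c("promoter", "exon", "intron",
                                       "intergenic")))
  stats::setNames(as.integer(out), names(out))
}

# exhaustive enumeration of the hypergeometric upper tail:
# draw n of N, K marked; P(overlap >= k) by listing every draw
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= K)
  mean(ov >= k)
}

# textbook pooled two-sample t
oracle_pooled_t <- function(a, b) {
  nA <- length(a); nB <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (nA + nB - 2)
  t <- (mean(a) - mean(b)) / sqrt(s2 * (1 / nA + 1 / nB))
  list(log2fc = mean(a) - mean(b), t = t,
       p = 2 * stats::pt(-abs(t), nA + nB - 2))
}

# exhaustive per-window PWM scoring (both strands)
oracle_scan_hit <- function(seq, p, score_min) {
  lom <- coregdep:::pwm_log_odds(p)
  L <- nrow(lom)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(toupper(seq), "")[[1]]
  score_word <- function(word) {
    idx <- match(word, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(-Inf)
    sum(lom[cbind(seq_len(L), idx)])
  }
  for (i in seq_len(length(chars) - L + 1)) {
    w <- chars[i:(i + L - 1)]
    if (score_word(w) >= score_min) return(TRUE)
    rc <- rev(unname(comp[w]))
    if (!anyNA(rc) && score_word(rc) >= score_min) return(TRUE)
  }
  FALSE
}

# step-by-step average-linkage agglomeration on a distance matrix
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  d_between <- function(a, b) mean(d[a, b])
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    ids <- which(active[seq_along(clusters)])
    for (x in seq_along(ids)) {
      for (y in seq_len(x - 1)) {
        h <- d_between(clusters[[ids[x]]], clusters[[ids[y]]])
        if (h < best) { best <- h; bi <- ids[y]; bj <- ids[x] }
      }
    }
    heights[step] <- best
    clusters[[length(clusters) + 1]] <- c(clusters[[bi]], clusters[[bj]])
    active[c(bi, bj)] <- FALSE
    active[length(clusters)] <- TRUE
  }
  heights
}

# random peak set generator for property tests
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                         max_width = 500) {
  if (n == 0) return(peak_set(character(), numeric(), numeric()))
  start <- floor(stats::runif(n, 0, max_pos))
  peak_set(chrom = sample(chroms, n, replace = TRUE),
           start = start,
           end = start + 1 + floor(stats::runif(n, 0, max_width)))
}

# random small annotation for property tests
random_annotation <- function(n_genes, chroms = c("chr1", "chr2"),
                              max_pos = 1e5, multi_tss = FALSE) {
  tss <- lapply(seq_len(n_genes), function(i) {
    t1 <- floor(stats::runif(1, 5000, max_pos - 5000))
    if (multi_tss && stats::runif(1) < 0.4)
      sort(c(t1, t1 + sample(1000:4000, 1))) else t1
  })
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  ex <- lapply(seq_len(n_genes), function(i) {
    t1 <- tss[[i]][1]
    s <- t1 + c(0, 800, 2000)
    list(starts = s, ends = s + c(300, 400, 250))
  })
  gene_annotation(gene_id = paste0("g", seq_len(n_genes)),
                  chrom = sample(chroms, n_genes, replace = TRUE),
                  strand = strand, tss = tss,
                  exon_starts = lapply(ex, `[[`, "starts"),
                  exon_ends = lapply(ex, `[[`, "ends"))
}
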