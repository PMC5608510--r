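test_that("hypergeometric overlap matches exhaustive enumeration", {
  u <- paste0("g", 1:10)
  st <- hypergeometric_overlap(u[1:4], u[c(1, 2, 3, 5, 6)], u)
  expect_equal(st$p_value, 66 / 252, tolerance = 1e-12)
  # empty overlap is certain: P(X >= 0) = 1
  expect_equal(hypergeometric_overlap(u[1:2], u[3:4], u)$p_value, 1)
  # A = universe forces the overlap
  expect_equal(hypergeometric_overlap(u, u[1:5], u)$p_value, 1)
  expect_error(hypergeometric_overlap(c(u[1], "zz"), u[1:2], u), "zz")

  # sweep of small universes against the enumeration oracle
  for (N in c(2, 5, 8, 12)) {
    univ <- paste0("x", seq_len(N))
    for (K in 0:N) {
      for (n in 0:N) {
        a <- univ[seq_len(K)]
        b <- univ[rev(seq_len(N))[seq_len(n)]]
        got <- hypergeometric_overlap(a, b, univ)
        expect_equal(got$p_value,
                     oracle_hyper_tail(N, K, n, got$k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("pairwise overlap matrices cover all unordered pairs", {
  set.seed(3)
  u <- paste0("g", 1:60)
  mk <- function(lbl) {
    g <- sample(u, sample(10:30, 1))
    signed_gene_set(g, sample(c("increased", "decreased"), length(g),
                              replace = TRUE), lbl)
  }
  sets17 <- stats::setNames(lapply(paste0("CR", 1:17), mk), paste0("CR", 1:17))
  ov <- pairwise_overlap_matrix(sets17, u)
  expect_equal(ov$n_pairs, 136L)

  sets2 <- sets17[1:2]
  expect_equal(pairwise_overlap_matrix(sets2, u)$n_pairs, 1L)

  sets3 <- sets17[1:3]
  ov3 <- pairwise_overlap_matrix(sets3, u, alpha = c(0.05, 0.01))
  expect_true(isSymmetric(ov3$counts))
  for (i in 1:3) expect_equal(ov3$counts[i, i], nrow(sets3[[i]]))
  for (i in 1:2) for (j in (i + 1):3) {
    direct <- hypergeometric_overlap(sets3[[i]], sets3[[j]], u)
    expect_equal(ov3$p[i, j], direct$p_value)
    expect_equal(ov3$counts[i, j], direct$k)
  }
  dup <- sets2
  names(dup) <- c("A", "A")
  expect_error(pairwise_overlap_matrix(dup, u), "unique")
})

test_that("directionality consistency reports conditional percentages", {
  A <- signed_gene_set(c("x", "y"), "increased", "A")
  B <- signed_gene_set(c("x", "y"), c("increased", "decreased"), "B")
  r <- directionality_consistency(A, B)
  expect_equal(r$pct_a_increased_in_b_increased, 50)
  expect_equal(r$n_overlap, 2)
  expect_equal(r$n_consistent, 1)
  expect_equal(r$n_opposite, 1)

  r2 <- directionality_consistency(A, A)
  expect_equal(r2$pct_a_increased_in_b_increased, 100)
  expect_equal(r2$pct_b_increased_in_a_increased, 100)
  # no decreased genes: the decreased percentages are undefined
  expect_true(is.nan(r2$pct_a_decreased_in_b_decreased))

  # random sets against a direct tally
  set.seed(15)
  u <- paste0("g", 1:50)
  ga <- sample(u, 30); gb <- sample(u, 25)
  A2 <- signed_gene_set(ga, sample(c("increased", "decreased"), 30, TRUE))
  B2 <- signed_gene_set(gb, sample(c("increased", "decreased"), 25, TRUE))
  r3 <- directionality_consistency(A2, B2)
  ai <- A2$gene[A2$direction == "increased"]
  ai_in_b <- ai[ai %in% B2$gene]
  expect_equal(r3$pct_a_increased_in_b_increased,
               100 * mean(B2$direction[match(ai_in_b, B2$gene)] ==
                            "increased"))
  shared <- intersect(ga, gb)
  expect_equal(r3$n_overlap, length(shared))
  expect_equal(r3$n_consistent + r3$n_opposite, length(shared))
})

test_that("effect correlations follow the covariance formula and tolerate
           zero-variance columns", {
  set.seed(19)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("c", 1:4)))
  m[, 2] <- m[, 1]
  m[, 3] <- -m[, 1]
  r <- effect_correlation(m)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  pear <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(r[1, 4], pear(m[, 1], m[, 4]), tolerance = 1e-12)

  m2 <- m
  m2[, 2] <- 5
  expect_warning(r2 <- effect_correlation(m2), "zero-variance")
  expect_true(all(r2[2, -2] == 0))
  expect_equal(r2[2, 2], 1)
})

test_that("pair combination keeps the highest-correlated pairs and
           reconciles direction tags", {
  sets <- list(
    A = signed_gene_set(c("g1", "g2"), c("increased", "decreased")),
    B = signed_gene_set(c("g2", "g3"), c("increased", "increased")),
    C = signed_gene_set("g4", "decreased"))
  corr <- matrix(c(1, 0.8, 0.1,
                   0.8, 1, 0.3,
                   0.1, 0.3, 1), 3, 3,
                 dimnames = list(names(sets), names(sets)))
  merged <- combine_pairs(corr, sets, r_min = 0.25)
  expect_length(merged, 2)
  expect_equal(attr(merged[[1]], "pair"), c("A", "B"))
  expect_equal(attr(merged[[1]], "r"), 0.8)
  m1 <- merged[[1]]
  expect_setequal(m1$gene, c("g1", "g2", "g3"))
  # g2 conflicts between parents -> NA tag; g1/g3 keep their parent's tag
  expect_true(is.na(m1$direction[m1$gene == "g2"]))
  expect_equal(m1$direction[m1$gene == "g1"], "increased")

  # column reordering leaves the merged output unchanged
  perm <- c("C", "A", "B")
  merged2 <- combine_pairs(corr[perm, perm], sets, r_min = 0.25)
  expect_equal(lapply(merged2, function(s) s[order(s$gene), ]$direction),
               lapply(merged, function(s) s[order(s$gene), ]$direction))
  expect_equal(vapply(merged2, attr, 0, "r"),
               vapply(merged, attr, 0, "r"))
})

test_that("gene clustering is average linkage on 1 - Pearson distance", {
  m <- rbind(g1 = c(1, -1, 1, -1),
             g2 = c(1, -1, 1, -1),
             g3 = c(-1, 1, -1, 1))
  cl <- cluster_genes(m)
  # identical profiles merge first at height 0
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))

  set.seed(44)
  m2 <- matrix(sample(c(-1, 0, 1), 24, replace = TRUE), 6, 4)
  m2 <- m2 + matrix(rnorm(24, sd = 0.01), 6, 4) # break exact ties
  cl2 <- cluster_genes(m2)
  d <- 1 - stats::cor(t(m2))
  diag(d) <- 0
  expect_equal(cl2$hclust$height,
               oracle_average_linkage_heights(d), tolerance = 1e-12)

  # row permutation relabels leaves but preserves the tree heights
  perm <- sample(6)
  cl3 <- cluster_genes(m2[perm, ])
  expect_equal(cl3$hclust$height, cl2$hclust$height, tolerance = 1e-12)

  # constant-profile genes are flagged and kept at distance 1
  m3 <- rbind(m2, g7 = rep(1, 4))
  expect_warning(cl4 <- cluster_genes(m3), "constant")
  expect_equal(unname(cl4$constant), 7L)

  expect_error(cluster_genes(rbind(c(1, 1), c(2, 2))), "non-constant")

  # newick export round-trips through ape
  tmp <- withr::local_tempfile(fileext = ".nwk")
  rownames(m2) <- paste0("g", 1:6)
  write_cluster_newick(cluster_genes(m2), tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, rownames(m2))
})
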