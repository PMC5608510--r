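#' Signed gene set
#'
#' A signed gene set records, for one coregulator-dependent signature, its
#' member genes together with the direction in which coregulator loss
#' changed their androgen regulation.
#'
#' @param genes character vector of unique gene identifiers.
#' @param direction per-gene tag, `"increased"` or `"decreased"`.
#' @param label set label.
#' @return `data.frame` with columns `gene`, `direction` and attribute
#'   `label`.
#' @export
signed_gene_set <- function(genes, direction, label = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("set members must be unique")
  direction <- as.character(direction)
  if (length(direction) == 1) direction <- rep(direction, length(genes))
  if (length(direction) != length(genes))
    stop("direction must match genes in length")
  if (length(genes) && !all(direction %in% c("increased", "decreased"), na.rm = TRUE))
    stop("direction must be 'increased' or 'decreased'")
  out <- data.frame(gene = genes, direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  out
}

#' Build signed gene sets from a dependence call table
#'
#' One set per coregulator: the affected genes, tagged `increased` for
#' `+` categories and `decreased` for `-` categories.
#'
#' @param calls a call table from [dependence_calls()].
#' @return named list of signed gene sets.
#' @export
calls_to_signed_sets <- function(calls) {
  aff <- calls[as.character(calls$category) != "unaffected", , drop = FALSE]
  cgs <- unique(as.character(calls$coregulator))
  out <- lapply(cgs, function(cg) {
    x <- aff[aff$coregulator == cg, , drop = FALSE]
    dir <- ifelse(grepl("\\+$", as.character(x$category)),
                  "increased", "decreased")
    signed_gene_set(x$gene, dir, label = cg)
  })
  stats::setNames(out, cgs)
}

# internal: member genes of a set given as signed set or character vector
set_members <- function(x) {
  if (is.data.frame(x)) as.character(x$gene) else as.character(x)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail (enrichment) probability `P(X >= k)` of observing at least
#' the seen overlap `k = |A n B|` when `|B|` genes are drawn without
#' replacement from a universe of `N` genes of which `K = |A|` are marked.
#' Computed with [stats::phyper()], which evaluates the tail in log space.
#'
#' @param setA,setB signed gene sets or character vectors; must be subsets
#'   of `universe`.
#' @param universe character vector of all genes eligible for membership
#'   (e.g. the nominated target panel).
#' @return list with elements `N`, `K`, `n`, `k`, `p_value` (class
#'   `overlap_stat`).
#' @export
hypergeometric_overlap <- function(setA, setB, universe) {
  a <- unique(set_members(setA))
  b <- unique(set_members(setB))
  universe <- unique(as.character(universe))
  outside <- setdiff(c(a, b), universe)
  if (length(outside))
    stop("set member(s) outside universe: ",
         paste(sort(outside), collapse = ", "))
  N <- length(universe)
  K <- length(a)
  n <- length(b)
  k <- length(intersect(a, b))
  p <- if (k == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p_value = min(1, p)),
            class = "overlap_stat")
}

#' @export
print.overlap_stat <- function(x, ...) {
  cat(sprintf("overlap: k=%d of K=%d, n=%d (universe %d); P(X>=k) = %.4g\n",
              x$k, x$K, x$n, x$N, x$p_value))
  invisible(x)
}

#' All pairwise overlap tests among gene sets
#'
#' Evaluates the hypergeometric overlap for every unordered pair of sets
#' (`C(m, 2)` tests for `m` sets) and counts significant pairs at each
#' requested alpha level. The counts matrix carries the set sizes on its
#' diagonal and the pairwise intersection sizes off-diagonal.
#'
#' @param sets named list (>= 2) of signed gene sets or character vectors;
#'   labels must be unique.
#' @param universe gene universe for the tests.
#' @param alpha significance levels for the summary counts
#'   (default `c(0.05, 0.01)`).
#' @return list with elements `counts` (symmetric matrix), `p` (symmetric
#'   p-value matrix, `NA` diagonal), `n_pairs`, and `n_sig` (named vector,
#'   one entry per alpha).
#' @export
pairwise_overlap_matrix <- function(sets, universe,
                                    alpha = c(0.05, 0.01)) {
  m <- length(sets)
  if (m < 2) stop("need at least 2 sets")
  labs <- names(sets)
  if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs))
    stop("sets must have unique non-empty labels")
  counts <- matrix(0L, m, m, dimnames = list(labs, labs))
  pmat <- matrix(NA_real_, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m)) counts[i, i] <- length(unique(set_members(sets[[i]])))
  pvals <- numeric()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      st <- hypergeometric_overlap(sets[[i]], sets[[j]], universe)
      counts[i, j] <- counts[j, i] <- st$k
      pmat[i, j] <- pmat[j, i] <- st$p_value
      pvals <- c(pvals, st$p_value)
    }
  }
  n_sig <- vapply(alpha, function(a) sum(pvals < a), integer(1))
  list(counts = counts, p = pmat, n_pairs = as.integer(m * (m - 1) / 2),
       n_sig = stats::setNames(n_sig, paste0("alpha_", alpha)))
}

#' Directionality consistency between two signed gene sets
#'
#' For the overlap of two coregulator-dependent signatures, reports how
#' often the direction of change (increased/decreased androgen regulation
#' after knockdown) agrees. The four conditional percentages condition on
#' membership in the other set: e.g. `pct_a_increased_in_b_increased` is,
#' among A-increased genes that are also members of B, the percentage
#' tagged increased in B.
#'
#' @param setA,setB signed gene sets (see [signed_gene_set()]).
#' @return list with `n_overlap`, `n_consistent`, `n_opposite`, and the
#'   four conditional percentages (`NaN` when the denominator is empty).
#' @export
directionality_consistency <- function(setA, setB) {
  stopifnot(is.data.frame(setA), is.data.frame(setB))
  shared <- intersect(setA$gene, setB$gene)
  da <- setA$direction[match(shared, setA$gene)]
  db <- setB$direction[match(shared, setB$gene)]
  pct <- function(from, from_dir, to, to_dir) {
    # of `from`-set genes tagged from_dir that are members of `to`,
    # the percentage tagged to_dir in `to`
    cand <- from$gene[from$direction == from_dir]
    cand <- cand[cand %in% to$gene]
    if (length(cand) == 0) return(NaN)
    100 * mean(to$direction[match(cand, to$gene)] == to_dir)
  }
  list(
    n_overlap = length(shared),
    n_consistent = sum(da == db),
    n_opposite = sum(da != db),
    pct_a_increased_in_b_increased = pct(setA, "increased", setB, "increased"),
    pct_b_increased_in_a_increased = pct(setB, "increased", setA, "increased"),
    pct_a_decreased_in_b_decreased = pct(setA, "decreased", setB, "decreased"),
    pct_b_decreased_in_a_decreased = pct(setB, "decreased", setA, "decreased"))
}

#' Pearson correlation of interaction effects across coregulators
#'
#' Correlation between coregulator columns of a genes x coregulators
#' matrix of interaction effects (`c3`). Columns with zero variance get
#' correlation 0 with a warning, keeping downstream pair-combination rules
#' well defined.
#'
#' @param delta_matrix numeric matrix, genes x coregulators (>= 3 genes,
#'   >= 2 columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
effect_correlation <- function(delta_matrix) {
  if (!is.matrix(delta_matrix) || ncol(delta_matrix) < 2 ||
      nrow(delta_matrix) < 3)
    stop("delta_matrix must have >= 3 genes and >= 2 coregulators")
  sds <- apply(delta_matrix, 2, stats::sd)
  r <- suppressWarnings(stats::cor(delta_matrix))
  if (any(sds == 0)) {
    warning("zero-variance column(s): ",
            paste(colnames(delta_matrix)[sds == 0], collapse = ", "),
            "; their correlations reported as 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r
}

#' Combine the most correlated pairs of gene sets
#'
#' Pairs of coregulator signatures with Pearson correlation at or above
#' `r_min` are merged (union of members), in descending correlation order.
#' Direction tags are retained where the two parents agree and set to `NA`
#' where they conflict.
#'
#' @param corr correlation matrix from [effect_correlation()].
#' @param sets named list of signed gene sets; names must match
#'   `colnames(corr)`.
#' @param r_min minimum correlation for combining (default 0.25).
#' @return list of merged sets; each element carries attributes `pair`
#'   (the two parent labels) and `r`.
#' @export
combine_pairs <- function(corr, sets, r_min = 0.25) {
  labs <- colnames(corr)
  if (!all(labs %in% names(sets)))
    stop("sets must be named to match colnames(corr)")
  iu <- which(upper.tri(corr), arr.ind = TRUE)
  rv <- corr[iu]
  keep <- which(rv >= r_min)
  keep <- keep[order(rv[keep], labs[iu[keep, 1]], labs[iu[keep, 2]],
                     decreasing = c(TRUE, FALSE, FALSE), method = "radix")]
  lapply(keep, function(ix) {
    la <- labs[iu[ix, 1]]
    lb <- labs[iu[ix, 2]]
    a <- sets[[la]]
    b <- sets[[lb]]
    genes <- union(a$gene, b$gene)
    da <- a$direction[match(genes, a$gene)]
    db <- b$direction[match(genes, b$gene)]
    dir <- ifelse(is.na(da), db, ifelse(is.na(db), da,
                                        ifelse(da == db, da, NA)))
    out <- data.frame(gene = genes, direction = dir,
                      stringsAsFactors = FALSE)
    attr(out, "label") <- paste(la, lb, sep = "+")
    attr(out, "pair") <- c(la, lb)
    attr(out, "r") <- unname(corr[la, lb])
    out
  })
}

#' Cluster genes by their coregulator-dependence profiles
#'
#' Agglomerative hierarchical clustering with average linkage on the
#' distance `1 - Pearson correlation` between gene profiles (rows of a
#' genes x coregulators matrix with entries -1/0/+1). Genes with constant
#' profiles have undefined correlation; they are assigned distance 1 to
#' every other gene, flagged, and a warning is raised.
#'
#' @param call_matrix numeric matrix, genes x coregulators; >= 2 rows.
#' @return list with elements `hclust` (a [stats::hclust] tree, leaves in
#'   input order tie-broken by input index), `order` (leaf order for
#'   heatmap rendering) and `constant` (indices of constant-profile genes).
#' @export
cluster_genes <- function(call_matrix) {
  if (!is.matrix(call_matrix) || nrow(call_matrix) < 2)
    stop("call_matrix must be a matrix with >= 2 rows")
  sds <- apply(call_matrix, 1, stats::sd)
  constant <- which(sds == 0)
  if (length(constant) == nrow(call_matrix))
    stop("need >= 2 genes with non-constant profiles")
  if (length(constant))
    warning(length(constant),
            " constant-profile gene(s) assigned distance 1 to all others")
  r <- suppressWarnings(stats::cor(t(call_matrix)))
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(hclust = hc, order = hc$order, constant = constant)
}

#' Write a clustering tree as newick
#'
#' @param clustering result of [cluster_genes()] (or an `hclust` object).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_newick <- function(clustering, path) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
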