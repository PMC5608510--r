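#' Expression study container
#'
#' Couples an intensity matrix (genes x samples) with a design table
#' mapping each sample to its siRNA target, treatment and replicate. All
#' contrast fitting in the package starts from this container.
#'
#' @param exprs numeric matrix, rows = genes (rownames required),
#'   columns = samples. Intensities must be strictly positive unless
#'   already log2-transformed.
#' @param design `data.frame` with columns `sample_id`, `sirna`,
#'   `treatment`, `replicate`; `sample_id` must match `colnames(exprs)`
#'   one-to-one.
#' @param log2_transformed logical; `TRUE` when `exprs` is already on the
#'   log2 scale.
#' @return an object of class `expression_study` (a list with elements
#'   `exprs`, `design`, `log2`).
#' @export
expression_study <- function(exprs, design, log2_transformed = FALSE) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("exprs must be a numeric matrix")
  if (is.null(rownames(exprs))) stop("exprs must have gene rownames")
  need <- c("sample_id", "sirna", "treatment", "replicate")
  if (!all(need %in% names(design)))
    stop("design must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("design sample_id values must be unique")
  if (!setequal(design$sample_id, colnames(exprs)) ||
      length(design$sample_id) != ncol(exprs))
    stop("design sample_id must match exprs columns one-to-one")
  if (!log2_transformed && any(exprs <= 0))
    stop("intensities must be > 0 before log2 transformation")
  design <- design[match(colnames(exprs), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(exprs = exprs, design = design, log2 = log2_transformed),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$exprs), "genes x", ncol(x$exprs),
      "samples;", if (x$log2) "log2 scale" else "raw intensities", "\n")
  cat("  siRNA:", paste(unique(x$design$sirna), collapse = ", "), "\n")
  cat("  treatment:", paste(unique(x$design$treatment), collapse = ", "), "\n")
  invisible(x)
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every column to the same distribution: the per-rank mean across
#' columns. Within-column rank order is preserved; tied values within a
#' column receive the mean of the reference values at the ranks they
#' occupy.
#'
#' @param mat numeric matrix with at least two columns; all values finite.
#' @return matrix of the same shape. Idempotent.
#' @examples
#' quantile_normalize(cbind(c(1, 2, 3), c(4, 5, 6)))
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2)
    stop("mat must be a matrix with >= 2 columns")
  if (any(!is.finite(mat))) stop("mat must contain only finite values")
  n <- nrow(mat)
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    o <- order(mat[, j])
    v <- mat[o, j]
    # a tie group occupying ranks i..j receives mean(ref[i:j])
    grp <- cumsum(c(TRUE, v[-1] != v[-n]))
    out[o, j] <- stats::ave(ref, grp, FUN = mean)
  }
  out
}

#' Normalize an expression study
#'
#' Applies quantile normalization (optional) and log2 transformation to a
#' raw-intensity study. Studies already on the log2 scale are returned
#' unchanged.
#'
#' @param study an [expression_study()].
#' @param quantile logical; quantile-normalize the raw intensities before
#'   the log2 transform (default `TRUE`). Quantile normalization assumes
#'   most genes are unchanged between samples; disable it for data, such
#'   as the built-in simulator's output, where a large fraction of rows
#'   carries real signal and no array-scale artifact exists.
#' @return an `expression_study` on the log2 scale.
#' @export
normalize_study <- function(study, quantile = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  if (study$log2) return(study)
  m <- study$exprs
  if (quantile) m <- quantile_normalize(m)
  expression_study(log2(m), study$design, log2_transformed = TRUE)
}

#' Sample identifiers matching design cells
#'
#' @param study an [expression_study()].
#' @param sirna,treatment optional filters on the design table.
#' @return character vector of matching `sample_id`s.
#' @export
samples_where <- function(study, sirna = NULL, treatment = NULL) {
  d <- study$design
  keep <- rep(TRUE, nrow(d))
  if (!is.null(sirna)) keep <- keep & d$sirna %in% sirna
  if (!is.null(treatment)) keep <- keep & d$treatment %in% treatment
  d$sample_id[keep]
}

# internal: solve trigamma(x) = y by bisection (trigamma is decreasing on
# (0, Inf)); y <= 0 or below trigamma(1e7) is treated as the infinite-df
# boundary and returns Inf
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= trigamma(1e7)) return(Inf)
  lo <- 1e-8
  hi <- 1e7
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) break
  }
  sqrt(lo * hi)
}

# internal: empirical-Bayes moderated inference shared by fit_contrast()
# and the interaction contrast.
#   effect    per-gene estimate (difference of cell means)
#   s2        per-gene pooled within-group residual variance
#   df_resid  residual degrees of freedom (scalar, same design all genes)
#   se_scale2 variance multiplier, sum over cells of 1/n_i
# Returns data.frame(log2fc, t_stat, p_value, df_total) with attributes
# d0 (prior df) and s02 (prior variance).
moderated_fit <- function(effect, s2, df_resid, se_scale2,
                          moderation = c("eb", "plain"), prior_df = NULL) {
  moderation <- match.arg(moderation)
  ngene <- length(effect)
  d0 <- 0
  s02 <- NA_real_
  if (moderation == "eb") {
    z <- log(s2)
    ok <- is.finite(z)
    if (any(ok)) {
      e <- z[ok] - digamma(df_resid / 2) + log(df_resid / 2)
      emean <- mean(e)
      evar <- if (sum(ok) > 1) stats::var(e) - trigamma(df_resid / 2) else -1
      if (!is.null(prior_df)) {
        d0 <- prior_df
        s02 <- if (is.finite(d0) && d0 > 0)
          exp(emean + digamma(d0 / 2) - log(d0 / 2)) else exp(emean)
      } else if (evar > 0) {
        d0 <- 2 * trigamma_inverse(evar)
        s02 <- if (is.finite(d0))
          exp(emean + digamma(d0 / 2) - log(d0 / 2)) else exp(mean(z[ok]))
      } else {
        # observed spread of log-variances is at or below sampling noise:
        # boundary case; the shared (geometric mean) variance is the prior
        d0 <- Inf
        s02 <- exp(mean(z[ok]))
      }
    }
  }
  if (d0 == 0 || is.na(s02)) {
    s2_post <- s2
    df_total <- df_resid
  } else if (is.infinite(d0)) {
    s2_post <- rep(s02, ngene)
    df_total <- Inf
  } else {
    s2_post <- (d0 * s02 + df_resid * s2) / (d0 + df_resid)
    df_total <- d0 + df_resid
  }
  se <- sqrt(s2_post * se_scale2)
  t_stat <- ifelse(se > 0, effect / se,
                   ifelse(effect == 0, 0, sign(effect) * Inf))
  p <- ifelse(is.finite(t_stat),
              2 * stats::pt(-abs(t_stat), df = df_total),
              0)
  p[t_stat == 0 & se == 0] <- 1
  out <- data.frame(log2fc = effect, t_stat = t_stat, p_value = p,
                    df_total = rep(df_total, ngene))
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

#' Fit a two-group contrast with optional variance moderation
#'
#' Computes per-gene `log2fc = mean(A) - mean(B)` on a log2-scale study,
#' with the residual variance pooled within the two groups. With
#' `moderation = "eb"` the gene variances are shrunk towards a common prior
#' under a scaled-F model whose hyperparameters `(d0, s0^2)` are estimated
#' by method of moments on `log(s^2)` (trigamma inversion by bisection);
#' the moderated t-statistic then has `d0 + d_g` degrees of freedom.
#' `moderation = "plain"` is the textbook pooled two-sample t
#' (`d0 = 0`). P-values are two-sided; FDRs are Benjamini-Hochberg across
#' genes within the contrast.
#'
#' @param study a log2-scale [expression_study()].
#' @param groupA,groupB character vectors of sample ids (or logical masks
#'   over the design rows); disjoint, each of size >= 2.
#' @param moderation `"eb"` (default) or `"plain"`.
#' @param prior_df optional forced prior degrees of freedom (e.g. `Inf`
#'   to shrink every gene fully to the prior variance); `NULL` estimates
#'   it from the data.
#' @return `data.frame` with columns `gene`, `log2fc`, `t_stat`,
#'   `p_value`, `fdr`, `df_total`; attributes `d0` and `s02` expose the
#'   estimated prior.
#' @export
fit_contrast <- function(study, groupA, groupB,
                         moderation = c("eb", "plain"), prior_df = NULL) {
  stopifnot(inherits(study, "expression_study"))
  moderation <- match.arg(moderation)
  if (!study$log2)
    stop("study must be log2-transformed; see normalize_study()")
  as_ids <- function(g) {
    if (is.logical(g)) study$design$sample_id[g] else as.character(g)
  }
  a <- as_ids(groupA)
  b <- as_ids(groupB)
  if (length(intersect(a, b))) stop("groups must be disjoint")
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 samples")
  bad <- setdiff(c(a, b), colnames(study$exprs))
  if (length(bad)) stop("unknown sample id(s): ", paste(bad, collapse = ", "))
  ma <- study$exprs[, a, drop = FALSE]
  mb <- study$exprs[, b, drop = FALSE]
  nA <- ncol(ma); nB <- ncol(mb)
  meanA <- rowMeans(ma)
  meanB <- rowMeans(mb)
  ss <- rowSums((ma - meanA)^2) + rowSums((mb - meanB)^2)
  df_resid <- nA + nB - 2
  s2 <- ss / df_resid
  fit <- moderated_fit(meanA - meanB, s2, df_resid, 1 / nA + 1 / nB,
                       moderation, prior_df)
  out <- cbind(data.frame(gene = rownames(study$exprs),
                          stringsAsFactors = FALSE),
               fit, fdr = bh_adjust(fit$p_value))
  attr(out, "d0") <- attr(fit, "d0")
  attr(out, "s02") <- attr(fit, "s02")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min(1, min_{j >= i} p_(j) * m / j)` over the ascending order
#' statistics, returned in input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- pmin(1, cummin(rev(p[o] * m / seq_len(m))))
  q <- rev(q)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Call differentially expressed genes (dual FDR + fold-change rule)
#'
#' Genes with `fdr < fdr_max` and `|log2fc| >= min_abs_log2fc` (the default
#' corresponds to a 2-fold change at FDR 0.05), tagged with the sign of
#' the fold change.
#'
#' @param result a contrast table from [fit_contrast()] (needs columns
#'   `gene`, `log2fc`, `fdr`).
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1,
#'   i.e. 2-fold).
#' @return `data.frame` with columns `gene`, `log2fc`, `fdr`, `sign`
#'   (`+1`/`-1`).
#' @export
call_de <- function(result, fdr_max = 0.05, min_abs_log2fc = 1.0) {
  if (!(fdr_max > 0 && min_abs_log2fc > 0))
    stop("thresholds must be > 0")
  keep <- result$fdr < fdr_max & abs(result$log2fc) >= min_abs_log2fc
  out <- result[keep, c("gene", "log2fc", "fdr")]
  out$sign <- ifelse(out$log2fc > 0, 1L, -1L)
  rownames(out) <- NULL
  out
}

#' Collapse probe-level rows to gene level
#'
#' @param mat probe x sample matrix.
#' @param gene_of_probe character vector mapping each row to a gene.
#' @param method summary per gene (default `"median"`; or `"mean"`).
#' @return gene x sample matrix.
#' @export
collapse_probes <- function(mat, gene_of_probe, method = c("median", "mean")) {
  method <- match.arg(method)
  f <- if (method == "median") stats::median else mean
  stopifnot(length(gene_of_probe) == nrow(mat))
  genes <- unique(gene_of_probe)
  out <- t(vapply(genes, function(g) {
    apply(mat[gene_of_probe == g, , drop = FALSE], 2, f)
  }, numeric(ncol(mat))))
  rownames(out) <- genes
  out
}
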