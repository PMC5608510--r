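# Small in-code fixtures shared across test files.

# a two-group study from an explicit matrix (columns s1..s_k split in half:
# first half androgen, second half vehicle, control siRNA)
two_group_study <- function(mat, log2 = TRUE) {
  k <- ncol(mat)
  colnames(mat) <- paste0("s", seq_len(k))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  des <- data.frame(sample_id = colnames(mat),
                    sirna = "control",
                    treatment = rep(c("androgen", "vehicle"), each = k / 2),
                    replicate = rep(seq_len(k / 2), 2))
  expression_study(mat, des, log2_transformed = log2)
}

group_a <- function(study) samples_where(study, treatment = "androgen")
group_b <- function(study) samples_where(study, treatment = "vehicle")

# a manually built response-pair table row
pair_row <- function(c1, c2, c3_fdr = 0.001, gene = "g1",
                     coregulator = "X") {
  data.frame(gene = gene, coregulator = coregulator,
             c1_log2fc = c1, c1_p = 0.001, c1_fdr = 0.001,
             c2_log2fc = c2, c2_p = 0.001, c2_fdr = 0.001,
             c3_log2fc = c2 - c1, c3_p = c3_fdr, c3_fdr = c3_fdr,
             stringsAsFactors = FALSE)
}

# simulated study ready for classification, with matched planted truth
simulated_calls <- function(config, quantile = FALSE, ...) {
  se <- simulate_expression(config)
  st <- normalize_study(se$study, quantile = quantile)
  calls <- dependence_calls(st, ...)
  tr <- se$truth$pairs
  m <- match(paste(calls$gene, calls$coregulator),
             paste(tr$gene_id, tr$coregulator))
  stopifnot(!anyNA(m))
  calls$planted <- tr$class[m]
  calls$planted_kd <- tr$kd_log2fc[m]
  calls$planted_c1 <-
    se$truth$genes$control_log2fc[match(calls$gene,
                                        se$truth$genes$gene_id)]
  calls
}
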