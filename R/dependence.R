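#' Androgen-response contrasts under control and coregulator knockdown
#'
#' Implements the three-comparison knockdown design. For one coregulator
#' siRNA the function fits, per gene:
#' \describe{
#'   \item{c1}{androgen response under control siRNA:
#'     (control, androgen) vs (control, vehicle);}
#'   \item{c2}{androgen response under the coregulator siRNA:
#'     (siX, androgen) vs (siX, vehicle);}
#'   \item{c3}{the interaction contrast `c2 - c1` (difference of
#'     differences), tested with its own moderated statistic whose residual
#'     variance is pooled over all four design cells.}
#' }
#' Each of the three comparisons is Benjamini-Hochberg adjusted across
#' genes within the comparison.
#'
#' @param study a log2-scale [expression_study()] containing control and
#'   coregulator siRNA samples under both treatments.
#' @param coregulator siRNA target name as it appears in the design.
#' @param control control siRNA label (default `"control"`).
#' @param treatment_levels length-2 character vector naming the androgen
#'   and vehicle treatments (default `c("androgen", "vehicle")`).
#' @param moderation `"eb"` (default) or `"plain"`; see [fit_contrast()].
#' @return `data.frame` with columns `gene`, `coregulator`, `c1_log2fc`,
#'   `c1_p`, `c1_fdr`, `c2_log2fc`, `c2_p`, `c2_fdr`, `c3_log2fc`, `c3_p`,
#'   `c3_fdr`.
#' @export
androgen_response_pair <- function(study, coregulator, control = "control",
                                   treatment_levels = c("androgen", "vehicle"),
                                   moderation = c("eb", "plain")) {
  stopifnot(inherits(study, "expression_study"))
  moderation <- match.arg(moderation)
  if (!study$log2)
    stop("study must be log2-transformed; see normalize_study()")
  andro <- treatment_levels[1]
  veh <- treatment_levels[2]
  cells <- list(
    ctrl_andro = samples_where(study, control, andro),
    ctrl_veh = samples_where(study, control, veh),
    kd_andro = samples_where(study, coregulator, andro),
    kd_veh = samples_where(study, coregulator, veh))
  labels <- c(ctrl_andro = paste0("sirna=", control, ", treatment=", andro),
              ctrl_veh = paste0("sirna=", control, ", treatment=", veh),
              kd_andro = paste0("sirna=", coregulator, ", treatment=", andro),
              kd_veh = paste0("sirna=", coregulator, ", treatment=", veh))
  short <- lengths(cells) < 2
  if (any(short))
    stop("design cell(s) missing or with < 2 replicates: ",
         paste(labels[short], collapse = "; "))

  c1 <- fit_contrast(study, cells$ctrl_andro, cells$ctrl_veh, moderation)
  c2 <- fit_contrast(study, cells$kd_andro, cells$kd_veh, moderation)

  # interaction contrast: variance pooled within the four cells
  m <- study$exprs
  cm <- lapply(cells, function(s) rowMeans(m[, s, drop = FALSE]))
  ss <- Reduce(`+`, lapply(names(cells), function(k) {
    rowSums((m[, cells[[k]], drop = FALSE] - cm[[k]])^2)
  }))
  n_cell <- lengths(cells)
  df_resid <- sum(n_cell - 1)
  s2 <- ss / df_resid
  effect <- (cm$kd_andro - cm$kd_veh) - (cm$ctrl_andro - cm$ctrl_veh)
  c3 <- moderated_fit(effect, s2, df_resid, sum(1 / n_cell), moderation)

  data.frame(gene = rownames(m),
             coregulator = coregulator,
             c1_log2fc = c1$log2fc, c1_p = c1$p_value, c1_fdr = c1$fdr,
             c2_log2fc = c2$log2fc, c2_p = c2$p_value, c2_fdr = c2$fdr,
             c3_log2fc = c3$log2fc, c3_p = c3$p_value,
             c3_fdr = bh_adjust(c3$p_value),
             stringsAsFactors = FALSE)
}

#' Dependence categories
#'
#' @return the five category labels in canonical order.
#' @export
dependence_categories <- function() {
  c("co+", "co-", "op+", "op-", "unaffected")
}

#' Classify coregulator dependence of androgen regulation
#'
#' A gene is AFFECTED by a coregulator knockdown when the interaction
#' contrast passes the dual rule (`c3_fdr < fdr_max` and
#' `|c3_log2fc| >= min_abs_delta_log2`) and the gene is androgen-regulated
#' in at least one condition (`max(|c1|, |c2|) >= min_regulated_abs_log2fc`).
#' Affected genes are labelled:
#' \itemize{
#'   \item suffix `+` when `|c2| > |c1|` (androgen regulation increased
#'     after coregulator loss), `-` when `|c2| < |c1|`; an exact tie takes
#'     `+` by convention;
#'   \item prefix `co` when the direction of androgen regulation is
#'     preserved (`sign(c1) == sign(c2)`), `op` when it strictly flips
#'     (`sign(c1) == -sign(c2)`, both non-zero); a zero sign counts as
#'     preserved.
#' }
#' All other genes are `unaffected`.
#'
#' @param pair a table from [androgen_response_pair()].
#' @param fdr_max interaction FDR threshold (default 0.05).
#' @param min_abs_delta_log2 minimum `|c3|` in log2 units (default 1,
#'   i.e. a 2-fold change in androgen response).
#' @param min_regulated_abs_log2fc minimum `max(|c1|, |c2|)` (default 1).
#' @return the input with an added `category` column (factor with levels
#'   [dependence_categories()]).
#' @export
classify_dependence <- function(pair, fdr_max = 0.05,
                                min_abs_delta_log2 = 1.0,
                                min_regulated_abs_log2fc = 1.0) {
  if (!(fdr_max > 0 && min_abs_delta_log2 > 0 &&
        min_regulated_abs_log2fc > 0))
    stop("thresholds must be > 0")
  c1 <- pair$c1_log2fc
  c2 <- pair$c2_log2fc
  affected <- pair$c3_fdr < fdr_max &
    abs(pair$c3_log2fc) >= min_abs_delta_log2 &
    pmax(abs(c1), abs(c2)) >= min_regulated_abs_log2fc
  suffix <- ifelse(abs(c2) >= abs(c1), "+", "-")
  prefix <- ifelse(sign(c1) * sign(c2) < 0, "op", "co")
  category <- ifelse(affected, paste0(prefix, suffix), "unaffected")
  out <- pair
  out$category <- factor(category, levels = dependence_categories())
  out
}

#' Classify dependence for every coregulator in a study
#'
#' Convenience wrapper running [androgen_response_pair()] +
#' [classify_dependence()] for each coregulator siRNA and binding the
#' results into one long-format call table.
#'
#' @param study a log2-scale [expression_study()].
#' @param coregulators character vector of siRNA targets; defaults to all
#'   non-control siRNAs in the design.
#' @param panel optional gene identifiers to restrict the calls to (e.g.
#'   a nominated target-gene panel).
#' @inheritParams androgen_response_pair
#' @inheritParams classify_dependence
#' @return long-format `data.frame`, one row per (gene, coregulator).
#' @export
dependence_calls <- function(study, coregulators = NULL,
                             control = "control",
                             treatment_levels = c("androgen", "vehicle"),
                             moderation = c("eb", "plain"),
                             fdr_max = 0.05, min_abs_delta_log2 = 1.0,
                             min_regulated_abs_log2fc = 1.0,
                             panel = NULL) {
  moderation <- match.arg(moderation)
  if (is.null(coregulators))
    coregulators <- setdiff(unique(study$design$sirna), control)
  if (!is.null(panel)) {
    keep <- rownames(study$exprs) %in% panel
    study <- expression_study(study$exprs[keep, , drop = FALSE],
                              study$design, log2_transformed = study$log2)
  }
  out <- lapply(coregulators, function(cg) {
    classify_dependence(
      androgen_response_pair(study, cg, control, treatment_levels,
                             moderation),
      fdr_max, min_abs_delta_log2, min_regulated_abs_log2fc)
  })
  do.call(rbind, out)
}

#' Summarize dependence calls per coregulator
#'
#' Per-coregulator counts of the four categories, the total number of
#' affected genes, the panel size and the affected fraction expressed as a
#' whole percent (e.g. 258 affected of a 452-gene panel reports 57).
#'
#' @param calls a call table from [classify_dependence()] /
#'   [dependence_calls()].
#' @return `data.frame` with one row per coregulator and columns
#'   `coregulator`, `co_plus`, `co_minus`, `op_plus`, `op_minus`,
#'   `affected`, `panel`, `affected_pct`.
#' @export
summarize_calls <- function(calls) {
  cols <- c("co_plus", "co_minus", "op_plus", "op_minus",
            "affected", "panel", "affected_pct")
  if (is.null(calls) || nrow(calls) == 0) {
    out <- data.frame(coregulator = character(), stringsAsFactors = FALSE)
    for (cl in cols) out[[cl]] <- numeric()
    return(out)
  }
  cats <- dependence_categories()
  tab <- table(calls$coregulator,
               factor(as.character(calls$category), levels = cats))
  panel <- as.integer(rowSums(tab))
  affected <- as.integer(rowSums(tab[, cats[1:4], drop = FALSE]))
  data.frame(coregulator = rownames(tab),
             co_plus = as.integer(tab[, "co+"]),
             co_minus = as.integer(tab[, "co-"]),
             op_plus = as.integer(tab[, "op+"]),
             op_minus = as.integer(tab[, "op-"]),
             affected = affected,
             panel = panel,
             affected_pct = round(100 * affected / panel),
             stringsAsFactors = FALSE, row.names = NULL)
}
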