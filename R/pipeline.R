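#' Pipeline run configuration
#'
#' Bundles every stage toggle, threshold and path for [run_pipeline()].
#' All thresholds default to the study design the package implements:
#' 300 kb assignment window, 1 kb peak extension, FDR < 0.05 with 2-fold
#' change, Pearson r >= 0.25 pair combination and the
#' "at most 2 signatures" motif-selectivity rule.
#'
#' @param out_dir directory for stage outputs (created if needed).
#' @param seed master seed; forwarded to the simulator and motif stage.
#' @param stages character vector of stages to run, in pipeline order,
#'   from `simulate`, `targets`, `de`, `classify`, `overlap`, `motifs`.
#'   Stages that are toggled off must find their inputs in `out_dir`.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param window,pad,min_lists,fdr_max,min_abs_log2fc,min_abs_delta_log2,min_regulated_abs_log2fc,r_min,alpha,max_signatures,score_min_frac,motif_alpha
#'   analysis thresholds; see the stage functions.
#' @param quantile_normalize logical; quantile-normalize intensities in
#'   the DE stage (default `FALSE` for simulator output, which carries no
#'   array-scale artifact and where most genes are truly regulated).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = file.path(tempdir(), "coregdep_run"),
                       seed = 1L,
                       stages = c("simulate", "targets", "de", "classify",
                                  "overlap", "motifs"),
                       sim = sim_config(),
                       window = 300000, pad = 1000, min_lists = 1,
                       fdr_max = 0.05, min_abs_log2fc = 1.0,
                       min_abs_delta_log2 = 1.0,
                       min_regulated_abs_log2fc = 1.0,
                       r_min = 0.25, alpha = c(0.05, 0.01),
                       max_signatures = 2, score_min_frac = 0.8,
                       motif_alpha = 0.05,
                       quantile_normalize = FALSE) {
  known <- c("simulate", "targets", "de", "classify", "overlap", "motifs")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = known[known %in% stages], sim = sim,
                 window = window, pad = pad, min_lists = min_lists,
                 fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc,
                 min_abs_delta_log2 = min_abs_delta_log2,
                 min_regulated_abs_log2fc = min_regulated_abs_log2fc,
                 r_min = r_min, alpha = alpha,
                 max_signatures = max_signatures,
                 score_min_frac = score_min_frac,
                 motif_alpha = motif_alpha,
                 quantile_normalize = quantile_normalize),
            class = "run_config")
}

#' Read / write a run configuration as a key-value text file
#'
#' Lines of the form `key = value`; vector values are comma-separated,
#' simulator fields use the `sim.` prefix and chromosome lengths the form
#' `chrom:length`. The representation round-trips losslessly through
#' [run_config()].
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config()` the path invisibly; `read_run_config()` a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) paste(v, collapse = ",")
  sim <- config$sim
  kv <- c(
    out_dir = config$out_dir, seed = config$seed,
    stages = fmt(config$stages),
    window = config$window, pad = config$pad, min_lists = config$min_lists,
    fdr_max = config$fdr_max, min_abs_log2fc = config$min_abs_log2fc,
    min_abs_delta_log2 = config$min_abs_delta_log2,
    min_regulated_abs_log2fc = config$min_regulated_abs_log2fc,
    r_min = config$r_min, alpha = fmt(config$alpha),
    max_signatures = config$max_signatures,
    score_min_frac = config$score_min_frac,
    motif_alpha = config$motif_alpha,
    quantile_normalize = config$quantile_normalize,
    "sim.n_genes" = sim$n_genes,
    "sim.n_coregulators" = sim$n_coregulators,
    "sim.chrom_lengths" = fmt(paste0(names(sim$chrom_lengths), ":",
                                     sim$chrom_lengths)),
    "sim.reps_per_condition" = sim$reps_per_condition,
    "sim.effect_log2fc" = sim$effect_log2fc,
    "sim.delta_log2fc" = sim$delta_log2fc,
    "sim.noise_sd" = sim$noise_sd,
    "sim.class_fractions" = fmt(paste0(names(sim$class_fractions), ":",
                                       sim$class_fractions)),
    "sim.baseline_log2" = sim$baseline_log2,
    "sim.baseline_sd" = sim$baseline_sd,
    "sim.frac_genes_with_peak" = sim$frac_genes_with_peak,
    "sim.n_decoy_peaks" = sim$n_decoy_peaks,
    "sim.window" = sim$window,
    "sim.peak_width" = sim$peak_width,
    "sim.multi_tss_fraction" = sim$multi_tss_fraction)
  writeLines(paste(names(kv), "=", kv), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("malformed config line: ",
                        lines[which(eq < 0)[1]])
  keys <- trimws(substr(lines, 1, eq - 1))
  vals <- trimws(substr(lines, eq + 1, nchar(lines)))
  kv <- stats::setNames(as.list(vals), keys)
  split_vec <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  named_num <- function(x) {
    parts <- strsplit(split_vec(x), ":", fixed = TRUE)
    stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                    vapply(parts, `[`, "", 1))
  }
  sim <- sim_config(
    n_genes = as.integer(kv$`sim.n_genes`),
    n_coregulators = as.integer(kv$`sim.n_coregulators`),
    chrom_lengths = named_num(kv$`sim.chrom_lengths`),
    reps_per_condition = as.integer(kv$`sim.reps_per_condition`),
    effect_log2fc = as.numeric(kv$`sim.effect_log2fc`),
    delta_log2fc = as.numeric(kv$`sim.delta_log2fc`),
    noise_sd = as.numeric(kv$`sim.noise_sd`),
    class_fractions = named_num(kv$`sim.class_fractions`),
    baseline_log2 = as.numeric(kv$`sim.baseline_log2`),
    baseline_sd = as.numeric(kv$`sim.baseline_sd`),
    frac_genes_with_peak = as.numeric(kv$`sim.frac_genes_with_peak`),
    n_decoy_peaks = as.integer(kv$`sim.n_decoy_peaks`),
    window = as.numeric(kv$`sim.window`),
    peak_width = as.numeric(kv$`sim.peak_width`),
    multi_tss_fraction = as.numeric(kv$`sim.multi_tss_fraction`),
    seed = as.integer(kv$seed))
  run_config(out_dir = kv$out_dir, seed = as.integer(kv$seed),
             stages = split_vec(kv$stages), sim = sim,
             window = as.numeric(kv$window), pad = as.numeric(kv$pad),
             min_lists = as.integer(kv$min_lists),
             fdr_max = as.numeric(kv$fdr_max),
             min_abs_log2fc = as.numeric(kv$min_abs_log2fc),
             min_abs_delta_log2 = as.numeric(kv$min_abs_delta_log2),
             min_regulated_abs_log2fc =
               as.numeric(kv$min_regulated_abs_log2fc),
             r_min = as.numeric(kv$r_min),
             alpha = as.numeric(split_vec(kv$alpha)),
             max_signatures = as.integer(kv$max_signatures),
             score_min_frac = as.numeric(kv$score_min_frac),
             motif_alpha = as.numeric(kv$motif_alpha),
             quantile_normalize = as.logical(kv$quantile_normalize))
}

# internal: read a stage artifact, with a dependency-aware error
stage_input <- function(out_dir, file, stage, produced_by, reader) {
  path <- file.path(out_dir, file)
  if (!file.exists(path))
    stop("stage '", stage, "' requires artifact '", file,
         "' produced by stage '", produced_by, "', but it is missing from ",
         out_dir)
  reader(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the coregulator-dependence pipeline end to end
#'
#' Executes the enabled stages in order
#' `simulate -> targets -> de -> classify -> overlap -> motifs`, reading
#' inputs of disabled stages from `out_dir` and writing every stage's
#' outputs there as plain-text tables. The run is fully determined by the
#' configuration (including its seed); re-running with an identical
#' configuration reproduces byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return the run manifest: a list with the configuration echo (all
#'   thresholds), the seed, and per-stage output files with MD5 checksums.
#'   The manifest is also written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(package = "coregdep",
                   version = as.character(utils::packageVersion("coregdep")),
                   seed = config$seed,
                   thresholds = list(
                     window = config$window, pad = config$pad,
                     fdr_max = config$fdr_max,
                     min_abs_log2fc = config$min_abs_log2fc,
                     min_abs_delta_log2 = config$min_abs_delta_log2,
                     r_min = config$r_min, alpha = config$alpha,
                     max_signatures = config$max_signatures),
                   stages = list())
  log_stage <- function(stage, files) {
    message("[coregdep] stage ", stage, ": ",
            length(files), " artifact(s) written")
    manifest$stages[[stage]] <<- list(
      outputs = basename(files),
      md5 = unname(tools::md5sum(files)))
  }

  if ("simulate" %in% stages) {
    ap <- simulate_annotation_and_peaks(config$sim)
    se <- simulate_expression(config$sim)
    # two synthetic "published" androgen-regulated gene lists for the
    # cross-matching step (deterministic subsets of the regulated genes)
    set.seed(stage_seed(config$sim$seed, 4))
    reg <- se$truth$genes$gene_id
    l1 <- sort(sample(reg, round(0.8 * length(reg))))
    l2 <- sort(sample(reg, round(0.7 * length(reg))))
    files <- c(
      write_tsv(ap$annotation, file.path(od, "annotation.tsv")),
      { write_bed(ap$peaks, file.path(od, "peaks.bed"))
        file.path(od, "peaks.bed") },
      write_matrix_tsv(se$study$exprs, file.path(od, "expression.tsv")),
      write_tsv(se$study$design, file.path(od, "design.tsv")),
      write_tsv(se$truth$genes, file.path(od, "truth_genes.tsv")),
      write_tsv(se$truth$pairs, file.path(od, "truth_pairs.tsv")),
      { writeLines(l1, file.path(od, "regulated_list_1.txt"))
        file.path(od, "regulated_list_1.txt") },
      { writeLines(l2, file.path(od, "regulated_list_2.txt"))
        file.path(od, "regulated_list_2.txt") },
      { chrom <- data.frame(chrom = names(config$sim$chrom_lengths),
                            length = as.numeric(config$sim$chrom_lengths))
        utils::write.table(chrom, file.path(od, "chrom.sizes"), sep = "\t",
                           quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
        file.path(od, "chrom.sizes") })
    log_stage("simulate", files)
  }

  if ("targets" %in% stages) {
    ann <- stage_input(od, "annotation.tsv", "targets", "simulate",
                       read_gene_annotation)
    pk <- stage_input(od, "peaks.bed", "targets", "simulate", read_bed)
    lists <- read_gene_lists(c(
      stage_input(od, "regulated_list_1.txt", "targets", "simulate",
                  identity),
      stage_input(od, "regulated_list_2.txt", "targets", "simulate",
                  identity)))
    asg <- assign_peaks_to_tss(pk, ann, window = config$window)
    nominated <- nominate_targets(asg, lists, min_lists = config$min_lists)
    cats <- categorize_peak_locations(pk, ann)
    files <- c(
      write_tsv(asg, file.path(od, "assignments.tsv")),
      { writeLines(nominated, file.path(od, "nominated_targets.txt"))
        file.path(od, "nominated_targets.txt") },
      write_tsv(data.frame(category = names(cats),
                           count = as.integer(cats)),
                file.path(od, "peak_categories.tsv")))
    log_stage("targets", files)
  }

  if ("de" %in% stages) {
    exprs <- stage_input(od, "expression.tsv", "de", "simulate",
                         read_matrix_tsv)
    design <- stage_input(od, "design.tsv", "de", "simulate", read_tsv)
    study <- normalize_study(expression_study(exprs, design),
                             quantile = config$quantile_normalize)
    c1 <- fit_contrast(study,
                       samples_where(study, "control", "androgen"),
                       samples_where(study, "control", "vehicle"))
    de <- call_de(c1, config$fdr_max, config$min_abs_log2fc)
    files <- c(
      write_tsv(c1[, c("gene", "log2fc", "t_stat", "p_value", "fdr")],
                file.path(od, "androgen_contrast.tsv")),
      write_tsv(de, file.path(od, "androgen_de.tsv")))
    log_stage("de", files)
  }

  if ("classify" %in% stages) {
    exprs <- stage_input(od, "expression.tsv", "classify", "simulate",
                         read_matrix_tsv)
    design <- stage_input(od, "design.tsv", "classify", "simulate", read_tsv)
    nominated <- stage_input(od, "nominated_targets.txt", "classify",
                             "targets", readLines)
    de <- stage_input(od, "androgen_de.tsv", "classify", "de", read_tsv)
    study <- normalize_study(expression_study(exprs, design),
                             quantile = config$quantile_normalize)
    panel <- intersect(nominated, de$gene)
    calls <- dependence_calls(study,
                              fdr_max = config$fdr_max,
                              min_abs_delta_log2 = config$min_abs_delta_log2,
                              min_regulated_abs_log2fc =
                                config$min_regulated_abs_log2fc,
                              panel = panel)
    files <- c(
      write_tsv(calls, file.path(od, "dependence_calls.tsv")),
      write_tsv(summarize_calls(calls), file.path(od, "call_summary.tsv")),
      { writeLines(panel, file.path(od, "panel.txt"))
        file.path(od, "panel.txt") })
    log_stage("classify", files)
  }

  if ("overlap" %in% stages) {
    calls <- stage_input(od, "dependence_calls.tsv", "overlap", "classify",
                         read_tsv)
    panel <- stage_input(od, "panel.txt", "overlap", "classify", readLines)
    sets <- calls_to_signed_sets(calls)
    if (length(sets) < 2)
      stop("stage 'overlap' needs >= 2 coregulator signatures")
    ov <- pairwise_overlap_matrix(sets, panel, alpha = config$alpha)
    delta <- matrix(calls$c3_log2fc,
                    nrow = length(unique(calls$gene)),
                    dimnames = list(unique(calls$gene),
                                    unique(calls$coregulator)))
    corr <- effect_correlation(delta)
    merged <- combine_pairs(corr, sets, r_min = config$r_min)
    sign_mat <- matrix(0, nrow = nrow(delta), ncol = ncol(delta),
                       dimnames = dimnames(delta))
    for (cg in colnames(sign_mat)) {
      s <- sets[[cg]]
      sign_mat[s$gene, cg] <- ifelse(s$direction == "increased", 1, -1)
    }
    keep <- apply(sign_mat, 1, function(r) stats::sd(r) > 0)
    files <- c(
      write_matrix_tsv(ov$counts, file.path(od, "overlap_counts.tsv")),
      write_matrix_tsv(ov$p, file.path(od, "overlap_p.tsv")),
      write_matrix_tsv(corr, file.path(od, "effect_correlation.tsv")),
      write_tsv(data.frame(
        pair = vapply(merged, function(s) attr(s, "label"), ""),
        r = vapply(merged, function(s) attr(s, "r"), 0),
        n_genes = vapply(merged, nrow, 0L)),
        file.path(od, "combined_pairs.tsv")))
    if (sum(keep) >= 2) {
      cl <- cluster_genes(sign_mat[keep, , drop = FALSE])
      files <- c(files,
                 write_cluster_newick(cl, file.path(od, "gene_tree.nwk")))
    }
    log_stage("overlap", files)
  }

  if ("motifs" %in% stages) {
    pk <- stage_input(od, "peaks.bed", "motifs", "simulate", read_bed)
    calls <- stage_input(od, "dependence_calls.tsv", "motifs", "classify",
                         read_tsv)
    asg <- stage_input(od, "assignments.tsv", "motifs", "targets", read_tsv)
    sizes_tab <- utils::read.table(
      file.path(od, "chrom.sizes"), sep = "\t", header = FALSE,
      col.names = c("chrom", "length"))
    sizes <- stats::setNames(sizes_tab$length, sizes_tab$chrom)
    ext <- extend_peaks(pk, pad = config$pad, chrom_sizes = sizes)
    target_peaks <- unique(asg$peak)
    pwms <- list(ARE = are_pwm())
    seqs <- simulate_peak_sequences(
      ext, plant_in = list(ARE = target_peaks), pwms = pwms,
      seed = stage_seed(config$seed, 3))
    sets <- calls_to_signed_sets(calls)
    fg <- lapply(sets, function(s) {
      nm <- asg$peak[asg$gene_id %in% s$gene]
      unname(seqs[unique(nm)])
    })
    fg <- fg[vapply(fg, length, 0L) > 0]
    bg_names <- setdiff(names(seqs), target_peaks)
    bg <- if (length(bg_names)) unname(seqs[bg_names]) else unname(seqs)
    enr <- motif_enrichment(fg, bg, pwms, alpha = config$motif_alpha)
    sel <- selective_motifs(enr, config$max_signatures)
    files <- c(
      write_tsv(enr, file.path(od, "motif_enrichment.tsv")),
      write_tsv(data.frame(
        motif = rep(names(sel), lengths(sel)),
        signature = unlist(sel, use.names = FALSE)),
        file.path(od, "selective_motifs.tsv")))
    log_stage("motifs", files)
  }

  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render figure-style summary tables for a completed run
#'
#' @param calls a dependence call table (possibly empty).
#' @param overlaps result of [pairwise_overlap_matrix()] or `NULL`.
#' @param enrichments a [motif_enrichment()] table or `NULL`.
#' @return list of `data.frame`s: `category_counts` (per-coregulator
#'   co+/co-/op+/op- counts), `overlap_matrix` (symmetric, set sizes on
#'   the diagonal) and `motif_counts` (enriched motifs per signature).
#'   Empty inputs yield empty but well-formed tables.
#' @export
render_summary <- function(calls = NULL, overlaps = NULL,
                           enrichments = NULL) {
  category_counts <- summarize_calls(calls)
  overlap_matrix <- if (is.null(overlaps)) {
    data.frame(set = character())
  } else {
    data.frame(set = rownames(overlaps$counts), overlaps$counts,
               check.names = FALSE, row.names = NULL)
  }
  motif_counts <- if (is.null(enrichments) || nrow(enrichments) == 0) {
    data.frame(signature = character(), n_enriched = integer())
  } else {
    ag <- stats::aggregate(enriched ~ signature, data = enrichments,
                           FUN = sum)
    data.frame(signature = ag$signature,
               n_enriched = as.integer(ag$enriched))
  }
  list(category_counts = category_counts,
       overlap_matrix = overlap_matrix,
       motif_counts = motif_counts)
}
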