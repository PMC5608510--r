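#' Simulation configuration
#'
#' Parameters of the synthetic genome / knockdown-expression generator.
#' Defaults emulate the measured design the package targets: 3 biological
#' replicates per (siRNA, treatment) cell, a 2-fold planted androgen
#' response, and knockdown-induced changes large enough to pass the
#' 2-fold interaction rule.
#'
#' @param n_genes number of simulated genes (default 2000).
#' @param n_coregulators number of coregulator siRNAs (default 17).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param reps_per_condition biological replicates per design cell
#'   (default 3, minimum 2).
#' @param effect_log2fc planted androgen log2 fold change under control
#'   siRNA (default 2.0; sign randomized per gene).
#' @param delta_log2fc planted knockdown-induced change of the androgen
#'   response, in log2 units (default 1.5). Must be smaller than
#'   `effect_log2fc` so that `co-` genes keep their direction.
#' @param noise_sd log2-scale residual standard deviation (default 0.25).
#' @param class_fractions named fractions for `co+`, `co-`, `op+`, `op-`,
#'   `unaffected`; non-negative, summing to 1.
#' @param baseline_log2 mean log2 intensity (default 8.0).
#' @param baseline_sd per-gene SD of baseline log2 intensity (default 1.0).
#' @param frac_genes_with_peak fraction of genes receiving at least one
#'   binding-site peak within the assignment window of a TSS (default 0.8).
#' @param n_decoy_peaks peaks placed beyond the window of every TSS where
#'   genome space allows (default 200).
#' @param window peak-to-TSS assignment window in bp (default 300000).
#' @param peak_width simulated peak width in bp (default 400).
#' @param multi_tss_fraction fraction of genes given a second TSS
#'   (default 0; the generator is single-TSS unless asked).
#' @param seed master seed; per-stage substreams are derived from it (see
#'   Details).
#' @details Stage k of the generator seeds the RNG with
#'   `(seed * 7919 + k) mod (2^31 - 1)` (annotation/peaks k = 1,
#'   expression k = 2, peak sequences k = 3), so stages can be regenerated
#'   independently and reproducibly.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_coregulators = 17,
                       chrom_lengths = c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7),
                       reps_per_condition = 3,
                       effect_log2fc = 2.0,
                       delta_log2fc = 1.5,
                       noise_sd = 0.25,
                       class_fractions = c("co+" = 0.15, "co-" = 0.15,
                                           "op+" = 0.05, "op-" = 0.05,
                                           unaffected = 0.60),
                       baseline_log2 = 8.0,
                       baseline_sd = 1.0,
                       frac_genes_with_peak = 0.8,
                       n_decoy_peaks = 200,
                       window = 300000,
                       peak_width = 400,
                       multi_tss_fraction = 0,
                       seed = 1L) {
  if (n_genes < 0) stop("n_genes must be >= 0")
  if (length(chrom_lengths) == 0) stop("chrom_lengths must be non-empty")
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome in chrom_lengths")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be named")
  if (reps_per_condition < 2) stop("reps_per_condition must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  need <- c("co+", "co-", "op+", "op-", "unaffected")
  if (!setequal(names(class_fractions), need))
    stop("class_fractions must name exactly: ", paste(need, collapse = ", "))
  class_fractions <- class_fractions[need]
  if (any(class_fractions < 0)) stop("class fractions must be >= 0")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  if (delta_log2fc >= effect_log2fc)
    stop("delta_log2fc must be < effect_log2fc so 'co-' genes keep their ",
         "direction of androgen regulation")
  structure(list(n_genes = as.integer(n_genes),
                 n_coregulators = as.integer(n_coregulators),
                 chrom_lengths = chrom_lengths,
                 reps_per_condition = as.integer(reps_per_condition),
                 effect_log2fc = effect_log2fc,
                 delta_log2fc = delta_log2fc,
                 noise_sd = noise_sd,
                 class_fractions = class_fractions,
                 baseline_log2 = baseline_log2,
                 baseline_sd = baseline_sd,
                 frac_genes_with_peak = frac_genes_with_peak,
                 n_decoy_peaks = as.integer(n_decoy_peaks),
                 window = window,
                 peak_width = peak_width,
                 multi_tss_fraction = multi_tss_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# internal: deterministic per-stage seed substream
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage) %% 2147483647)
}

#' Simulate a gene annotation and matching peak set
#'
#' Places one TSS per gene uniformly on the configured chromosomes (a
#' configurable fraction of genes receive a second TSS), builds a small
#' exon structure downstream of each TSS, puts at least one peak with
#' midpoint inside the assignment window for `frac_genes_with_peak` of the
#' genes, and adds decoy peaks in the genome space that lies beyond the
#' window of every TSS (fewer, with a warning, when the windows saturate
#' the genome). Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return list with elements `annotation` (see [gene_annotation()]) and
#'   `peaks` (a peak `data.frame`; gene-linked peaks are named
#'   `ARBS_<gene>_<i>`, decoys `decoy_<i>`).
#' @export
simulate_annotation_and_peaks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1))
  cl <- config$chrom_lengths
  n <- config$n_genes
  w <- config$window
  pw <- config$peak_width

  if (n > 0) {
    chrom <- sample(names(cl), n, replace = TRUE,
                    prob = cl / sum(cl))
    len <- as.numeric(cl[chrom])
    tss1 <- floor(stats::runif(n, 0, len))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    second <- stats::runif(n) < config$multi_tss_fraction
    tss_list <- lapply(seq_len(n), function(i) {
      t1 <- tss1[i]
      if (!second[i]) return(t1)
      t2 <- min(len[i] - 1, t1 + sample(2000:20000, 1))
      sort(unique(c(t1, t2)))
    })
    # 2-4 exons marching downstream of the first TSS (strand-aware)
    exon_list <- lapply(seq_len(n), function(i) {
      k <- sample(2:4, 1)
      sizes <- sample(150:300, k, replace = TRUE)
      gaps <- sample(500:2000, k, replace = TRUE)
      if (strand[i] == "+") {
        s <- tss1[i] + cumsum(c(0, sizes[-k] + gaps[-k]))
        e <- s + sizes
      } else {
        e <- tss1[i] + 1 - cumsum(c(0, sizes[-k] + gaps[-k]))
        s <- e - sizes
      }
      keep <- s >= 0 & e <= len[i] & s < e
      if (!any(keep)) { s <- max(0, tss1[i] - 150); e <- s + 150 }
      else { s <- s[keep]; e <- e[keep] }
      o <- order(s)
      list(starts = s[o], ends = e[o])
    })
    ann <- gene_annotation(
      gene_id = sprintf("gene_%04d", seq_len(n)),
      chrom = chrom, strand = strand, tss = tss_list,
      exon_starts = lapply(exon_list, `[[`, "starts"),
      exon_ends = lapply(exon_list, `[[`, "ends"))
  } else {
    ann <- gene_annotation(character(), character(), character(),
                           list(), list(), list())
  }

  # gene-linked peaks: midpoint within the window of the first TSS
  if (n > 0) {
    with_peak <- which(stats::runif(n) < config$frac_genes_with_peak)
  } else with_peak <- integer()
  if (length(with_peak)) {
    len <- as.numeric(cl[ann$chrom[with_peak]])
    t1 <- vapply(ann$tss[with_peak], function(x) split_coords(x)[1], 0)
    lo <- pmax(ceiling(pw / 2), t1 - w)
    hi <- pmin(floor(len - pw / 2) - 1, t1 + w)
    mid <- floor(lo + stats::runif(length(with_peak)) * (hi - lo + 1))
    gp <- peak_set(chrom = ann$chrom[with_peak],
                   start = mid - floor(pw / 2),
                   end = mid - floor(pw / 2) + pw,
                   name = paste0("ARBS_", ann$gene_id[with_peak], "_1"))
  } else gp <- peak_set(character(), numeric(), numeric())

  # decoy peaks: sampled from the genome space beyond every TSS window
  dp <- peak_set(character(), numeric(), numeric())
  if (config$n_decoy_peaks > 0) {
    tsst <- if (n > 0) tss_table(ann) else
      data.frame(chrom = character(), tss = numeric())
    half_lo <- floor(pw / 2)
    half_hi <- pw - half_lo
    # admissible midpoints: beyond the window of every TSS, with room for
    # the whole peak inside the chromosome
    free <- lapply(names(cl), function(ch) {
      chlen <- as.numeric(cl[[ch]])
      bounds <- IRanges::IRanges(half_lo + 1, chlen - half_hi) # 1-based mids
      t <- tsst$tss[tsst$chrom == ch]
      if (length(t) == 0) return(bounds)
      cov <- IRanges::reduce(
        IRanges::IRanges(pmax(1, t - w + 1), pmin(chlen, t + w + 1)))
      gaps <- IRanges::gaps(cov, start = 1, end = chlen)
      IRanges::restrict(gaps, start = IRanges::start(bounds),
                        end = IRanges::end(bounds))
    })
    names(free) <- names(cl)
    uw <- vapply(free, function(ir) sum(IRanges::width(ir)), 0)
    total <- sum(uw)
    if (total <= 0) {
      warning("no genome space beyond the TSS windows; 0 decoy peaks placed")
    } else {
      k <- config$n_decoy_peaks
      pick_ch <- sample(names(cl), k, replace = TRUE, prob = uw / total)
      starts <- numeric(k); chs <- character(k); ok <- logical(k)
      for (i in seq_len(k)) {
        ir <- free[[pick_ch[i]]]
        if (length(ir) == 0) next
        seg <- sample.int(length(ir), 1,
                          prob = IRanges::width(ir) / sum(IRanges::width(ir)))
        m1 <- IRanges::start(ir)[seg] +
          floor(stats::runif(1) * IRanges::width(ir)[seg]) # 1-based midpoint
        chs[i] <- pick_ch[i]
        starts[i] <- (m1 - 1) - half_lo # 0-based interval start
        ok[i] <- TRUE
      }
      if (any(ok))
        dp <- peak_set(chrom = chs[ok], start = starts[ok],
                       end = starts[ok] + pw,
                       name = paste0("decoy_", seq_len(sum(ok))))
      if (sum(ok) < config$n_decoy_peaks)
        warning("placed ", sum(ok), " of ", config$n_decoy_peaks,
                " decoy peaks (TSS windows cover most of the genome)")
    }
  }
  peaks <- rbind(gp, dp)
  rownames(peaks) <- NULL
  list(annotation = ann, peaks = peaks)
}

#' Simulate a knockdown x treatment expression study with planted classes
#'
#' Generates one sample per (siRNA in {control} + coregulators) x
#' (treatment in {androgen, vehicle}) x replicate. Log2 intensities are
#' `baseline_g + response(g, siRNA) * [treatment == androgen] +
#' N(0, noise_sd)` and the emitted matrix is `2^` of that, so the additive
#' planted effects are exact after log2 transformation. Each gene gets a
#' control androgen response of `+-effect_log2fc`; each (gene, coregulator)
#' pair draws a dependence class from `class_fractions` and its knockdown
#' response follows the class definition:
#' `co+`/`co-` keep the sign and move the magnitude up/down by
#' `delta_log2fc`; `op+`/`op-` flip the sign with the magnitude moved
#' up/down by `delta_log2fc`.
#'
#' @param config a [sim_config()].
#' @param coregulator_names unique names of the simulated coregulators;
#'   default `COREG01 ... COREGnn` per `config$n_coregulators`.
#' @return list with `study` (a raw-intensity [expression_study()]) and
#'   `truth` (list of `genes` = `data.frame(gene_id, control_log2fc)` and
#'   `pairs` = `data.frame(gene_id, coregulator, class, kd_log2fc)`).
#' @export
simulate_expression <- function(config, coregulator_names = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(coregulator_names))
    coregulator_names <- sprintf("COREG%02d", seq_len(config$n_coregulators))
  if (length(coregulator_names) == 0)
    stop("coregulator_names must be non-empty")
  if (anyDuplicated(coregulator_names))
    stop("duplicate coregulator names")
  set.seed(stage_seed(config$seed, 2))
  n <- config$n_genes
  genes <- sprintf("gene_%04d", seq_len(n))
  reps <- config$reps_per_condition
  sirnas <- c("control", coregulator_names)
  design <- expand.grid(replicate = seq_len(reps),
                        treatment = c("vehicle", "androgen"),
                        sirna = sirnas,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("sirna", "treatment", "replicate")]
  design$sample_id <- paste(design$sirna, design$treatment,
                            design$replicate, sep = "_")

  baseline <- config$baseline_log2 +
    stats::rnorm(n, 0, config$baseline_sd)
  csign <- sample(c(-1, 1), n, replace = TRUE)
  control_fc <- csign * config$effect_log2fc

  cls_levels <- names(config$class_fractions)
  ncg <- length(coregulator_names)
  cls <- matrix(sample(cls_levels, n * ncg, replace = TRUE,
                       prob = config$class_fractions),
                nrow = n, ncol = ncg,
                dimnames = list(genes, coregulator_names))
  d <- config$delta_log2fc
  kd_fc <- matrix(control_fc, n, ncg)
  mag <- abs(control_fc)
  kd_fc[cls == "co+"] <- (csign * (mag + d))[row(cls)[cls == "co+"]]
  kd_fc[cls == "co-"] <- (csign * (mag - d))[row(cls)[cls == "co-"]]
  kd_fc[cls == "op+"] <- (-csign * (mag + d))[row(cls)[cls == "op+"]]
  kd_fc[cls == "op-"] <- (-csign * (mag - d))[row(cls)[cls == "op-"]]

  response_for <- function(sirna) {
    if (sirna == "control") control_fc
    else kd_fc[, match(sirna, coregulator_names)]
  }
  logm <- matrix(0, nrow = n, ncol = nrow(design),
                 dimnames = list(genes, design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- baseline +
      (design$treatment[j] == "androgen") * response_for(design$sirna[j])
    logm[, j] <- mu + if (config$noise_sd > 0)
      stats::rnorm(n, 0, config$noise_sd) else 0
  }
  study <- expression_study(2^logm, design, log2_transformed = FALSE)
  truth <- list(
    genes = data.frame(gene_id = genes, control_log2fc = control_fc,
                       stringsAsFactors = FALSE),
    pairs = data.frame(gene_id = rep(genes, ncg),
                       coregulator = rep(coregulator_names, each = n),
                       class = as.character(cls),
                       kd_log2fc = as.numeric(kd_fc),
                       stringsAsFactors = FALSE))
  list(study = study, truth = truth)
}

#' Built-in androgen-response-element-like PWM
#'
#' A 15-bp palindromic two-half-site motif (AGAACAnnnTGTTCT) used by the
#' simulator to plant binding-site signal in peak sequences and by the
#' pipeline's motif stage as the primary query motif.
#'
#' @param strength probability mass on the consensus base at informative
#'   positions (default 0.85; the remainder is spread evenly).
#' @return a [pwm()].
#' @export
are_pwm <- function(strength = 0.85) {
  consensus <- strsplit("AGAACANNNTGTTCT", "")[[1]]
  m <- t(vapply(consensus, function(b) {
    if (b == "N") rep(0.25, 4)
    else {
      v <- rep((1 - strength) / 3, 4)
      v[match(b, c("A", "C", "G", "T"))] <- strength
      v
    }
  }, numeric(4)))
  rownames(m) <- NULL
  pwm("ARE", m)
}

#' Simulate DNA sequences for a set of peaks
#'
#' Draws an i.i.d. uniform-background sequence for every peak and embeds
#' one sampled realisation of a motif (bases drawn per-position from the
#' PWM) at a random offset in the selected peaks. Used by the pipeline's
#' motif stage, where no real genome exists.
#'
#' @param peaks a peak `data.frame`; sequence lengths follow the interval
#'   widths.
#' @param plant_in named list: motif id -> character vector of peak names
#'   receiving one embedded instance of that motif.
#' @param pwms named list of [pwm()] objects covering the ids in
#'   `plant_in`.
#' @param seed RNG seed for this stage.
#' @return named character vector of sequences (names = peak names).
#' @export
simulate_peak_sequences <- function(peaks, plant_in = list(), pwms = list(),
                                    seed = 1L) {
  peaks <- validate_peaks(peaks)
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  widths <- peaks$end - peaks$start
  seqs <- vapply(widths, function(wd) {
    paste(sample(bases, wd, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- peaks$name
  for (mid in names(plant_in)) {
    p <- pwms[[mid]]
    if (is.null(p)) stop("plant_in references unknown motif: ", mid)
    L <- nrow(p$mat)
    for (nm in intersect(plant_in[[mid]], names(seqs))) {
      wd <- nchar(seqs[[nm]])
      if (wd < L) next
      inst <- paste(vapply(seq_len(L), function(i) {
        sample(bases, 1, prob = p$mat[i, ])
      }, character(1)), collapse = "")
      at <- sample.int(wd - L + 1, 1)
      substr(seqs[[nm]], at, at + L - 1) <- inst
    }
  }
  seqs
}
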