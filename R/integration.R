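#' Assign peaks to genes by TSS proximity
#'
#' Emits one assignment for every (peak, TSS) pair on the same chromosome
#' whose peak midpoint lies within `window` bp of the TSS (inclusive). A
#' peak may map to several genes and a gene to several peaks; a gene with
#' multiple TSSs is matched through any of them. The midpoint of the
#' half-open interval `[start, end)` is `floor((start + end) / 2)`.
#'
#' Peaks on chromosomes absent from the annotation are skipped with a
#' warning rather than an error.
#'
#' @param peaks a peak `data.frame` (see [peak_set()]).
#' @param annotation a gene annotation (see [gene_annotation()]).
#' @param window maximum midpoint-to-TSS distance in bp (default 300000,
#'   i.e. 300 kb).
#' @return `data.frame` with columns `peak` (name), `gene_id`, `tss` and
#'   `distance` (bp, midpoint minus TSS, oriented so that positive values
#'   are downstream of the TSS on the gene's strand).
#' @examples
#' ann <- gene_annotation("g1", "chr1", "+", 400000, 400000, 400600)
#' pk <- peak_set("chr1", 140000, 160000)
#' assign_peaks_to_tss(pk, ann) # midpoint 150000, distance -250000
#' @export
assign_peaks_to_tss <- function(peaks, annotation, window = 300000) {
  peaks <- validate_peaks(peaks)
  if (!(is.numeric(window) && length(window) == 1 && window > 0))
    stop("window must be a positive number")
  tss <- tss_table(annotation)
  missing_chr <- setdiff(unique(peaks$chrom), unique(tss$chrom))
  if (length(missing_chr))
    warning("skipping peaks on chromosome(s) absent from annotation: ",
            paste(missing_chr, collapse = ", "))
  empty <- data.frame(peak = character(), gene_id = character(),
                      tss = numeric(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0 || nrow(tss) == 0) return(empty)

  mid <- peak_midpoint(peaks)
  lv <- unique(c(peaks$chrom, tss$chrom))
  q <- GenomicRanges::GRanges(factor(peaks$chrom, levels = lv),
                              IRanges::IRanges(mid + 1, mid + 1))
  # inclusive window [tss - window, tss + window] in 0-based positions
  s <- GenomicRanges::GRanges(
    factor(tss$chrom, levels = lv),
    IRanges::IRanges(pmax(0, tss$tss - window) + 1, tss$tss + window + 1))
  hits <- GenomicRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) return(empty)
  raw <- mid[qi] - tss$tss[si]
  keep <- abs(raw) <= window # exact inclusive filter (guards clipped left ends)
  qi <- qi[keep]; si <- si[keep]; raw <- raw[keep]
  data.frame(peak = peaks$name[qi],
             gene_id = tss$gene_id[si],
             tss = tss$tss[si],
             distance = ifelse(tss$strand[si] == "-", -raw, raw),
             stringsAsFactors = FALSE)
}

#' Nominate target genes by cross-matching peak assignments with
#' regulated-gene lists
#'
#' A gene is nominated when it carries at least one peak assignment and
#' appears in at least `min_lists` of the supplied regulated-gene lists.
#'
#' @param assignments output of [assign_peaks_to_tss()].
#' @param regulated_lists list of character vectors of gene identifiers
#'   (published androgen-regulated gene lists); must be non-empty.
#' @param min_lists minimum number of lists a gene must appear in
#'   (default 1).
#' @return sorted character vector of nominated gene identifiers.
#' @export
nominate_targets <- function(assignments, regulated_lists, min_lists = 1) {
  if (!is.list(regulated_lists) || length(regulated_lists) == 0)
    stop("regulated_lists must be a non-empty list of gene vectors")
  if (!(is.numeric(min_lists) && min_lists >= 1))
    stop("min_lists must be >= 1")
  with_peak <- unique(as.character(assignments$gene_id))
  if (length(with_peak) == 0) return(character())
  hits <- rowSums(vapply(regulated_lists,
                         function(l) with_peak %in% l,
                         logical(length(with_peak))))
  sort(with_peak[hits >= min_lists])
}

#' Categorize peak locations relative to gene structure
#'
#' Each peak (by midpoint) receives exactly one category with precedence
#' promoter > exon > intron > intergenic. The promoter window is the closed
#' interval `[TSS - promoter_upstream, TSS + promoter_downstream]`,
#' orientated by gene strand. Introns are positions inside a gene's exon
#' span that fall in no exon. Gene tables do not identify enhancers, so
#' distal regulatory regions fall into intergenic (or intronic) here.
#'
#' @param peaks a peak `data.frame`.
#' @param annotation a gene annotation; must be non-empty.
#' @param promoter_upstream,promoter_downstream promoter window half-widths
#'   in bp (defaults 3000 and 500).
#' @return named integer vector of counts for categories `promoter`,
#'   `exon`, `intron`, `intergenic`; sums to `nrow(peaks)`.
#' @export
categorize_peak_locations <- function(peaks, annotation,
                                      promoter_upstream = 3000,
                                      promoter_downstream = 500) {
  peaks <- validate_peaks(peaks)
  if (nrow(annotation) == 0) stop("annotation must be non-empty")
  cats <- c("promoter", "exon", "intron", "intergenic")
  if (nrow(peaks) == 0)
    return(stats::setNames(rep(0L, 4), cats))

  mid <- peak_midpoint(peaks)
  tss <- tss_table(annotation)
  ex <- exon_table(annotation)
  lv <- unique(c(peaks$chrom, tss$chrom, ex$chrom))
  pt <- GenomicRanges::GRanges(factor(peaks$chrom, levels = lv),
                               IRanges::IRanges(mid + 1, mid + 1))
  hit_any <- function(start0, end0, chrom) {
    # closed 0-based position interval [start0, end0] -> 1-based [s+1, e+1]
    keep <- start0 <= end0
    gr <- GenomicRanges::GRanges(
      factor(chrom[keep], levels = lv),
      IRanges::IRanges(pmax(0, start0[keep]) + 1, end0[keep] + 1))
    GenomicRanges::countOverlaps(pt, gr) > 0
  }
  up <- ifelse(tss$strand == "-", promoter_downstream, promoter_upstream)
  dn <- ifelse(tss$strand == "-", promoter_upstream, promoter_downstream)
  in_prom <- hit_any(tss$tss - up, tss$tss + dn, tss$chrom)
  in_exon <- if (nrow(ex)) hit_any(ex$start, ex$end - 1, ex$chrom)
             else rep(FALSE, nrow(peaks))
  # gene span: min exon start .. max exon end per gene
  if (nrow(ex)) {
    sp_start <- tapply(ex$start, ex$gene_id, min)
    sp_end <- tapply(ex$end, ex$gene_id, max)
    sp_chrom <- ex$chrom[match(names(sp_start), ex$gene_id)]
    in_body <- hit_any(as.numeric(sp_start), as.numeric(sp_end) - 1, sp_chrom)
  } else in_body <- rep(FALSE, nrow(peaks))

  cat_vec <- rep("intergenic", nrow(peaks))
  cat_vec[in_body & !in_exon] <- "intron"
  cat_vec[in_exon] <- "exon"
  cat_vec[in_prom] <- "promoter"
  out <- table(factor(cat_vec, levels = cats))
  stats::setNames(as.integer(out), cats)
}

#' Fraction of peaks in A overlapping peaks in B
#'
#' Fraction of records in `peaksA` with at least 1 bp overlap with any
#' record in `peaksB`. An empty `peaksA` yields 0 with a warning.
#'
#' @param peaksA,peaksB peak `data.frame`s.
#' @return a number in `[0, 1]`.
#' @export
overlap_fraction <- function(peaksA, peaksB) {
  peaksA <- validate_peaks(peaksA, "peaksA")
  peaksB <- validate_peaks(peaksB, "peaksB")
  if (nrow(peaksA) == 0) {
    warning("peaksA is empty; overlap fraction defined as 0")
    return(0)
  }
  if (nrow(peaksB) == 0) return(0)
  lv <- unique(c(peaksA$chrom, peaksB$chrom))
  ga <- peaks_to_granges(peaksA, extra_seqs = lv)
  gb <- peaks_to_granges(peaksB, extra_seqs = lv)
  mean(GenomicRanges::countOverlaps(ga, gb) > 0)
}

#' Extend peaks symmetrically, clipping at chromosome bounds
#'
#' Each interval `[start, end)` becomes
#' `[max(0, start - pad), min(chrom_length, end + pad))`. The record count
#' is unchanged. When `pad > 0`, `chrom_sizes` must name every chromosome
#' present in `peaks` so the right end can be clipped.
#'
#' @param peaks a peak `data.frame`.
#' @param pad extension in bp at both ends (default 1000); `pad = 0`
#'   returns the input unchanged.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return the extended peak `data.frame`.
#' @export
extend_peaks <- function(peaks, pad = 1000, chrom_sizes) {
  peaks <- validate_peaks(peaks)
  if (!(is.numeric(pad) && length(pad) == 1 && pad >= 0))
    stop("pad must be a single non-negative number")
  if (pad == 0) return(peaks)
  missing_chr <- setdiff(unique(peaks$chrom), names(chrom_sizes))
  if (length(missing_chr))
    stop("chrom_sizes missing chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  len <- as.numeric(chrom_sizes[peaks$chrom])
  out <- peaks
  out$start <- pmax(0, peaks$start - pad)
  out$end <- pmin(len, peaks$end + pad)
  out
}
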