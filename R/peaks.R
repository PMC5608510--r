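#' Construct a peak set
#'
#' A peak set is a plain `data.frame` of genomic intervals in 0-based,
#' half-open coordinates (`[start, end)`, the BED convention), with optional
#' `name`, `score` and `strand` columns. All interval operations in the
#' package (`assign_peaks_to_tss()`, `overlap_fraction()`,
#' `categorize_peak_locations()`, `extend_peaks()`) consume this format.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` for every record.
#' @param name optional record names (default `peak_1`, `peak_2`, ...).
#' @param score optional numeric scores (default 0).
#' @param strand optional strand in `+`, `-`, `.` (default `.`).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @examples
#' peak_set("chr1", c(100, 500), c(300, 900))
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL,
                     strand = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (n > 0 && any(!is.finite(start) | !is.finite(end)))
    stop("peak coordinates must be finite")
  if (any(start < 0)) stop("peak start must be >= 0")
  if (any(start >= end)) stop("peaks must satisfy start < end (half-open)")
  if (is.null(name)) name <- if (n) paste0("peak_", seq_len(n)) else character()
  if (is.null(score)) score <- rep(0, n)
  if (is.null(strand)) strand <- rep(".", n)
  data.frame(chrom = as.character(chrom), start = start, end = end,
             name = as.character(name), score = as.numeric(score),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

# internal: validate an object as a peak set data.frame
validate_peaks <- function(peaks, arg = "peaks") {
  if (!is.data.frame(peaks) ||
      !all(c("chrom", "start", "end") %in% names(peaks)))
    stop(arg, " must be a data.frame with columns chrom, start, end")
  if (nrow(peaks) > 0) {
    if (any(peaks$start < 0) || any(peaks$start >= peaks$end))
      stop(arg, " has records violating 0 <= start < end")
  }
  peaks
}

# internal: peak midpoints under the half-open convention
peak_midpoint <- function(peaks) floor((peaks$start + peaks$end) / 2)

# internal: convert a peak set to GRanges (1-based closed coordinates)
peaks_to_granges <- function(peaks, extra_seqs = character()) {
  lv <- unique(c(extra_seqs, as.character(peaks$chrom)))
  if (length(lv) == 0) lv <- "chrUn"
  GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = lv),
    ranges = IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
}

#' Read / write BED peak files
#'
#' Thin wrappers around [rtracklayer::import()]/[rtracklayer::export()] that
#' translate between BED (0-based half-open on disk) and the package's peak
#' `data.frame` representation, which uses the same convention.
#'
#' @param path file path.
#' @param peaks a peak set as returned by [peak_set()].
#' @return `read_bed()` returns a peak `data.frame`; `write_bed()` returns
#'   `path` invisibly.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  n <- length(gr)
  nm <- if (!is.null(gr$name)) as.character(gr$name) else NULL
  sc <- if (!is.null(gr$score)) as.numeric(gr$score) else NULL
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  peak_set(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1,
           end = GenomicRanges::end(gr),
           name = nm, score = sc, strand = if (n) st else NULL)
}

#' @rdname read_bed
#' @export
write_bed <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  gr <- peaks_to_granges(peaks)
  strand_chr <- peaks$strand
  strand_chr[!strand_chr %in% c("+", "-")] <- "*"
  GenomicRanges::strand(gr) <- strand_chr
  gr$name <- peaks$name
  gr$score <- peaks$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chromosome name and length in bp (no header).
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  stats::setNames(as.numeric(tab$length), tab$chrom)
}

#' Gene annotation table
#'
#' A gene annotation is a `data.frame` with one row per gene:
#' `gene_id`, `chrom`, `strand` (`+`/`-`), `tss` (comma-separated 0-based
#' TSS positions; genes may have several TSSs), `exon_starts` and
#' `exon_ends` (comma-separated, 0-based half-open, sorted,
#' non-overlapping). [gene_annotation()] validates and normalises the
#' fields; `read_gene_annotation()`/`write_gene_annotation()` round-trip the
#' table through TSV.
#'
#' @param gene_id,chrom,strand per-gene character vectors.
#' @param tss list (or comma-separated character vector) of TSS positions.
#' @param exon_starts,exon_ends lists (or comma-separated character vectors)
#'   of exon coordinates.
#' @return a validated annotation `data.frame`.
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss,
                            exon_starts, exon_ends) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (n > 0 && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  join <- function(x) {
    if (is.list(x)) vapply(x, function(v) paste(v, collapse = ","), "")
    else as.character(x)
  }
  ann <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    tss = join(tss),
                    exon_starts = join(exon_starts),
                    exon_ends = join(exon_ends),
                    stringsAsFactors = FALSE)
  # validate exon structure per gene
  for (i in seq_len(n)) {
    es <- split_coords(ann$exon_starts[i])
    ee <- split_coords(ann$exon_ends[i])
    if (length(es) != length(ee)) stop("exon_starts/exon_ends length mismatch")
    if (length(es) && (any(es >= ee) || is.unsorted(es, strictly = TRUE) ||
                       any(es[-1] < ee[-length(ee)])))
      stop("exons must be sorted, non-overlapping intervals with start < end")
  }
  ann
}

# internal: "100,200" -> c(100, 200)
split_coords <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric())
  as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' @rdname gene_annotation
#' @param path file path.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  gene_annotation(tab$gene_id, tab$chrom, tab$strand, tab$tss,
                  tab$exon_starts, tab$exon_ends)
}

#' @rdname gene_annotation
#' @param annotation an annotation `data.frame`.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Long-format TSS table of an annotation
#'
#' Expands the comma-separated `tss` column into one row per (gene, TSS).
#'
#' @param annotation an annotation `data.frame` (see [gene_annotation()]).
#' @return `data.frame` with columns `gene_id`, `chrom`, `strand`, `tss`.
#' @export
tss_table <- function(annotation) {
  tl <- lapply(annotation$tss, split_coords)
  k <- lengths(tl)
  data.frame(gene_id = rep(annotation$gene_id, k),
             chrom = rep(annotation$chrom, k),
             strand = rep(annotation$strand, k),
             tss = unlist(tl, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# internal: long exon table (gene_id, chrom, start, end)
exon_table <- function(annotation) {
  es <- lapply(annotation$exon_starts, split_coords)
  ee <- lapply(annotation$exon_ends, split_coords)
  k <- lengths(es)
  data.frame(gene_id = rep(annotation$gene_id, k),
             chrom = rep(annotation$chrom, k),
             start = unlist(es, use.names = FALSE),
             end = unlist(ee, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Read newline-delimited gene lists
#'
#' @param paths character vector of file paths, one gene symbol per line.
#' @return list of character vectors (blank lines dropped).
#' @export
read_gene_lists <- function(paths) {
  lapply(paths, function(p) {
    x <- readLines(p, warn = FALSE)
    x[nzchar(trimws(x))]
  })
}
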