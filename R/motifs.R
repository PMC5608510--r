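#' Position weight matrix
#'
#' @param id motif identifier.
#' @param mat numeric L x 4 matrix of per-position base probabilities,
#'   columns in A, C, G, T order; each row must sum to 1 (tolerance 1e-6).
#'   A count matrix is accepted and converted to probabilities.
#' @param background base frequencies (A, C, G, T), summing to 1
#'   (default uniform).
#' @param pseudocount additive smoothing applied to the probabilities
#'   before log-odds scoring (default 1e-3), so zero entries stay finite.
#' @return an object of class `pwm`.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4), pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("mat must have 4 columns (A, C, G, T)")
  if (any(mat < 0)) stop("mat entries must be non-negative")
  rs <- rowSums(mat)
  if (any(rs <= 0)) stop("each position needs positive mass")
  if (any(abs(rs - 1) > 1e-6)) mat <- mat / rs # counts -> probabilities
  if (abs(sum(background) - 1) > 1e-6)
    stop("background must sum to 1")
  colnames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, mat = mat,
                 background = stats::setNames(background, c("A", "C", "G", "T")),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "- length", nrow(x$mat), "\n")
  invisible(x)
}

# internal: log2-odds matrix with additive pseudocount smoothing
pwm_log_odds <- function(p) {
  pc <- p$pseudocount
  pr <- (p$mat + pc) / (1 + 4 * pc)
  log2(sweep(pr, 2, p$background, "/"))
}

#' Maximum achievable log-odds score of a PWM
#'
#' @param p a [pwm()].
#' @return sum over positions of the best per-position log2-odds.
#' @export
pwm_max_score <- function(p) sum(apply(pwm_log_odds(p), 1, max))

#' Scan a DNA sequence with a PWM
#'
#' Slides the motif over both strands and scores each window by
#' `sum(log2(p_base / bg_base))`. Windows containing non-ACGT characters
#' never match. Hit positions are 0-based window starts on the forward
#' strand; the reverse strand is scanned by scoring the
#' reverse-complemented matrix on the forward sequence.
#'
#' @param seq DNA string, length >= motif length.
#' @param p a [pwm()].
#' @param score_min log-odds threshold for a hit; default 80% of the
#'   motif's maximum achievable score.
#' @return list with `has_hit` (logical) and `hits`
#'   (`data.frame(pos, strand, score)`).
#' @export
scan_sequence <- function(seq, p, score_min = NULL) {
  stopifnot(inherits(p, "pwm"))
  if (is.null(score_min)) score_min <- 0.8 * pwm_max_score(p)
  lom <- pwm_log_odds(p)
  L <- nrow(lom)
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  n <- length(chars)
  if (n < L) stop("sequence shorter than motif (", n, " < ", L, ")")
  code <- match(chars, c("A", "C", "G", "T")) # NA for ambiguous bases
  nw <- n - L + 1
  score_with <- function(m) {
    sc <- numeric(nw)
    ok <- rep(TRUE, nw)
    for (j in seq_len(L)) {
      cj <- code[j:(j + nw - 1)]
      ok <- ok & !is.na(cj)
      v <- m[j, ifelse(is.na(cj), 1L, cj)]
      sc <- sc + v
    }
    sc[!ok] <- -Inf
    sc
  }
  fwd <- score_with(lom)
  lom_rc <- lom[L:1, 4:1, drop = FALSE] # reverse positions, complement bases
  rev <- score_with(lom_rc)
  fi <- which(fwd >= score_min)
  ri <- which(rev >= score_min)
  hits <- rbind(
    data.frame(pos = fi - 1, strand = rep("+", length(fi)),
               score = fwd[fi]),
    data.frame(pos = ri - 1, strand = rep("-", length(ri)),
               score = rev[ri]))
  hits <- hits[order(hits$pos, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  list(has_hit = nrow(hits) > 0, hits = hits)
}

# internal: logical vector, one entry per sequence, any hit
scan_presence <- function(seqs, p, score_min) {
  vapply(seqs, function(s) scan_sequence(s, p, score_min)$has_hit,
         logical(1), USE.NAMES = FALSE)
}

#' Per-signature motif over-representation
#'
#' For each motif and each foreground signature, counts the sequences with
#' at least one hit and tests enrichment of the foreground hit rate over
#' the background rate. The default test is the upper-tail binomial
#' `P(X >= k_fg | n_fg, k_bg / n_bg)` (backgrounds are large and
#' resampled); an exact hypergeometric on the pooled sequences is
#' available via `method`. P-values are Benjamini-Hochberg adjusted across
#' motifs within each signature; the `enriched` flag applies `alpha` to
#' the adjusted values.
#'
#' @param fg_seqs named list of character vectors: foreground sequences
#'   per signature.
#' @param bg_seqs character vector of background sequences (non-empty).
#' @param pwms list of [pwm()] objects (a single `pwm` is accepted).
#' @param score_min log-odds hit threshold; `NULL` (default) uses 80% of
#'   each motif's maximum achievable score.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param method `"binomial"` (default) or `"hypergeometric"`.
#' @return `data.frame` with columns `motif`, `signature`, `n_fg`, `k_fg`,
#'   `n_bg`, `k_bg`, `p_value`, `q_value`, `enriched`.
#' @export
motif_enrichment <- function(fg_seqs, bg_seqs, pwms, score_min = NULL,
                             alpha = 0.05,
                             method = c("binomial", "hypergeometric")) {
  method <- match.arg(method)
  if (length(bg_seqs) == 0) stop("bg_seqs must be non-empty")
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.null(names(fg_seqs)) || any(!nzchar(names(fg_seqs))))
    stop("fg_seqs must be a named list of signatures")
  n_bg <- length(bg_seqs)
  rows <- list()
  for (p in pwms) {
    smin <- if (is.null(score_min)) 0.8 * pwm_max_score(p) else score_min
    k_bg <- sum(scan_presence(bg_seqs, p, smin))
    for (sig in names(fg_seqs)) {
      fg <- fg_seqs[[sig]]
      n_fg <- length(fg)
      k_fg <- sum(scan_presence(fg, p, smin))
      pv <- if (k_fg == 0) 1 else if (method == "binomial") {
        stats::pbinom(k_fg - 1, n_fg, k_bg / n_bg, lower.tail = FALSE)
      } else {
        stats::phyper(k_fg - 1, k_fg + k_bg, n_fg + n_bg - k_fg - k_bg,
                      n_fg, lower.tail = FALSE)
      }
      rows[[length(rows) + 1]] <-
        data.frame(motif = p$id, signature = sig, n_fg = n_fg, k_fg = k_fg,
                   n_bg = n_bg, k_bg = k_bg, p_value = min(1, pv),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (sig in unique(out$signature)) {
    i <- out$signature == sig
    out$q_value[i] <- bh_adjust(out$p_value[i])
  }
  out$enriched <- out$q_value < alpha
  rownames(out) <- NULL
  out
}

#' Selectively enriched motifs
#'
#' Motifs whose enrichment flag is set in at least one and at most
#' `max_signatures` signatures; such motifs discriminate between
#' coregulator-dependent signatures instead of marking all of them.
#'
#' @param records an enrichment table from [motif_enrichment()].
#' @param max_signatures maximum number of signatures a selective motif
#'   may be enriched in (default 2).
#' @return named list: motif id -> character vector of signatures.
#' @export
selective_motifs <- function(records, max_signatures = 2) {
  enr <- records[records$enriched %in% TRUE, , drop = FALSE]
  sigs <- split(enr$signature, enr$motif)
  sigs <- lapply(sigs, unique)
  sigs[lengths(sigs) >= 1 & lengths(sigs) <= max_signatures]
}

#' Read JASPAR-format PWM files
#'
#' Parses the JASPAR text format: a `>id name` header followed by four
#' lines `A [ counts... ]`, `C [...]`, `G [...]`, `T [...]` (brackets
#' optional). Counts are converted to probabilities per position.
#'
#' @param path file path; may contain several motifs.
#' @param background,pseudocount passed to [pwm()].
#' @return named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4),
                        pseudocount = 1e-3) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no '>' headers found in ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    j <- if (h < length(heads)) heads[h + 1] - 1 else length(lines)
    id <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]][1]
    block <- lines[(i + 1):j]
    if (length(block) < 4) stop("motif ", id, ": expected 4 base rows")
    vals <- lapply(block[1:4], function(l) {
      base <- sub("^\\s*([ACGTacgt]).*", "\\1", l)
      nums <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", l))
      list(base = toupper(base),
           v = as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    })
    bases <- vapply(vals, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("motif ", id, ": rows must cover A, C, G, T")
    m <- do.call(cbind, lapply(c("A", "C", "G", "T"), function(b) {
      vals[[match(b, bases)]]$v
    }))
    out[[id]] <- pwm(id, m, background, pseudocount)
  }
  out
}

#' Read a minimal MEME-format motif file
#'
#' Supports the MEME minimal text format: optional
#' `Background letter frequencies` line, then for each motif a
#' `MOTIF <id>` line, a `letter-probability matrix:` line, and `w` rows of
#' four probabilities (A C G T).
#'
#' @inheritParams read_jaspar
#' @return named list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path, warn = FALSE)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    toks <- strsplit(trimws(lines[bgl[1] + 1]), "\\s+")[[1]]
    freq <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(freq) <- toupper(toks[seq(1, length(toks), by = 2)])
    bg <- unname(freq[c("A", "C", "G", "T")])
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) stop("no MOTIF entries found in ", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]][1]
    lp <- s + grep("^letter-probability matrix",
                   lines[(s + 1):length(lines)])[1]
    w <- suppressWarnings(
      as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[lp])))
    rows <- list()
    i <- lp + 1
    while (i <= length(lines)) {
      v <- suppressWarnings(
        as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(v) != 4 || any(is.na(v))) break
      rows[[length(rows) + 1]] <- v
      i <- i + 1
      if (!is.na(w) && length(rows) == w) break
    }
    m <- do.call(rbind, rows)
    out[[id]] <- pwm(id, m, bg, pseudocount)
  }
  out
}

#' Read / write FASTA sequence files
#'
#' Wrappers around [Biostrings::readDNAStringSet()] returning plain named
#' character vectors, the representation the scanner consumes.
#'
#' @param path file path.
#' @param seqs named character vector of DNA sequences.
#' @return `read_fasta()` a named character vector; `write_fasta()` the
#'   path, invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Shuffle sequences preserving composition
#'
#' `method = "dinucleotide"` performs an Altschul-Erickson shuffle that
#' preserves the exact dinucleotide counts of each sequence (a uniform
#' random Eulerian path on the dinucleotide multigraph);
#' `method = "mononucleotide"` permutes the characters. Randomness comes
#' from the R session RNG; call `set.seed()` first for reproducibility.
#'
#' @param seqs character vector of sequences.
#' @param method shuffle type.
#' @return character vector of shuffled sequences.
#' @export
shuffle_sequences <- function(seqs,
                              method = c("dinucleotide", "mononucleotide")) {
  method <- match.arg(method)
  vapply(seqs, function(s) {
    if (method == "mononucleotide") {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    } else {
      shuffle_dinuc_one(s)
    }
  }, character(1), USE.NAMES = FALSE)
}

# internal: Altschul-Erickson dinucleotide-preserving shuffle of one
# sequence; first and last characters are fixed by construction
shuffle_dinuc_one <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (n < 3) return(s)
  from <- chars[-n]
  to <- chars[-1]
  fin <- chars[n]
  verts <- unique(chars)
  out_edges <- split(to, from) # multiset of successors per vertex
  # choose random last out-edges forming a tree oriented towards `fin`
  repeat {
    last_to <- vapply(verts, function(v) {
      if (v == fin || is.null(out_edges[[v]])) NA_character_
      else out_edges[[v]][sample.int(length(out_edges[[v]]), 1)]
    }, character(1))
    ok <- TRUE
    for (v in verts) {
      if (v == fin || is.null(out_edges[[v]])) next
      cur <- v
      seen <- character()
      while (cur != fin) {
        if (cur %in% seen || is.na(last_to[cur])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_to[cur]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # permute the remaining out-edges; append the chosen last edge
  ordered <- lapply(stats::setNames(verts, verts), function(v) {
    ev <- out_edges[[v]]
    if (is.null(ev)) return(character())
    if (!is.na(last_to[v])) {
      drop <- match(last_to[v], ev)
      ev <- ev[-drop]
    }
    ev <- if (length(ev) > 1) sample(ev) else ev
    c(ev, if (!is.na(last_to[v])) last_to[v])
  })
  used <- stats::setNames(integer(length(verts)), verts)
  res <- character(n)
  res[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- ordered[[cur]][used[cur]]
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}
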