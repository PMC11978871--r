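#' Repeat feature table constructor / validator
#'
#' Repeats are 0-based half-open intervals (BED convention) with a strand
#' and a family label.
#'
#' @param chrom,start,end,strand,family Vectors of equal length;
#'   \code{start < end}, strand in \code{+}/\code{-}.
#' @param name Optional feature names (default family_i).
#' @return A data frame of class \code{repeat_features}.
#' @export
repeat_features <- function(chrom, start, end, strand, family,
                            name = NULL) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(strand), length(strand) == length(family))
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start >= end)) stop("repeat features must have start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (is.null(name)) name <- paste0(family, "_", seq_along(chrom))
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       name = name, strand = as.character(strand),
                       family = as.character(family),
                       stringsAsFactors = FALSE),
            class = c("repeat_features", "data.frame"))
}

#' Detect inverted-repeat pairs by local alignment
#'
#' For each same-family pair of repeats on one chromosome with opposite
#' strands and a gap of at most \code{window} bp, the plus-strand sequence of
#' the upstream repeat is aligned against the reverse complement of the
#' downstream repeat with exact affine-gap local (Smith-Waterman) alignment
#' using the blastn-style scores match +2, mismatch -3, gap open 5, gap
#' extend 2. Pairs whose alignment identity (matches / alignment columns)
#' exceeds \code{min_identity} and whose aligned span covers at least
#' \code{min_coverage} of the shorter repeat are reported as inverted-repeat
#' pairs. A repeat may belong to multiple pairs.
#'
#' @param repeats A \code{\link{repeat_features}} table.
#' @param genome A named \code{Biostrings::DNAStringSet} (or named character
#'   vector) with one entry per chromosome.
#' @param window Maximum gap between the two repeats, bp (default 1500).
#' @param min_identity Identity threshold in percent (default 80; strictly
#'   greater-than).
#' @param min_coverage Minimum aligned fraction of the shorter repeat
#'   (default 0.8).
#' @return A data frame of class \code{ir_pairs}: indices and names of the
#'   upstream/downstream members, \code{gap_bp}, \code{percent_identity},
#'   \code{alignment_score}, \code{coverage}.
#' @export
find_ir_pairs <- function(repeats, genome, window = 1500, min_identity = 80,
                          min_coverage = 0.8) {
  stopifnot(is.data.frame(repeats))
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  miss <- setdiff(unique(repeats$chrom), names(genome))
  if (length(miss)) stop("no genome sequence for chromosome(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(repeats$end > Biostrings::width(genome)[match(repeats$chrom, names(genome))] |
                 repeats$start < 0)
  if (length(bad)) {
    stop("repeat feature outside sequence bounds: ",
         paste(repeats$name[bad], collapse = ", "))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  ord <- order(repeats$chrom, repeats$start)
  rp <- repeats[ord, , drop = FALSE]
  rp$.idx <- ord
  out <- list()
  for (chr in unique(rp$chrom)) {
    rc <- rp[rp$chrom == chr, , drop = FALSE]
    n <- nrow(rc)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        gap <- rc$start[j] - rc$end[i]
        if (gap > window) break  # sorted by start; later j only further away
        if (rc$family[i] != rc$family[j]) next
        if (rc$strand[i] == rc$strand[j]) next
        s_up <- Biostrings::subseq(genome[[chr]], rc$start[i] + 1, rc$end[i])
        s_dn <- Biostrings::subseq(genome[[chr]], rc$start[j] + 1, rc$end[j])
        aln <- Biostrings::pairwiseAlignment(
          s_up, Biostrings::reverseComplement(s_dn), type = "local",
          substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
        cols <- nchar(as.character(Biostrings::pattern(aln)))
        if (cols == 0) next
        ident <- 100 * Biostrings::nmatch(aln) / cols
        span_p <- Biostrings::width(Biostrings::pattern(aln))
        span_s <- Biostrings::width(Biostrings::subject(aln))
        shorter <- min(rc$end[i] - rc$start[i], rc$end[j] - rc$start[j])
        coverage <- min(span_p, span_s) / shorter
        if (ident > min_identity && coverage >= min_coverage) {
          out[[length(out) + 1]] <- data.frame(
            upstream = rc$.idx[i], downstream = rc$.idx[j],
            upstream_name = rc$name[i], downstream_name = rc$name[j],
            chrom = chr, gap_bp = gap, percent_identity = ident,
            alignment_score = Biostrings::score(aln), coverage = coverage,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(upstream = integer(0), downstream = integer(0),
               upstream_name = character(0), downstream_name = character(0),
               chrom = character(0), gap_bp = integer(0),
               percent_identity = numeric(0), alignment_score = numeric(0),
               coverage = numeric(0))
  rownames(res) <- NULL
  structure(res, repeats = repeats, class = c("ir_pairs", "data.frame"))
}

#' Coverage track constructor / validator
#'
#' A per-base coverage track as sorted, non-overlapping 0-based half-open
#' intervals with a value each, plus a normalization record.
#'
#' @param chrom,start,end,value Equal-length vectors.
#' @param normalized Logical; has per-million scaling been applied.
#' @param total_reads Total (non-rRNA) mapped reads behind the track, if
#'   known.
#' @return A data frame of class \code{coverage_track}.
#' @export
coverage_track <- function(chrom = character(0), start = integer(0),
                           end = integer(0), value = numeric(0),
                           normalized = FALSE, total_reads = NA_real_) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start >= df$end)) stop("coverage intervals must have start < end")
    if (any(!is.finite(df$value))) stop("coverage values must be finite")
    ord <- order(df$chrom, df$start)
    if (!identical(ord, seq_len(nrow(df)))) df <- df[ord, , drop = FALSE]
    ov <- unlist(tapply(seq_len(nrow(df)), df$chrom, function(i) {
      if (length(i) < 2) return(FALSE)
      df$start[i][-1] < df$end[i][-length(i)]
    }))
    if (any(ov)) stop("coverage intervals overlap within a chromosome")
    rownames(df) <- NULL
  }
  structure(df, normalized = normalized, total_reads = total_reads,
            class = c("coverage_track", "data.frame"))
}

#' Scale a coverage track to per-million non-rRNA reads
#'
#' Multiplies every value by \code{1e6 / total_non_rrna_reads}, i.e. rescales
#' the track as if one million non-rRNA reads had been mapped; the
#' normalization is recorded on the track.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param total_non_rrna_reads Total non-rRNA mapped read count (> 0).
#' @return The normalized \code{coverage_track}.
#' @export
normalize_coverage <- function(track, total_non_rrna_reads) {
  stopifnot(inherits(track, "coverage_track"))
  if (!is.numeric(total_non_rrna_reads) || total_non_rrna_reads <= 0) {
    stop("total_non_rrna_reads must be > 0")
  }
  coverage_track(track$chrom, track$start, track$end,
                 track$value * 1e6 / total_non_rrna_reads,
                 normalized = TRUE, total_reads = total_non_rrna_reads)
}

# piecewise-constant combination of two tracks on one chromosome; segments
# between the pooled breakpoints are fully inside or outside each interval
combine_chrom <- function(a, b, op) {
  bp <- sort(unique(c(a$start, a$end, b$start, b$end)))
  if (length(bp) < 2) return(NULL)
  s <- bp[-length(bp)]
  e <- bp[-1]
  val_at <- function(tr, pos) {
    v <- numeric(length(pos))
    if (nrow(tr)) {
      idx <- findInterval(pos, tr$start)
      hit <- idx >= 1 & pos < tr$end[pmax(idx, 1)]
      v[hit] <- tr$value[idx[hit]]
    }
    v
  }
  in_track <- function(tr, pos) {
    if (!nrow(tr)) return(rep(FALSE, length(pos)))
    idx <- findInterval(pos, tr$start)
    idx >= 1 & pos < tr$end[pmax(idx, 1)]
  }
  covered <- in_track(a, s) | in_track(b, s)
  data.frame(start = s, end = e, value = op(val_at(a, s), val_at(b, s)))[covered, , drop = FALSE]
}

#' Subtract one coverage track from another
#'
#' Interval-intersection arithmetic \code{a - b} over the union of
#' breakpoints; regions covered by only one track treat the other as zero.
#' The output spans the union of covered regions (zero-valued segments from
#' exact cancellation are retained), with adjacent equal-value segments
#' merged.
#'
#' @param a,b \code{\link{coverage_track}}s (typically both normalized).
#' @return A \code{coverage_track} of \code{a - b}.
#' @export
subtract_tracks <- function(a, b) {
  stopifnot(inherits(a, "coverage_track"), inherits(b, "coverage_track"))
  chroms <- union(unique(a$chrom), unique(b$chrom))
  pieces <- lapply(chroms, function(chr) {
    ac <- a[a$chrom == chr, , drop = FALSE]
    bc <- b[b$chrom == chr, , drop = FALSE]
    seg <- combine_chrom(ac, bc, `-`)
    if (is.null(seg) || !nrow(seg)) return(NULL)
    seg <- merge_equal_runs(seg)
    cbind(chrom = chr, seg, stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) return(coverage_track(normalized = attr(a, "normalized")))
  df <- do.call(rbind, pieces)
  coverage_track(df$chrom, df$start, df$end, df$value,
                 normalized = isTRUE(attr(a, "normalized")) && isTRUE(attr(b, "normalized")))
}

merge_equal_runs <- function(seg) {
  if (nrow(seg) < 2) return(seg)
  keep <- logical(nrow(seg))
  keep[1] <- TRUE
  for (i in 2:nrow(seg)) {
    keep[i] <- !(seg$start[i] == seg$end[i - 1] && seg$value[i] == seg$value[i - 1])
  }
  grp <- cumsum(keep)
  out <- do.call(rbind, lapply(split(seq_len(nrow(seg)), grp), function(ii) {
    data.frame(start = seg$start[ii[1]], end = seg$end[ii[length(ii)]],
               value = seg$value[ii[1]])
  }))
  rownames(out) <- NULL
  out
}

#' Threshold-and-merge peak calling on a coverage track
#'
#' A deliberately simple stand-in for bedGraph peak callers: maximal runs of
#' intervals with \code{value >= min_value} are merged across gaps of at most
#' \code{merge_gap} bp and kept if at least \code{min_length} bp long.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param min_value Minimum value for a base to be inside a peak.
#' @param min_length Minimum peak length, bp.
#' @param merge_gap Maximum gap to bridge between adjacent runs, bp.
#' @return Data frame of peak intervals: \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @export
call_peaks <- function(track, min_value = 1, min_length = 50, merge_gap = 0) {
  stopifnot(inherits(track, "coverage_track"), min_value >= 0,
            min_length >= 0, merge_gap >= 0)
  out <- lapply(unique(track$chrom), function(chr) {
    tc <- track[track$chrom == chr & track$value >= min_value, , drop = FALSE]
    if (!nrow(tc)) return(NULL)
    # merge runs that touch or are within merge_gap
    starts <- tc$start
    ends <- tc$end
    keep_start <- c(TRUE, starts[-1] - ends[-length(ends)] > merge_gap)
    grp <- cumsum(keep_start)
    ms <- tapply(starts, grp, min)
    me <- tapply(ends, grp, max)
    d <- data.frame(chrom = chr, start = as.integer(ms), end = as.integer(me),
                    stringsAsFactors = FALSE)
    d[d$end - d$start >= min_length, , drop = FALSE]
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Area under the coverage curve over an interval
#'
#' \code{sum(value * overlap_width)} over all track intervals intersecting
#' the peak.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param chrom,start,end The query interval (0-based half-open).
#' @return The AuC in value x bp units (0 if the peak is disjoint from the
#'   track).
#' @export
peak_auc <- function(track, chrom, start, end) {
  tc <- track[track$chrom == chrom, , drop = FALSE]
  if (!nrow(tc)) return(0)
  ov <- pmin(tc$end, end) - pmax(tc$start, start)
  sum(tc$value[ov > 0] * ov[ov > 0])
}

#' Quantify peaks across enrichment and input tracks
#'
#' Computes, per peak, the AuC in the enrichment (fCLIP) and input tracks
#' and the log2 fold change \code{log2((auc_fclip + pseudo) / (auc_input +
#' pseudo))}; a pseudo-AuC floor avoids division by zero. If control tracks
#' (the same libraries without the tagged protein) are supplied, their log2FC
#' is reported alongside and the standard enrichment filter is
#' \code{log2fc >= 1} with \code{control_log2fc <= 0}.
#'
#' @param peaks Peak data frame (\code{chrom}, \code{start}, \code{end}).
#' @param fclip,input Normalized \code{\link{coverage_track}}s.
#' @param control_fclip,control_input Optional control tracks.
#' @param pseudo Pseudo-AuC floor in normalized units (default 1).
#' @return A data frame of class \code{peak_quant}: the peak coordinates
#'   plus \code{auc_fclip}, \code{auc_input}, \code{log2fc},
#'   \code{control_log2fc} (NA without controls), and \code{enriched}.
#' @export
quantify_peaks <- function(peaks, fclip, input, control_fclip = NULL,
                           control_input = NULL, pseudo = 1) {
  stopifnot(inherits(fclip, "coverage_track"), inherits(input, "coverage_track"),
            pseudo >= 0)
  if (!isTRUE(attr(fclip, "normalized")) || !isTRUE(attr(input, "normalized"))) {
    warning("quantifying unnormalized tracks; log2FC will depend on depth")
  }
  n <- nrow(peaks)
  auc_f <- auc_i <- ctrl <- numeric(n)
  for (i in seq_len(n)) {
    auc_f[i] <- peak_auc(fclip, peaks$chrom[i], peaks$start[i], peaks$end[i])
    auc_i[i] <- peak_auc(input, peaks$chrom[i], peaks$start[i], peaks$end[i])
    if (!is.null(control_fclip) && !is.null(control_input)) {
      cf <- peak_auc(control_fclip, peaks$chrom[i], peaks$start[i], peaks$end[i])
      ci <- peak_auc(control_input, peaks$chrom[i], peaks$start[i], peaks$end[i])
      ctrl[i] <- log2((cf + pseudo) / (ci + pseudo))
    } else {
      ctrl[i] <- NA_real_
    }
  }
  if (pseudo == 0 && any(auc_i == 0)) {
    warning("zero input AuC without a pseudo-floor; log2FC is infinite for ",
            sum(auc_i == 0), " peak(s)")
  }
  l2 <- log2((auc_f + pseudo) / (auc_i + pseudo))
  enriched <- l2 >= 1 & (is.na(ctrl) | ctrl <= 0)
  out <- cbind(peaks, auc_fclip = auc_f, auc_input = auc_i, log2fc = l2,
               control_log2fc = ctrl, enriched = enriched)
  rownames(out) <- NULL
  structure(out, class = c("peak_quant", "data.frame"))
}

#' Classify peaks relative to inverted-repeat pairs
#'
#' A peak overlapping a member of an inverted-repeat pair is classified
#' \code{"IR-Alu"}; a peak within less than \code{window} bp of a member, or
#' lying between the two members of one pair (flanked), is
#' \code{"near IR-Alu"}; anything else is \code{"other"}.
#'
#' @param peaks Peak data frame (\code{chrom}, \code{start}, \code{end}).
#' @param ir_pairs An \code{\link{find_ir_pairs}} result (its \code{repeats}
#'   attribute supplies member coordinates).
#' @param window Proximity window, bp (default 300, strict inequality).
#' @return Character vector of classifications, one per peak.
#' @export
annotate_near_ir <- function(peaks, ir_pairs, window = 300) {
  reps <- attr(ir_pairs, "repeats")
  n <- nrow(peaks)
  cls <- rep("other", n)
  if (is.null(reps) || nrow(ir_pairs) == 0 || n == 0) return(cls)
  members <- unique(c(ir_pairs$upstream, ir_pairs$downstream))
  mem <- reps[members, , drop = FALSE]
  for (i in seq_len(n)) {
    pc <- peaks$chrom[i]; ps <- peaks$start[i]; pe <- peaks$end[i]
    m <- mem[mem$chrom == pc, , drop = FALSE]
    if (nrow(m) && any(pmin(m$end, pe) - pmax(m$start, ps) > 0)) {
      cls[i] <- "IR-Alu"
      next
    }
    near <- nrow(m) && any(pmax(m$start - pe, ps - m$end) < window &
                             pmax(m$start - pe, ps - m$end) >= 0)
    if (!near) {
      # flanked: peak strictly between the two members of one pair
      for (j in seq_len(nrow(ir_pairs))) {
        if (ir_pairs$chrom[j] != pc) next
        up <- reps[ir_pairs$upstream[j], ]
        dn <- reps[ir_pairs$downstream[j], ]
        if (ps >= up$end && pe <= dn$start) { near <- TRUE; break }
      }
    }
    if (near) cls[i] <- "near IR-Alu"
  }
  cls
}

#' Editing level as mismatch counts per million reads
#'
#' A-to-G mismatch CPM per region: \code{count * 1e6 / total_mapped_reads}.
#' Counts are assumed strand-resolved upstream (A-to-G on plus-strand
#' features, T-to-C on minus-strand features).
#'
#' @param mismatch_counts Named or unnamed vector of per-region A-to-G
#'   mismatch counts.
#' @param total_mapped_reads Total mapped reads (> 0).
#' @return An \code{editing_stats} data frame: \code{region},
#'   \code{mismatch_count}, \code{cpm}, with the aggregate CPM as attribute
#'   \code{total_cpm}.
#' @export
editing_cpm <- function(mismatch_counts, total_mapped_reads) {
  if (!is.numeric(total_mapped_reads) || total_mapped_reads <= 0) {
    stop("total_mapped_reads must be > 0")
  }
  stopifnot(all(mismatch_counts >= 0))
  region <- names(mismatch_counts)
  if (is.null(region)) region <- paste0("region", seq_along(mismatch_counts))
  cpm <- mismatch_counts * 1e6 / total_mapped_reads
  structure(data.frame(region = region,
                       mismatch_count = as.numeric(mismatch_counts),
                       cpm = as.numeric(cpm), stringsAsFactors = FALSE),
            total_cpm = sum(cpm),
            class = c("editing_stats", "data.frame"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round(divergence * length(chars))
  if (n_mut == 0) return(seq)
  idx <- sample(length(chars), n_mut)
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Synthesize a genome with planted inverted repeats
#'
#' Builds a random-background chromosome carrying \code{n_pairs} planted
#' inverted-repeat pairs at a controlled divergence and gap, plus same-strand
#' (direct-repeat) decoy pairs and inverted pairs separated by more than the
#' detection window. Units are spaced so that no unintended cross-pairing
#' falls within the window. The truth table lists the intended pairs.
#'
#' @param n_pairs Number of planted inverted pairs.
#' @param repeat_len Repeat length, bp (default 300, Alu-like).
#' @param divergence Substitution fraction applied to the downstream copy,
#'   in [0, 1).
#' @param gap_range Range the inter-repeat gap is drawn from, bp.
#' @param n_decoys Same-strand decoy pairs.
#' @param n_over_window Inverted pairs with gap beyond the window.
#' @param over_window_gap Gap used for over-window pairs (default 2000).
#' @param seed Integer seed.
#' @return A list: \code{genome} (named character, one chromosome),
#'   \code{repeats} (a \code{\link{repeat_features}} table), \code{truth}
#'   (data frame of intended pair member names).
#' @export
synth_genome <- function(n_pairs = 20, repeat_len = 300, divergence = 0,
                         gap_range = c(100, 1000), n_decoys = 20,
                         n_over_window = 10, over_window_gap = 2000,
                         seed = 1L) {
  stopifnot(divergence >= 0, divergence < 1, n_pairs >= 0, repeat_len >= 20)
  set.seed(seed)
  spacer <- 3000  # keeps neighbouring units outside any <=1.5 kb window
  pieces <- character(0)
  chrom <- "chrSyn"
  pos <- 0L
  feats <- list()
  truth <- list()
  add_piece <- function(s) {
    pieces[[length(pieces) + 1]] <<- s
    pos <<- pos + nchar(s)
  }
  add_unit <- function(kind, k, gap, invert, diverg) {
    add_piece(random_dna(spacer))
    rseq <- random_dna(repeat_len)
    nm1 <- paste0(kind, k, "_a")
    nm2 <- paste0(kind, k, "_b")
    s1 <- pos
    add_piece(rseq)
    e1 <- pos
    add_piece(random_dna(gap))
    s2 <- pos
    second <- if (invert) rev_comp(mutate_seq(rseq, diverg)) else mutate_seq(rseq, diverg)
    add_piece(second)
    e2 <- pos
    feats[[length(feats) + 1]] <<- data.frame(
      chrom = chrom, start = c(s1, s2), end = c(e1, e2),
      name = c(nm1, nm2), strand = c("+", if (invert) "-" else "+"),
      family = "AluSyn", stringsAsFactors = FALSE)
    if (invert && gap <= 1500) {
      truth[[length(truth) + 1]] <<- data.frame(upstream_name = nm1,
                                                downstream_name = nm2,
                                                stringsAsFactors = FALSE)
    }
  }
  for (k in seq_len(n_pairs)) {
    add_unit("ir", k, sample(gap_range[1]:gap_range[2], 1), TRUE, divergence)
  }
  for (k in seq_len(n_decoys)) {
    add_unit("direct", k, sample(gap_range[1]:gap_range[2], 1), FALSE, divergence)
  }
  for (k in seq_len(n_over_window)) {
    add_unit("far", k, over_window_gap, TRUE, divergence)
  }
  add_piece(random_dna(spacer))
  fdf <- do.call(rbind, feats)
  genome <- stats::setNames(paste(pieces, collapse = ""), chrom)
  list(genome = genome,
       repeats = repeat_features(fdf$chrom, fdf$start, fdf$end, fdf$strand,
                                 fdf$family, fdf$name),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(upstream_name = character(0),
                    downstream_name = character(0)))
}

rev_comp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
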