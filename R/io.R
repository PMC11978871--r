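#' Write / read a fluorescence trace as tab-separated text
#'
#' Traces are written as a TSV (\code{frame_index}, \code{time_s},
#' \code{donor}, \code{acceptor}) with a JSON sidecar (\code{<file>.json})
#' carrying the frame interval, seed, and config hash, so that
#' \code{read_trace(write_trace(x))} reproduces the object bit-exactly.
#'
#' @param trace A \code{fluorescence_trace}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  utils::write.table(format(as.data.frame(trace), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(frame_interval = attr(trace, "frame_interval"),
               seed = attr(trace, "seed"),
               config_hash = attr(trace, "config_hash"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @param path Path of a TSV written by \code{write_trace}.
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("frame_index", "time_s", "donor", "acceptor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("malformed trace file ", path, ": missing column(s) ",
                         paste(miss, collapse = ", "))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  fi <- meta$frame_interval
  if (is.null(fi)) fi <- if (nrow(df) >= 2) diff(df$time_s[1:2]) else NA_real_
  structure(df, frame_interval = as.numeric(fi),
            seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_,
            config_hash = meta$config_hash,
            class = c("fluorescence_trace", "data.frame"))
}

#' Write / read gel lanes as CSV
#'
#' Lanes are stored one per row: \code{conc_nM, I0, I1, ..., In}.
#'
#' @param lanes List of \code{\link{gel_lane}} objects (equal site counts).
#' @param path CSV path.
#' @return \code{path}, invisibly (write); a list of \code{gel_lane}s (read).
#' @export
write_lanes <- function(lanes, path) {
  ns <- unique(vapply(lanes, function(l) l$n_sites, integer(1)))
  if (length(ns) != 1) stop("all lanes must have the same number of sites")
  m <- t(vapply(lanes, function(l) c(l$protein_conc, l$band_intensities),
                numeric(ns + 2)))
  colnames(m) <- c("conc_nM", paste0("I", 0:ns))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lanes
#' @export
read_lanes <- function(path) {
  df <- utils::read.csv(path)
  if (!"conc_nM" %in% names(df)) {
    stop("malformed lane file ", path, ": missing conc_nM column")
  }
  icols <- grep("^I[0-9]+$", names(df), value = TRUE)
  if (length(icols) < 2) stop("malformed lane file ", path, ": no band columns")
  icols <- icols[order(as.integer(sub("I", "", icols)))]
  lapply(seq_len(nrow(df)), function(i) {
    gel_lane(df$conc_nM[i], as.numeric(df[i, icols]))
  })
}

#' Write / read a coverage track in bedGraph format
#'
#' Four whitespace-delimited columns (chrom, start, end, value), 0-based
#' half-open. Reading validates the records: non-numeric fields, start >=
#' end, or unsorted/overlapping intervals are rejected with a diagnostic
#' naming the offending line.
#'
#' @param track A \code{\link{coverage_track}}.
#' @param path bedGraph path.
#' @return \code{path}, invisibly (write); a \code{coverage_track} (read).
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  utils::write.table(as.data.frame(track)[, c("chrom", "start", "end", "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) return(coverage_track())
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 4)) {
    stop("malformed bedGraph ", path, ": line ", which(nf < 4)[1],
         " has fewer than 4 fields")
  }
  chrom <- vapply(parts, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  value <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 4)))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) stop("malformed bedGraph ", path, ": non-numeric field on line ", bad[1])
  bad <- which(start >= end)
  if (length(bad)) stop("malformed bedGraph ", path, ": start >= end on line ", bad[1])
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    if (length(i) > 1 && any(diff(start[i]) < 0)) {
      stop("bedGraph ", path, " is not sorted by start within ", chr,
           "; sort the file (e.g. sort -k1,1 -k2,2n) and retry")
    }
  }
  coverage_track(chrom, start, end, value)
}

#' Write / read BED6 feature files
#'
#' Writes \code{\link{repeat_features}} as BED6 (name column carries the
#' feature name, score 0, family appended as a 7th column). Reading
#' validates coordinates and strand.
#'
#' @param features A \code{\link{repeat_features}} table.
#' @param path BED path.
#' @return \code{path}, invisibly (write); a \code{repeat_features} (read).
#' @export
write_bed <- function(features, path) {
  stopifnot(is.data.frame(features))
  df <- data.frame(features$chrom, features$start, features$end,
                   features$name, 0L, features$strand, features$family)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  nf <- lengths(parts)
  if (any(nf < 6)) {
    stop("malformed BED ", path, ": line ", which(nf < 6)[1],
         " has fewer than 6 fields")
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("malformed BED ", path, ": non-numeric coordinate on line ", bad[1])
  bad <- which(start >= end)
  if (length(bad)) stop("malformed BED ", path, ": start >= end on line ", bad[1])
  strand <- vapply(parts, `[`, character(1), 6)
  if (!all(strand %in% c("+", "-"))) {
    stop("malformed BED ", path, ": strand must be '+' or '-'")
  }
  family <- if (all(nf >= 7)) vapply(parts, `[`, character(1), 7) else
    vapply(parts, `[`, character(1), 4)
  repeat_features(vapply(parts, `[`, character(1), 1), start, end, strand,
                  family, name = vapply(parts, `[`, character(1), 4))
}

#' Write / read a genome as FASTA
#'
#' Thin wrappers over \code{Biostrings} FASTA I/O returning plain named
#' character vectors.
#'
#' @param genome Named character vector (or \code{DNAStringSet}).
#' @param path FASTA path.
#' @return \code{path}, invisibly (write); a named character vector (read).
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Derive a child seed from a global seed
#'
#' Deterministic fan-out of one run-level seed into per-module seeds, kept
#' within the 32-bit integer range.
#'
#' @param global_seed Integer run seed.
#' @param index Child index (>= 1).
#' @return Integer child seed.
#' @export
derive_seed <- function(global_seed, index) {
  as.integer((as.numeric(global_seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

#' Execute a named pipeline step and write a run manifest
#'
#' A minimal reproducible-run driver: executes one of the package's
#' subcommands with the parameters in \code{config}, writes its outputs
#' under \code{out_dir}, and records a manifest (subcommand, parameters,
#' seeds, package version, MD5 of every output file). Re-running the same
#' config and seed reproduces the outputs bit-exactly.
#'
#' Subcommands: \code{simulate-traces}, \code{analyze-traces},
#' \code{fit-binding}, \code{simulate-activation}, \code{find-ir},
#' \code{quantify-peaks}, \code{synth-genome}.
#'
#' @param config A list with \code{subcommand}, \code{seed}, and a
#'   \code{params} list understood by the subcommand.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$subcommand)) stop("config$subcommand is missing")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- config$params
  if (is.null(params)) params <- list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  sub <- config$subcommand
  if (sub == "simulate-traces") {
    cfg <- do.call(sim_config, c(params$config, list(rng_seed = derive_seed(seed, 1))))
    fp <- do.call(fret_model_params, if (is.null(params$fret)) list() else params$fret)
    n <- if (is.null(params$n_molecules)) 5L else as.integer(params$n_molecules)
    sim <- simulate_traces(cfg, fp, n)
    for (i in seq_len(n)) {
      f <- file.path(out_dir, sprintf("trace_%03d.tsv", i))
      write_trace(sim$traces[[i]], f)
      files <- c(files, f, paste0(f, ".json"))
    }
  } else if (sub == "analyze-traces") {
    paths <- params$traces
    if (is.null(paths)) {
      paths <- list.files(params$in_dir, pattern = "\\.tsv$", full.names = TRUE)
    }
    if (!length(paths) || !all(file.exists(unlist(paths)))) {
      stop("missing input trace file(s): ",
           paste(unlist(paths)[!file.exists(unlist(paths))], collapse = ", "))
    }
    traces <- lapply(paths, read_trace)
    fp <- do.call(fret_model_params, if (is.null(params$fret)) list() else params$fret)
    res <- analyze_traces(traces, fp)
    f <- file.path(out_dir, "analysis.json")
    jsonlite::write_json(list(
      sliding_time_s = res$autocorrelation$sliding_time,
      sliding_time_se = res$autocorrelation$sliding_time_se,
      n_events = res$autocorrelation$n_events,
      mean_residence_s = mean(res$residence_s)), f, auto_unbox = TRUE,
      digits = NA)
    files <- c(files, f)
    if (!is.null(res$events)) {
      f2 <- file.path(out_dir, "events.tsv")
      utils::write.table(res$events, f2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f2)
    }
    if (!is.null(res$autocorrelation)) {
      f3 <- file.path(out_dir, "autocorrelation.tsv")
      utils::write.table(data.frame(lag_s = res$autocorrelation$lag_s,
                                    G = res$autocorrelation$G),
                         f3, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f3)
    }
    if (!res$histogram$empty) {
      f4 <- file.path(out_dir, "fret_histogram.tsv")
      utils::write.table(data.frame(bin_low = utils::head(res$histogram$breaks, -1),
                                    bin_high = res$histogram$breaks[-1],
                                    count = res$histogram$counts),
                         f4, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f4)
    }
  } else if (sub == "fit-binding") {
    if (!file.exists(params$lanes)) stop("missing input file: ", params$lanes)
    lanes <- read_lanes(params$lanes)
    bc <- binding_curve(lanes, fix_h = params$fix_h)
    f <- file.path(out_dir, "hill_fit.json")
    jsonlite::write_json(unclass(bc$fit), f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  } else if (sub == "simulate-activation") {
    kp <- do.call(kinetic_params, c(params$kinetics,
                                    list(rng_seed = derive_seed(seed, 2))))
    hs <- do.call(heatmap_spec, c(params$grid, list(params = kp)))
    hm <- activation_heatmap(hs)
    f <- file.path(out_dir, "activation_heatmap.csv")
    utils::write.csv(hm, f, row.names = FALSE)
    files <- c(files, f)
  } else if (sub == "synth-genome") {
    sg <- do.call(synth_genome, c(params, list(seed = derive_seed(seed, 3))))
    f1 <- file.path(out_dir, "genome.fa")
    f2 <- file.path(out_dir, "repeats.bed")
    write_fasta(sg$genome, f1)
    write_bed(sg$repeats, f2)
    files <- c(files, f1, f2)
  } else if (sub == "find-ir") {
    for (p in c(params$genome, params$repeats)) {
      if (!file.exists(p)) stop("missing input file: ", p)
    }
    genome <- read_fasta(params$genome)
    reps <- read_bed(params$repeats)
    pairs <- find_ir_pairs(reps, genome,
                           window = if (is.null(params$window)) 1500 else params$window,
                           min_identity = if (is.null(params$min_identity)) 80 else params$min_identity)
    f <- file.path(out_dir, "ir_pairs.tsv")
    utils::write.table(as.data.frame(pairs), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  } else if (sub == "quantify-peaks") {
    for (p in c(params$fclip, params$input)) {
      if (!file.exists(p)) stop("missing input file: ", p)
    }
    fclip <- normalize_coverage(read_bedgraph(params$fclip), params$fclip_total)
    input <- normalize_coverage(read_bedgraph(params$input), params$input_total)
    peaks <- call_peaks(subtract_tracks(fclip, input),
                        min_value = if (is.null(params$min_value)) 1 else params$min_value,
                        min_length = if (is.null(params$min_length)) 50 else params$min_length)
    pq <- quantify_peaks(peaks, fclip, input)
    f <- file.path(out_dir, "peak_quant.tsv")
    utils::write.table(as.data.frame(pq), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  } else {
    stop("unknown subcommand: ", sub)
  }
  manifest <- list(subcommand = sub, seed = seed, params = params,
                   package_version = as.character(utils::packageVersion("pkrscan")),
                   outputs = lapply(stats::setNames(files, basename(files)),
                                    function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
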