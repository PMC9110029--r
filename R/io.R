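# Readers and writers for the pipeline's tabular and sequence formats.

#' Read transport traces from CSV
#'
#' Long format needs columns `time_min` and `signal`, with optional
#' `construct`, `condition`, `replicate`. Wide format (one `time_min`
#' column followed by one column per replicate) is auto-detected; the other
#' columns become replicates 1..k sharing the time grid. Non-monotonic
#' times are reported with the offending row number.
#'
#' @param path CSV file path.
#' @return A list of [transport_trace()] objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_min" %in% names(df))
    stop("missing required column 'time_min' in ", path)
  if ("signal" %in% names(df)) {
    if (!"construct" %in% names(df)) df$construct <- "unknown"
    if (!"condition" %in% names(df)) df$condition <- "unknown"
    if (!"replicate" %in% names(df)) df$replicate <- 1L
    key <- interaction(df$construct, df$condition, df$replicate, drop = TRUE)
    traces <- lapply(split(seq_len(nrow(df)), key), function(idx) {
      sub <- df[idx, ]
      bad <- which(diff(sub$time_min) <= 0)
      if (length(bad))
        stop(sprintf("non-monotonic time at data row %d of %s",
                     idx[bad[1] + 1], path))
      transport_trace(sub$time_min, sub$signal, sub$construct[1],
                      sub$condition[1], sub$replicate[1])
    })
    unname(traces)
  } else {
    reps <- setdiff(names(df), "time_min")
    if (!length(reps))
      stop("missing required column 'signal' in ", path)
    bad <- which(diff(df$time_min) <= 0)
    if (length(bad))
      stop(sprintf("non-monotonic time at data row %d of %s", bad[1] + 1, path))
    lapply(seq_along(reps), function(i) {
      transport_trace(df$time_min, df[[reps[i]]], construct = "unknown",
                      condition = "unknown", replicate = i)
    })
  }
}

#' Write transport traces to long-format CSV
#'
#' Columns: `time_min`, `signal`, `construct`, `condition`, `replicate`.
#'
#' @param traces A [transport_trace()] or list thereof.
#' @param path Output path.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "transport_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_min = tr$times, signal = tr$signal,
               construct = tr$construct, condition = tr$condition,
               replicate = tr$replicate, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a step scan as CSV plus a JSON summary
#'
#' @param scan A `step_scan` from [scan_steps()].
#' @param csv_path,json_path Output paths (either may be NULL to skip).
#' @export
write_scan <- function(scan, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(scan, "step_scan"))
  if (!is.null(csv_path))
    utils::write.csv(scan$table, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(best_n = scan$best_n, plateau = scan$plateau,
                              best_fit = as.list(scan$best_fit),
                              replicate_mode = scan$replicate_mode),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(scan)
}

#' Read an annotated protein set from FASTA plus a TSV annotation table
#'
#' The annotation table has columns `id`, `loc_class` and (for secreted
#' records) 1-based inclusive `ss_start`, `ss_end` (UniProt convention).
#' FASTA ids absent from the table (or vice versa) are reported with a
#' warning and dropped; an empty intersection aborts; a signal-peptide
#' span beyond the sequence end is a hard error naming the record.
#'
#' @param fasta_path Path to an amino-acid FASTA file.
#' @param annot_path Path to the tab-separated annotation table.
#' @return A list of [protein_record()]s.
#' @export
read_annotated_fasta <- function(fasta_path, annot_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  annot <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  req <- c("id", "loc_class")
  if (!all(req %in% names(annot)))
    stop("annotation table needs columns: ", paste(req, collapse = ", "))
  if (!"ss_start" %in% names(annot)) annot$ss_start <- NA_integer_
  if (!"ss_end" %in% names(annot)) annot$ss_end <- NA_integer_
  common <- intersect(ids, annot$id)
  if (!length(common))
    stop("no FASTA ids match the annotation table")
  only_fa <- setdiff(ids, annot$id)
  only_an <- setdiff(annot$id, ids)
  if (length(only_fa))
    warning("FASTA ids without annotation (excluded): ",
            paste(utils::head(only_fa, 5), collapse = ", "))
  if (length(only_an))
    warning("annotated ids missing from FASTA (excluded): ",
            paste(utils::head(only_an, 5), collapse = ", "))
  lapply(common, function(id) {
    row <- annot[match(id, annot$id), ]
    seq <- as.character(seqs[[match(id, ids)]])
    if (!is.na(row$ss_end) && row$ss_end >= nchar(seq))
      stop("signal peptide span exceeds sequence for record ", id)
    protein_record(id, seq, row$loc_class,
                   ss_start = row$ss_start, ss_end = row$ss_end)
  })
}

#' Write a synthetic proteome as FASTA plus annotation TSV
#'
#' @param proteome A [make_proteome()] result.
#' @param fasta_path,annot_path Output paths.
#' @export
write_proteome <- function(proteome, fasta_path, annot_path) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  seqs <- Biostrings::AAStringSet(
    vapply(proteome$records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(proteome$records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(proteome$annotation, annot_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(proteome)
}
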