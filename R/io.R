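#' Read event-level data from FCS or delimited text
#'
#' Reads an `n x d` event matrix from either an FCS 3.0/3.1 file (detected
#' by its magic bytes) or a comma-separated text table with a header row.
#' Channel names for FCS come from the `$PnN` keywords (with `$PnS` as the
#' alternative short name; `$PnN` is preferred).
#'
#' @param path file path.
#' @param channels optional character vector selecting (and ordering)
#'   channels; an unknown channel is an error that lists the available
#'   names.
#' @param sample_id sample identifier; defaults to the file name.
#' @return an [event_matrix()].
#' @export
read_events <- function(path, channels = NULL, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- basename(path)
  magic <- readBin(path, "raw", n = 6L)
  is_fcs <- identical(rawToChar(magic[1:3]), "FCS")
  mat <- if (is_fcs) read_fcs_matrix(path) else read_csv_matrix(path)
  if (!is.null(channels)) {
    missing <- setdiff(channels, colnames(mat))
    if (length(missing)) {
      stop("channel(s) not found: ", paste(missing, collapse = ", "),
           "; available: ", paste(colnames(mat), collapse = ", "),
           call. = FALSE)
    }
    mat <- mat[, channels, drop = FALSE]
  }
  event_matrix(mat, sample_id = sample_id)
}

read_csv_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("no events in ", path, call. = FALSE)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    stop("malformed delimited file (non-numeric columns): ", path,
         call. = FALSE)
  }
  mat
}

# Minimal FCS 3.0/3.1 reader: HEADER offsets -> TEXT keywords -> DATA.
# Supports list-mode ($MODE L) float ($DATATYPE F), double (D) and
# unsigned integer (I) data with uniform byte order.
read_fcs_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version: ", version, call. = FALSE)
  }
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)

  seek(con, text_beg)
  txt <- readChar(con, text_end - text_beg + 1L, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- stats::setNames(parts[seq(2, length(parts), 2)],
                        toupper(trimws(parts[seq(1, length(parts), 2)])))

  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(trimws(kw[["$DATATYPE"]]))
  mode <- toupper(trimws(kw[["$MODE"]]))
  if (!identical(mode, "L")) {
    stop("only list-mode ($MODE L) FCS data is supported", call. = FALSE)
  }
  byteord <- trimws(kw[["$BYTEORD"]])
  endian <- if (byteord %in% c("1,2,3,4")) "little" else "big"
  if (data_beg == 0 && !is.na(kw["$BEGINDATA"])) {
    data_beg <- as.numeric(trimws(kw[["$BEGINDATA"]]))
    data_end <- as.numeric(trimws(kw[["$ENDDATA"]]))
  }
  bits <- as.integer(kw[paste0("$P", seq_len(npar), "B")])
  seek(con, data_beg)
  nvals <- npar * ntot
  vals <- switch(dtype,
    F = readBin(con, "numeric", n = nvals, size = 4L, endian = endian),
    D = readBin(con, "numeric", n = nvals, size = 8L, endian = endian),
    I = {
      if (length(unique(bits)) != 1 || !unique(bits) %in% c(16L, 32L)) {
        stop("only uniform 16- or 32-bit integer FCS data is supported",
             call. = FALSE)
      }
      readBin(con, "integer", n = nvals, size = unique(bits) / 8L,
              endian = endian, signed = unique(bits) > 16L)
    },
    stop("unsupported $DATATYPE: ", dtype, call. = FALSE))
  if (length(vals) < nvals) {
    stop("malformed FCS file: truncated DATA segment", call. = FALSE)
  }
  nm <- kw[paste0("$P", seq_len(npar), "N")]
  alt <- kw[paste0("$P", seq_len(npar), "S")]
  nm[is.na(nm)] <- alt[is.na(nm)]
  nm[is.na(nm)] <- paste0("P", which(is.na(nm)))
  matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE,
         dimnames = list(NULL, trimws(unname(nm))))
}

#' Write an event matrix to CSV
#'
#' Deterministic column order (as stored), full `%.17g` float precision so
#' a write/read roundtrip is exact.
#'
#' @param Y [event_matrix()] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(Y, path) {
  v <- em_values(Y)
  lines <- c(paste(colnames(v), collapse = ","),
             apply(v, 1, function(r) {
               paste(sprintf("%.17g", r), collapse = ",")
             }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a study report as CSV
#'
#' Emits the per-dataset misclassification table followed by a summary
#' block (prefixed lines) with condition means, intra-metacluster
#' variability and the provenance seed. Byte-identical for identical
#' inputs and seed.
#'
#' @param study a [run_simulation_study()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(study, path) {
  stopifnot(inherits(study, "study_result"))
  pd <- study$per_dataset
  lines <- c("condition,dataset,misclassification,converged",
             sprintf("%s,%d,%.17g,%s", pd$condition, pd$dataset,
                     pd$misclassification, pd$converged))
  s <- study$summary
  lines <- c(lines, "",
             "#summary,condition,mean_misclassification,intra_metacluster_variability",
             sprintf("#summary,%s,%.17g,%.17g", s$condition,
                     s$mean_misclassification,
                     s$intra_metacluster_variability),
             sprintf("#seed,%d", study$seed))
  writeLines(lines, path)
  invisible(path)
}
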