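#' Event-level cytometry matrix
#'
#' Lightweight container for event-level flow cytometry data: an `n x d`
#' numeric matrix (events in rows, channels in columns) carrying channel
#' names and a sample identifier. All core functions accept either an
#' `event_matrix` or a bare numeric matrix/vector.
#'
#' @param values numeric matrix (`n x d`) or vector (treated as one channel)
#'   of per-event intensities; all entries must be finite.
#' @param channel_names character vector of length `d`; defaults to the
#'   column names of `values` or `"ch1"`, ..., `"chd"`.
#' @param sample_id single string identifying the sample.
#'
#' @return An object of class `event_matrix`: the numeric matrix with
#'   attributes `sample_id` and column names set to `channel_names`.
#' @export
#'
#' @examples
#' y <- event_matrix(cbind(FSC = rlnorm(50, 5), SSC = rlnorm(50, 4)))
#' dim(y)
event_matrix <- function(values, channel_names = NULL, sample_id = "sample") {
  if (is.vector(values) && is.numeric(values)) {
    values <- matrix(values, ncol = 1L)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix or vector", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("event matrix must have at least one event and one channel",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("event matrix entries must all be finite", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- colnames(values)
    if (is.null(channel_names)) {
      channel_names <- paste0("ch", seq_len(ncol(values)))
    }
  }
  if (length(channel_names) != ncol(values)) {
    stop("'channel_names' must have one name per column", call. = FALSE)
  }
  colnames(values) <- channel_names
  structure(values, sample_id = as.character(sample_id)[1],
            class = c("event_matrix", class(matrix())))
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix: %d events x %d channels (sample '%s')\n",
              nrow(x), ncol(x), sample_id(x)))
  cat("channels:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname event_matrix
#' @param x object to query or coerce.
#' @export
sample_id <- function(x) {
  sid <- attr(x, "sample_id")
  if (is.null(sid)) "sample" else sid
}

#' @rdname event_matrix
#' @export
as_event_matrix <- function(x, sample_id = "sample") {
  if (inherits(x, "event_matrix")) return(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  event_matrix(x, sample_id = sample_id)
}

# strip the class so plain matrix algebra applies
em_values <- function(x) {
  if (inherits(x, "event_matrix")) {
    attr(x, "sample_id") <- NULL
    class(x) <- setdiff(class(x), "event_matrix")
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  x
}

# short deterministic fingerprint of a data matrix for provenance records
data_fingerprint <- function(x) {
  x <- em_values(x)
  sprintf("n%dd%d-%s", nrow(x), ncol(x),
          format(sum(abs(x)) + sum(x * seq_len(nrow(x))) %% 1e6, digits = 12))
}
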