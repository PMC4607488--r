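#' ICN time-course container
#'
#' Bundles the K network time courses of one scanning session with its
#' sampling interval and condition label. Rows are networks, columns are
#' samples (volumes).
#'
#' @param data numeric K x T matrix; row names are taken as network labels
#'   (defaulting to [default_icn_names()] when absent).
#' @param tr sampling interval in seconds.
#' @param subject subject identifier.
#' @param condition condition label, conventionally `"EO"` or `"EC"`.
#' @return an object of class `time_course_set`.
#' @export
time_course_set <- function(data, tr = 2, subject = NA_character_,
                            condition = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stopf("time courses must be a finite numeric matrix")
  if (nrow(data) < 1L || ncol(data) < 2L)
    stopf("need at least one network and two samples")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stopf("tr must be a positive scalar (seconds)")
  if (is.null(rownames(data)))
    rownames(data) <- default_icn_names(nrow(data))
  structure(list(data = data, tr = tr,
                 subject = as.character(subject),
                 condition = as.character(condition)),
            class = "time_course_set")
}

#' @export
print.time_course_set <- function(x, ...) {
  cat(sprintf("time_course_set: %d networks x %d samples, TR = %gs",
              nrow(x$data), ncol(x$data), x$tr))
  if (!is.na(x$subject)) cat(sprintf(", subject %s", x$subject))
  if (!is.na(x$condition)) cat(sprintf(" [%s]", x$condition))
  cat("\n")
  invisible(x)
}

#' Read/write time-course tables
#'
#' Sessions are stored as tab-separated text with one row per network:
#' the first column (`ICN`) holds the network label, remaining columns the
#' samples.
#'
#' @param path file path.
#' @param tr,subject,condition metadata attached to the returned set.
#' @return [time_course_set()] for the reader; invisible path for the writer.
#' @export
read_timecourses <- function(path, tr = 2, subject = NA_character_,
                             condition = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  dimnames(mat) <- list(as.character(df[[1]]), NULL)
  storage.mode(mat) <- "double"
  time_course_set(mat, tr = tr, subject = subject, condition = condition)
}

#' @rdname read_timecourses
#' @param tcs a [time_course_set()].
#' @export
write_timecourses <- function(tcs, path) {
  df <- data.frame(ICN = rownames(tcs$data), tcs$data, check.names = FALSE)
  colnames(df) <- c("ICN", paste0("t", seq_len(ncol(tcs$data))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 6-column rigid-body motion-parameter file
#'
#' Whitespace-delimited text, one row per volume: three translations in mm
#' followed by three rotations in radians.
#'
#' @param path file path.
#' @return numeric T x 6 matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (ncol(m) != 6L) stopf("motion file must have 6 columns, got %d", ncol(m))
  m
}
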