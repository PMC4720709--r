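# Long-format text I/O for path sets.
#
# Schema: one header line, tab-delimited columns
#   path_id  label  time  coordinate_index  value
# with one row per (path, time, coordinate).  Every path must cover the
# full grid; missing cells are an error.

#' Write a path set as a delimited long-format table
#'
#' @param ps a [pathset()].
#' @param file output path.
#' @return `file`, invisibly.
#' @seealso [read_pathset()]
#' @export
write_pathset <- function(ps, file) {
  stopifnot(inherits(ps, "pathset"))
  n <- ps$n; N <- ps$grid$N; p <- ps$grid$p
  df <- data.frame(
    path_id = rep(seq_len(n), each = N * p),
    label = rep(ps$label, n * N * p),
    time = rep(rep(ps$grid$times, each = p), times = n),
    coordinate_index = rep(rep(seq_len(p), times = N), times = n),
    value = as.vector(sapply(seq_len(n), function(i) stack_paths(
      matrix(ps$paths[i, , ], N, p)))))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a path set from a delimited long-format table
#'
#' Parses the long-format table written by [write_pathset()].  The
#' observation grid is inferred from the distinct times in the file and
#' canonically sorted, so rows may appear in any order; every path must
#' however cover every (time, coordinate) cell exactly once, and all rows
#' must carry the same label.
#'
#' @param file input path.
#' @param p state dimension; inferred from `coordinate_index` by default.
#' @return A [pathset()].
#' @export
read_pathset <- function(file, p = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("path_id", "label", "time", "coordinate_index", "value")
  if (!all(need %in% names(df)))
    stop("header must contain columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$value) || anyNA(df$value))
    stop("non-numeric or missing 'value' at row ",
         which(!is.finite(suppressWarnings(as.numeric(df$value))))[1L])
  times <- sort(unique(df$time))
  coords <- sort(unique(df$coordinate_index))
  if (is.null(p)) p <- length(coords)
  if (!identical(as.integer(coords), seq_len(p)))
    stop("'coordinate_index' must cover 1..p")
  ids <- sort(unique(df$path_id))
  n <- length(ids); N <- length(times)
  labs <- unique(df$label)
  if (length(labs) != 1L)
    stop("all rows must carry the same label; found: ",
         paste(labs, collapse = ", "))
  arr <- array(NA_real_, dim = c(n, N, p))
  ii <- match(df$path_id, ids)
  jj <- match(df$time, times)
  kk <- match(df$coordinate_index, coords)
  flat <- ii + (jj - 1L) * n + (kk - 1L) * n * N
  if (anyDuplicated(flat)) {
    d <- which(duplicated(flat))[1L]
    stop("duplicate cell for path ", df$path_id[d], " at time ",
         df$time[d], " coordinate ", df$coordinate_index[d],
         " (row ", d, ")")
  }
  arr[flat] <- df$value
  if (anyNA(arr)) {
    miss <- which(is.na(arr), arr.ind = TRUE)[1L, ]
    stop("path ", ids[miss[1L]], " is missing time ", times[miss[2L]],
         " coordinate ", miss[3L])
  }
  pathset(arr, obs_grid(times, p = p), label = labs[1L])
}
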