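# Long-format spectra CSV: one row per fruit x frequency.
SPECTRA_HEADER <- c("fruit_id", "size_mm", "a_star", "label", "freq_hz",
                    "z_real_ohm", "z_imag_ohm")

#' Write a fruit dataset as long-format spectra CSV
#'
#' Header `fruit_id,size_mm,a_star,label,freq_hz,z_real_ohm,z_imag_ohm`;
#' rows grouped by fruit with frequencies ascending; UTF-8, '.' decimal.
#'
#' @param ds A `fruit_dataset`.
#' @param path Output file path.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "fruit_dataset"))
  n <- length(ds$fruit_id); m <- length(ds$grid)
  df <- data.frame(
    fruit_id = rep(ds$fruit_id, each = m),
    size_mm = rep(ds$size, each = m),
    a_star = rep(ds$a_star, each = m),
    label = rep(ds$label, each = m),
    freq_hz = rep(ds$grid, times = n),
    z_real_ohm = as.vector(t(Re(ds$z))),
    z_imag_ohm = as.vector(t(Im(ds$z))))
  utils::write.csv(format(df, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format spectra CSV back into a fruit dataset
#'
#' Validates the exact header, numeric cells, and that each fruit's rows
#' carry strictly increasing frequencies on a common grid. Round-trips
#' [write_spectra_csv()] output exactly (within numeric printing precision).
#'
#' @param path CSV path.
#' @return A `fruit_dataset`.
#' @export
read_spectra_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, SPECTRA_HEADER))
    stop("parse error: expected header '",
         paste(SPECTRA_HEADER, collapse = ","), "'", call. = FALSE)
  df <- utils::read.csv(path, colClasses = c(fruit_id = "character"),
                        fileEncoding = "UTF-8")
  num_cols <- setdiff(SPECTRA_HEADER, "fruit_id")
  for (cl in num_cols)
    if (nrow(df) > 0 && !is.numeric(df[[cl]]))
      stop("parse error: non-numeric cells in column '", cl, "'",
           call. = FALSE)
  ids <- unique(df$fruit_id)
  if (length(ids) == 0) {
    ds <- list(fruit_id = character(0), size = numeric(0),
               a_star = numeric(0), label = integer(0), grid = numeric(0),
               z = matrix(complex(0), 0, 0))
    class(ds) <- "fruit_dataset"
    return(ds)
  }
  grid <- df$freq_hz[df$fruit_id == ids[1]]
  if (any(diff(grid) <= 0))
    stop("parse error: non-monotone frequencies for fruit '", ids[1], "'",
         call. = FALSE)
  z <- matrix(complex(real = NA_real_), length(ids), length(grid))
  size <- a_star <- numeric(length(ids)); label <- integer(length(ids))
  for (i in seq_along(ids)) {
    rows <- df[df$fruit_id == ids[i], , drop = FALSE]
    if (any(diff(rows$freq_hz) <= 0) ||
        !isTRUE(all.equal(rows$freq_hz, grid)))
      stop("parse error: non-monotone or mismatched frequencies for fruit '",
           ids[i], "'", call. = FALSE)
    z[i, ] <- complex(real = rows$z_real_ohm, imaginary = rows$z_imag_ohm)
    size[i] <- rows$size_mm[1]; a_star[i] <- rows$a_star[1]
    label[i] <- rows$label[1]
  }
  ds <- list(fruit_id = ids, size = size, a_star = a_star, label = label,
             grid = grid, z = z)
  class(ds) <- "fruit_dataset"
  ds
}

#' Write / read a feature table CSV
#'
#' Fixed column order `fruit_id,label,magn_f1..f5,phase_f1..f5,
#' tand_f1..f5,py,min_phase,size_mm,a_star`.
#'
#' @param table Feature table from [assemble_features()].
#' @param path CSV path.
#' @export
write_features_csv <- function(table, path) {
  cols <- c("fruit_id", "label", feature_names(), "a_star")
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(fruit_id = "character"),
                        fileEncoding = "UTF-8")
  need <- c("fruit_id", "label", feature_names())
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("parse error: feature CSV lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Write selected frequencies as CSV (`parameter,rank,freq_hz`)
#'
#' @param sel Selection list from [screen_frequencies()].
#' @param path CSV path.
#' @export
write_selection_csv <- function(sel, path) {
  rows <- do.call(rbind, lapply(c("magnitude", "phase", "tan_delta"),
                                function(p)
    data.frame(parameter = p, rank = seq_along(sel[[p]]),
               freq_hz = sel[[p]])))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_selection_csv
#' @export
read_selection_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  out <- lapply(split(df, df$parameter), function(d)
    d$freq_hz[order(d$rank)])
  out[c("magnitude", "phase", "tan_delta")]
}
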