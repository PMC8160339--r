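#' Signed percent difference between training and test scores
#'
#' `100 * (test - train) / train`, rounded half-away-from-zero to one
#' decimal -- the convention of the final report table.
#'
#' @param train_score Training F score (must be > 0).
#' @param test_score Test F score.
#' @return Signed percentage, one decimal.
#' @examples
#' percent_diff(0.772, 0.699)
#' @export
percent_diff <- function(train_score, test_score) {
  if (any(train_score <= 0))
    stop("undefined difference: train score is 0", call. = FALSE)
  x <- 100 * (test_score - train_score) / train_score
  round_half_away(x, 1)
}

# round half away from zero to `digits` decimals; the inner round() guards
# against binary representation error just below the .5 boundary
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(round(abs(x) * m, 8) + 0.5) / m
}

#' Table-style final report of train/test F scores
#'
#' Assembles the per-algorithm, per-beta result table: number of features,
#' training F, test F and the percent difference, ordered LR, DT, NBC, KNN,
#' SVM, MLP-1, MLP-2. F values are rounded to 3 decimals, percent
#' differences to 1.
#'
#' @param results Named list keyed by algorithm (`LR`, `DT`, `NBC`, `KNN`,
#'   `SVM`, `MLP-1`, `MLP-2`); each element a named list keyed by beta label
#'   (`f1`, `f05`, `f2`) of lists with `n_features`, `train`, `test`.
#' @param algorithms Required algorithm order.
#' @param betas Beta block labels to render.
#' @return `data.frame` of class `ripeness_report` with columns `algorithm`
#'   and, per beta block, `<b>_n_features`, `<b>_train`, `<b>_test`,
#'   `<b>_pct_diff`.
#' @export
make_report <- function(results,
                        algorithms = c("LR", "DT", "NBC", "KNN", "SVM",
                                       "MLP-1", "MLP-2"),
                        betas = c("f1", "f05", "f2")) {
  missing <- setdiff(algorithms, names(results))
  if (length(missing))
    stop("incomplete results: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- lapply(algorithms, function(alg) {
    row <- list(algorithm = alg)
    for (b in betas) {
      cell <- results[[alg]][[b]]
      if (is.null(cell))
        stop("incomplete results: ", alg, " lacks block '", b, "'",
             call. = FALSE)
      row[[paste0(b, "_n_features")]] <- cell$n_features
      row[[paste0(b, "_train")]] <- round_half_away(cell$train, 3)
      row[[paste0(b, "_test")]] <- round_half_away(cell$test, 3)
      row[[paste0(b, "_pct_diff")]] <- percent_diff(cell$train, cell$test)
    }
    as.data.frame(row, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ripeness_report", "data.frame")
  out
}

#' Render a report as aligned text
#'
#' @param x A `ripeness_report`.
#' @param ... Unused.
#' @method print ripeness_report
#' @export
print.ripeness_report <- function(x, ...) {
  df <- as.data.frame(x)
  blocks <- unique(sub("_(n_features|train|test|pct_diff)$", "",
                       names(df)[-1]))
  hdr <- c("Algorithm",
           unlist(lapply(blocks, function(b)
             paste(toupper(b), c("Nr.", "Train", "Test", "%Diff")))))
  m <- cbind(df$algorithm,
             do.call(cbind, lapply(names(df)[-1], function(cl)
               formatC(df[[cl]], format = "fg"))))
  widths <- pmax(nchar(hdr), apply(nchar(m), 2, max))
  line <- function(v) paste(mapply(formatC, v, width = widths), collapse = "  ")
  cat(line(hdr), "\n")
  for (i in seq_len(nrow(m))) cat(line(m[i, ]), "\n")
  invisible(x)
}

#' Write a report as TSV
#'
#' @param report A `ripeness_report`.
#' @param path Output path.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
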