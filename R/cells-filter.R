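#' Filter debris from a cell table by metric thresholds
#'
#' Removes segmented objects that fail any of the configured bounds on
#' footprint area, track length, and mean phase, darkfield and QDF signal --
#' the classic debris signature being small, short-lived, low-phase objects.
#' A per-criterion report of removed rows is attached as the `filter_report`
#' attribute.
#'
#' @param table Data frame with (at least) the columns named by the
#'   thresholds used: `area_um2`, `track_length`, `mean_phase`, `mean_df`,
#'   `mean_qdf`.
#' @param thresholds Named list; each element is `c(min, max)` (use `NA` or
#'   `Inf` for an open bound). Names must be a subset of
#'   `area`, `track_length`, `mean_phase`, `mean_df`, `mean_qdf`.
#' @return The surviving rows of `table`, with attribute `filter_report`:
#'   a data frame of per-criterion removal counts.
#' @export
filter_debris <- function(table, thresholds) {
  stopifnot(is.data.frame(table), is.list(thresholds))
  cols <- c(area = "area_um2", track_length = "track_length",
            mean_phase = "mean_phase", mean_df = "mean_df",
            mean_qdf = "mean_qdf")
  unknown <- setdiff(names(thresholds), names(cols))
  if (length(unknown))
    stop("unknown debris metric(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(names(cols), collapse = ", "))
  keep <- rep(TRUE, nrow(table))
  report <- data.frame(metric = character(0), min = numeric(0),
                       max = numeric(0), removed = integer(0))
  for (m in names(thresholds)) {
    col <- cols[[m]]
    if (!col %in% names(table))
      stop("cell table lacks column '", col, "' needed by threshold '", m, "'")
    b <- thresholds[[m]]
    lo <- if (is.na(b[1])) -Inf else b[1]
    hi <- if (length(b) < 2 || is.na(b[2])) Inf else b[2]
    ok <- table[[col]] >= lo & table[[col]] <= hi
    ok[is.na(ok)] <- FALSE
    report <- rbind(report, data.frame(metric = m, min = lo, max = hi,
                                       removed = sum(keep & !ok)))
    keep <- keep & ok
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}
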