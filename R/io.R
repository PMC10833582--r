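#' Write a price table to CSV
#'
#' Exports a fitted pricing model (or an already-flattened price table) with
#' the deterministic column order `drug, mode, index, rd_component,
#' manuf_component, multiplier, per_treatment, per_vial`. Money columns are
#' rounded to 2 decimals by default; with `full_precision = TRUE` they are
#' written with all significant digits so that re-reading reproduces the
#' values exactly.
#'
#' @param x A `"cbp"` fit or a data.frame in the export layout.
#' @param path Output CSV path.
#' @param full_precision Write full double precision instead of 2 decimals.
#' @return `path`, invisibly.
#' @export
write_price_table <- function(x, path, full_precision = FALSE) {
  df <- if (inherits(x, "cbp")) as.data.frame(x) else as.data.frame(x)
  cols <- c("drug", "mode", "index", "rd_component", "manuf_component",
            "multiplier", "per_treatment", "per_vial")
  if (!all(cols %in% names(df))) {
    stop("price table must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("refusing to write an empty price table",
                           call. = FALSE)
  df <- df[, cols]
  money <- c("rd_component", "manuf_component", "per_treatment", "per_vial")
  if (!full_precision) {
    df[money] <- lapply(df[money], round, digits = 2)
  } else {
    df[money] <- lapply(df[money], function(v) format(v, digits = 17,
                                                      trim = TRUE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a price table written by [write_price_table()]
#'
#' @param path CSV path.
#' @return data.frame with numeric money columns.
#' @export
read_price_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  money <- c("rd_component", "manuf_component", "per_treatment", "per_vial")
  df[money] <- lapply(df[money], as.numeric)
  df
}
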