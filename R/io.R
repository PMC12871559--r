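#' Read an initial-rate dataset from CSV
#'
#' Reads comma-separated rate tables with a mandatory header and dot
#' decimals. Column names are matched case-insensitively against common
#' synonyms -- e.g. `S`, `[S]`, `substrate`, `substrate_mM` for the
#' substrate column -- and mapped onto the canonical layout `S_mM`, `I_mM`,
#' `replicate`, `v0`; the applied mapping is reported via `message()` when
#' any non-canonical name is encountered. A missing replicate column is
#' filled with a running index within each (S, I) cell.
#'
#' @param path CSV file path.
#' @return A data frame of class `"rate_data"`.
#' @seealso [write_rates()]
#' @export
read_rates <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  syn <- list(
    S_mM = c("s_mm", "s", "[s]", "substrate", "substrate_mm", "s_conc",
             "substrate_conc"),
    I_mM = c("i_mm", "i", "[i]", "inhibitor", "inhibitor_mm", "i_conc",
             "inhibitor_conc"),
    replicate = c("replicate", "rep", "r", "repl"),
    v0 = c("v0", "v", "rate", "velocity", "initial_rate", "v0_rate")
  )
  lower <- tolower(trimws(names(raw)))
  out <- list()
  mapped <- character()
  for (canon in names(syn)) {
    hit <- which(lower %in% c(tolower(canon), syn[[canon]]))
    if (length(hit) > 1) {
      stop("ambiguous columns for ", canon, " in ", path, ": ",
           paste(names(raw)[hit], collapse = ", "), call. = FALSE)
    }
    if (length(hit) == 1) {
      out[[canon]] <- raw[[hit]]
      if (names(raw)[hit] != canon) {
        mapped <- c(mapped, sprintf("%s -> %s", names(raw)[hit], canon))
      }
    }
  }
  need <- c("S_mM", "I_mM", "v0")
  if (!all(need %in% names(out))) {
    stop("could not identify required columns (",
         paste(setdiff(need, names(out)), collapse = ", "),
         ") in ", path, call. = FALSE)
  }
  if (length(mapped)) {
    message("column mapping: ", paste(mapped, collapse = "; "))
  }
  d <- as.data.frame(out)
  if (is.null(d$replicate)) {
    d$replicate <- stats::ave(seq_len(nrow(d)),
                              d$S_mM, d$I_mM, FUN = seq_along)
  }
  bad <- which(!is.finite(d$v0) | d$v0 <= 0 | !is.finite(d$S_mM) |
                 d$S_mM <= 0 | !is.finite(d$I_mM) | d$I_mM < 0)
  if (length(bad)) {
    stop("invalid rate records at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  d <- d[, c("S_mM", "I_mM", "replicate", "v0")]
  structure(d, class = c("rate_data", "data.frame"))
}

#' Write an initial-rate dataset to CSV
#'
#' Writes the canonical dialect (comma-separated, dot decimal, header
#' `S_mM,I_mM,replicate,v0`). Values round-trip through [read_rates()]
#' losslessly to at least 12 significant digits.
#'
#' @param data A rate data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(data, path) {
  data <- as.data.frame(data)
  need <- c("S_mM", "I_mM", "replicate", "v0")
  if (!all(need %in% names(data))) {
    stop("data must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- data[, need]
  for (col in c("S_mM", "I_mM", "v0")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
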