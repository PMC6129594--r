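#' Parcellation schemes
#'
#' A parcellation scheme maps each row/column of a whole-brain connectivity
#' matrix to a named brain region and a hemisphere. Node indices are 0-based
#' and contiguous; the scheme must contain equal numbers of left (`L`) and
#' right (`R`) regions. Homotopic left/right pairs are identified by position:
#' the k-th `L` region and the k-th `R` region (in scheme order) are treated
#' as anatomical counterparts.
#'
#' @param index integer vector of 0-based matrix positions
#' @param name character vector of full region names
#' @param abbrev character vector of unique region abbreviations
#' @param hemisphere character vector of `"L"`/`"R"` labels
#' @return a `parcellation` data.frame with columns
#'   `index`, `name`, `abbrev`, `hemisphere`
#' @export
parcellation <- function(index, name, abbrev, hemisphere) {
  df <- data.frame(index = as.integer(index), name = as.character(name),
                   abbrev = as.character(abbrev),
                   hemisphere = as.character(hemisphere),
                   stringsAsFactors = FALSE)
  validate_parcellation(df)
}

validate_parcellation <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("index", "name", "abbrev", "hemisphere") %in% names(df)))
  df <- df[order(df$index), , drop = FALSE]
  if (!identical(df$index, seq_len(nrow(df)) - 1L))
    stop("parcellation node indices must be contiguous from 0")
  if (!all(df$hemisphere %in% c("L", "R")))
    stop("hemisphere labels must be 'L' or 'R'")
  nl <- sum(df$hemisphere == "L"); nr <- sum(df$hemisphere == "R")
  if (nl != nr)
    stop(sprintf("unequal hemisphere sizes: %d L vs %d R", nl, nr))
  if (anyDuplicated(paste(df$abbrev, df$hemisphere)))
    stop("region abbreviations must be unique within each hemisphere")
  rownames(df) <- NULL
  class(df) <- c("parcellation", "data.frame")
  df
}

#' Read a parcellation file
#'
#' Expects a tab-separated file with header columns
#' `index`, `name`, `abbrev`, `hemisphere`.
#'
#' @param path path to the TSV file
#' @return a `parcellation` object
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop("parcellation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_parcellation(df)
}

#' The packaged AAL-90 parcellation
#'
#' The automated anatomical labeling atlas: 90 regions, 45 per hemisphere,
#' in the conventional alternating left/right order.
#'
#' @return a `parcellation` object with 90 rows
#' @export
aal90_parcellation <- function() {
  read_parcellation(system.file("extdata", "aal90.tsv", package = "hemiasym",
                                mustWork = TRUE))
}

#' Build a generic alternating parcellation of arbitrary size
#'
#' Used for reduced-size synthetic cohorts; region abbreviations are
#' `R01 ... Rnn`. Falls back to AAL-90 naming when
#' `n_per_hemisphere == 45`.
#'
#' @param n_per_hemisphere regions per hemisphere
#' @return a `parcellation` object with `2 * n_per_hemisphere` rows
#' @export
default_parcellation <- function(n_per_hemisphere = 45) {
  if (n_per_hemisphere == 45) return(aal90_parcellation())
  ab <- sprintf("R%02d", seq_len(n_per_hemisphere))
  parcellation(index = seq_len(2 * n_per_hemisphere) - 1L,
               name = rep(paste("Region", seq_len(n_per_hemisphere)), each = 2),
               abbrev = rep(ab, each = 2),
               hemisphere = rep(c("L", "R"), n_per_hemisphere))
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation: %d regions (%d per hemisphere)>\n",
              nrow(x), nrow(x) / 2))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
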