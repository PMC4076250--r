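#' N50 of a set of sequence lengths
#'
#' The N50 is the largest length L such that sequences of length >= L
#' together contain at least half of the total bases.
#'
#' @param lengths integer vector of sequence lengths.
#' @return a single integer; 0 for an empty input.
#' @examples
#' n50(c(8, 7, 5, 4))  # 7
#' @export
n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  lengths <- lengths[!is.na(lengths) & lengths > 0]
  if (length(lengths) == 0L) return(0)
  lengths <- sort(lengths, decreasing = TRUE)
  as.integer(lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1L]])
}

#' Lower median of a numeric vector
#'
#' For odd n the ordinary median; for even n the lower of the two central
#' order statistics. Used for gap estimates so that the result is always an
#' observed value, robust to a single outlying read.
#'
#' @param x numeric vector, length >= 1.
#' @return a single number.
#' @export
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param s character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# stage logging: message()-based so callers can suppressMessages()
ls_log <- function(fmt, ...) {
  message(sprintf(paste0("[longscaff] ", fmt), ...))
}

# classed error helpers; the CLI maps classes to exit codes
ls_error <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "longscaff_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

ls_input_error <- function(fmt, ...) ls_error("longscaff_input_error", fmt, ...)
ls_parse_error <- function(fmt, ...) ls_error("longscaff_parse_error", fmt, ...)
ls_aligner_error <- function(fmt, ...) ls_error("longscaff_aligner_error", fmt, ...)
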