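# shared internal helpers

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published metric tables in this
#' field conventionally round half up (0.8445 -> 0.845 at 3 decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.8445, 0.0005), 3)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

abort_integrity <- function(msg, ...) {
  rlang::abort(msg, class = "taxatext_integrity_error", ...)
}

abort_usage <- function(msg, ...) {
  rlang::abort(msg, class = "taxatext_usage_error", ...)
}

abort_parse <- function(msg, ...) {
  rlang::abort(msg, class = "taxatext_parse_error", ...)
}

`%||%` <- rlang::`%||%`

# Normalize free text for stable matching: NFC, collapse whitespace, trim.
squish_nfc <- function(x) {
  stringr::str_squish(stringi::stri_trans_nfc(x))
}

#' Path to a packaged example / fixture file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
#' @examples
#' taxatext_example()
#' taxatext_example("dictionary.tsv")
taxatext_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "taxatext")))
  }
  path <- system.file("extdata", file, package = "taxatext")
  if (!nzchar(path)) {
    abort_usage(paste0("no packaged file '", file, "'"))
  }
  path
}
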