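# Annotation dictionary: ordered lowercase stem keys -> concept URIs.

#' Coerce a data frame to an annotation dictionary
#'
#' A dictionary is an ordered two-column tibble mapping lowercase stem keys
#' (deliberately truncated strings such as `"predat"`, matched as substrings
#' so one entry covers all inflections) to absolute concept URIs. Invariants:
#' keys non-empty, unique, no uppercase characters; URIs carry a scheme.
#'
#' @param x data frame with columns `key` and `uri`.
#' @param provenance optional source path recorded as an attribute.
#' @return a tibble of class `taxatext_dictionary`.
#' @export
as_dictionary <- function(x, provenance = NULL) {
  x <- tibble::as_tibble(x)
  if (!all(c("key", "uri") %in% names(x))) {
    abort_parse("dictionary needs columns 'key' and 'uri'")
  }
  x <- x[c("key", "uri")]
  x$key <- as.character(x$key)
  x$uri <- as.character(x$uri)
  if (any(!nzchar(x$key) | is.na(x$key))) {
    abort_integrity("dictionary contains an empty key")
  }
  upper <- grepl("[[:upper:]]", x$key)
  if (any(upper)) {
    abort_integrity(paste0("dictionary key contains uppercase (keys must be ",
                           "pre-lowercased): '", x$key[upper][1], "'"))
  }
  dup <- duplicated(x$key)
  if (any(dup)) {
    abort_integrity(paste0("duplicate dictionary key: '", x$key[dup][1], "'"))
  }
  bad_uri <- !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x$uri)
  if (any(bad_uri)) {
    abort_integrity(paste0("malformed URI (no scheme): '",
                           x$uri[bad_uri][1], "'"))
  }
  structure(x, class = c("taxatext_dictionary", class(tibble::tibble())),
            provenance = provenance)
}

#' Read an annotation dictionary from TSV
#'
#' Two tab-separated columns (key, uri), one entry per line, `#`-prefixed
#' comment lines and blank lines ignored, UTF-8. File order is preserved —
#' the annotator scans keys in dictionary order.
#'
#' @param path path to the TSV file.
#' @return a [as_dictionary()] object.
#' @export
#' @examples
#' read_dictionary(taxatext_example("dictionary.tsv"))
read_dictionary <- function(path) {
  if (!file.exists(path)) abort_usage(paste("no such dictionary:", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    rlang::warn(paste("empty dictionary:", path))
    return(as_dictionary(tibble::tibble(key = character(), uri = character()),
                         provenance = path))
  }
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  if (any(!nzchar(parts[, 2]))) {
    abort_parse(paste0("dictionary line without a tab-separated URI: '",
                       lines[!nzchar(parts[, 2])][1], "'"))
  }
  as_dictionary(tibble::tibble(key = stringr::str_trim(parts[, 1]),
                               uri = stringr::str_trim(parts[, 2])),
                provenance = path)
}

#' Read a dictionary written as quoted literal pairs
#'
#' Tolerant importer for lines of the form `'key': 'uri',` (the style in
#' which such dictionaries are often printed inside source code), as an
#' alternative to the canonical TSV format.
#'
#' @param path path to the file.
#' @return a [as_dictionary()] object.
#' @export
read_dictionary_literal <- function(path) {
  if (!file.exists(path)) abort_usage(paste("no such dictionary:", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  m <- stringr::str_match(
    lines, "^\\s*['\"]([^'\"]+)['\"]\\s*:\\s*['\"]([^'\"]+)['\"],?\\s*$"
  )
  keep <- !is.na(m[, 1])
  if (!any(keep)) {
    rlang::warn(paste("no literal-style entries found in", path))
  }
  as_dictionary(tibble::tibble(key = m[keep, 2], uri = m[keep, 3]),
                provenance = path)
}

#' Write a dictionary to TSV
#'
#' @param d a dictionary.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(d, path) {
  d <- as_dictionary(d)
  writeLines(paste(d$key, d$uri, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Audit a dictionary for risky entries
#'
#' The annotator's performance depends almost entirely on dictionary
#' construction, so this flags: keys that are substrings of other keys (both
#' will fire on the longer term's text), very short keys (< 4 characters,
#' high collision risk), and several keys sharing one URI (informational —
#' hits stay distinct but unique-URI tallies merge).
#'
#' @param d a dictionary.
#' @return tibble of issues with columns `issue`, `key`, `detail`; zero rows
#'   when the dictionary is clean.
#' @export
validate_dictionary <- function(d) {
  d <- as_dictionary(d)
  issues <- list()
  if (nrow(d) > 1) {
    pairs <- tidyr::crossing(a = d$key, b = d$key)
    pairs <- pairs[pairs$a != pairs$b &
                     stringr::str_detect(pairs$b, stringr::fixed(pairs$a)), ]
    if (nrow(pairs)) {
      issues$substring <- tibble::tibble(
        issue = "substring_key",
        key = pairs$a,
        detail = paste0("'", pairs$a, "' is a substring of '", pairs$b,
                        "'; both fire on text containing '", pairs$b, "'")
      )
    }
  }
  short <- d$key[nchar(d$key) < 4]
  if (length(short)) {
    issues$short <- tibble::tibble(
      issue = "short_key", key = short,
      detail = "key shorter than 4 characters: high collision risk"
    )
  }
  shared <- dplyr::filter(dplyr::count(d, .data$uri), .data$n > 1)
  if (nrow(shared)) {
    issues$shared <- tibble::tibble(
      issue = "shared_uri", key = NA_character_,
      detail = paste0(shared$n, " keys map to ", shared$uri)
    )
  }
  if (length(issues) == 0) {
    return(tibble::tibble(issue = character(), key = character(),
                          detail = character()))
  }
  dplyr::bind_rows(issues)
}

#' The packaged default ecology dictionary
#'
#' A small stem-keyed dictionary of ecologically relevant concepts with
#' DBpedia-style URIs, used as the default by the synthetic-corpus generator
#' and the worked examples.
#'
#' @return a dictionary tibble.
#' @export
default_dictionary <- function() {
  read_dictionary(taxatext_example("dictionary.tsv"))
}
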