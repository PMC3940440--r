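# URI annotation by lowercase substring search of dictionary stems.

#' Annotate one text with dictionary URIs
#'
#' The body is lowercased once, then every dictionary key is searched for as
#' a contiguous substring, in dictionary order. A key that occurs yields
#' exactly one hit at its first occurrence; after a find the scan moves on
#' to the next key (per-key occurrence counting is deliberately out of
#' scope). Matching crosses word boundaries by design — that is what makes
#' stem keys like `"predat"` cover "predator", "predation", "predatory" —
#' so word-part collisions (e.g. `"forest"` inside "kelp forest") are
#' accepted behavior, to be measured by the evaluation functions rather
#' than prevented here.
#'
#' @param text a single plain-text string (already markup-free).
#' @param d a dictionary ([as_dictionary()]).
#' @return tibble with one row per matching key, in dictionary order:
#'   `key`, `uri`, `offset` (0-based character index into the lowercased
#'   body). Zero rows when nothing matches — a valid outcome.
#' @export
#' @examples
#' d <- as_dictionary(data.frame(
#'   key = "predat", uri = "http://dbpedia.org/resource/Predation"))
#' annotate_text("The Great White is an apex Predator.", d)
annotate_text <- function(text, d) {
  d <- as_dictionary(d)
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text) || nrow(d) == 0) {
    return(tibble::tibble(key = character(), uri = character(),
                          offset = integer()))
  }
  body <- stringr::str_to_lower(text)
  starts <- stringr::str_locate(body, stringr::fixed(d$key))[, "start"]
  hit <- !is.na(starts)
  tibble::tibble(key = d$key[hit], uri = d$uri[hit],
                 offset = as.integer(starts[hit] - 1L))
}

#' Annotate a table of text objects
#'
#' Applies [annotate_text()] to each row of a text-object tibble.
#'
#' @param objects tibble with columns `object_id` and `body` (e.g. the
#'   `objects` table of a corpus, or the result of [filter_objects()]).
#' @param d a dictionary.
#' @return tibble `object_id`, `key`, `uri`, `offset`, sorted by
#'   `object_id` with hits in dictionary order within each object.
#' @export
annotate_objects <- function(objects, d) {
  objects <- tibble::as_tibble(objects)
  d <- as_dictionary(d)
  if (nrow(objects) == 0) {
    return(tibble::tibble(object_id = character(), key = character(),
                          uri = character(), offset = integer()))
  }
  res <- purrr::map2(objects$object_id, objects$body, function(id, body) {
    hits <- annotate_text(body, d)
    if (nrow(hits)) hits$object_id <- id
    hits
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(object_id = character(), key = character(),
                          uri = character(), offset = integer()))
  }
  ord <- order(out$object_id)
  out[ord, c("object_id", "key", "uri", "offset")]
}

#' Annotate a whole corpus at object or taxon scope
#'
#' At `"object"` scope each text object gets its own result. At `"taxon"`
#' scope annotations are pooled per taxon page: the unique URIs are the
#' union over that taxon's objects, and each key keeps the provenance of
#' its earliest hit (first object in id order, lowest offset). Taxon scope
#' trades specificity for dictionary economy — a general stem suffices to
#' tag the taxon even if no single object would warrant it.
#'
#' @param x a [corpus()] object.
#' @param d a dictionary.
#' @param scope `"object"` or `"taxon"`.
#' @return at object scope, the [annotate_objects()] tibble; at taxon scope
#'   a tibble `taxon_id`, `key`, `uri`, `object_id`, `offset`.
#' @export
annotate_corpus <- function(x, d, scope = c("object", "taxon")) {
  stopifnot(inherits(x, "taxatext_corpus"))
  if (!is.character(scope) || !all(scope %in% c("object", "taxon"))) {
    abort_usage("scope must be \"object\" or \"taxon\"")
  }
  scope <- match.arg(scope)
  hits <- annotate_objects(x$objects, d)
  if (scope == "object") return(hits)
  hits <- dplyr::left_join(
    hits, x$objects[c("object_id", "taxon_id")], by = "object_id"
  )
  hits |>
    dplyr::arrange(.data$taxon_id, .data$object_id, .data$offset) |>
    dplyr::distinct(.data$taxon_id, .data$key, .keep_all = TRUE) |>
    dplyr::select("taxon_id", "key", "uri", "object_id", "offset")
}

#' Summarize annotation results per unit
#'
#' Reports, per object (or per taxon), the raw hit count and the unique-URI
#' count — both tallies matter because several stem keys may map to one
#' concept URI. The attached averages report both the mean hits per unit and
#' the mean unique URIs per unit.
#'
#' @param hits an annotation tibble from [annotate_objects()] or
#'   [annotate_corpus()].
#' @param units optional character vector of all unit ids, so units with
#'   zero hits appear as zero rows (the no-annotation share is itself a
#'   reported statistic).
#' @return tibble `unit`, `n_hits`, `n_unique_uris`, with attribute
#'   `averages` (named numeric: `mean_hits`, `mean_unique_uris`,
#'   `share_without_hits`).
#' @export
annotation_summary <- function(hits, units = NULL) {
  id_col <- if ("taxon_id" %in% names(hits) &&
                !"object_id" %in% names(hits)) "taxon_id" else
    if ("object_id" %in% names(hits)) "object_id" else "taxon_id"
  tab <- hits |>
    dplyr::group_by(unit = .data[[id_col]]) |>
    dplyr::summarise(n_hits = dplyr::n(),
                     n_unique_uris = dplyr::n_distinct(.data$uri),
                     .groups = "drop")
  if (!is.null(units)) {
    tab <- dplyr::left_join(tibble::tibble(unit = as.character(units)),
                            tab, by = "unit")
    tab$n_hits[is.na(tab$n_hits)] <- 0L
    tab$n_unique_uris[is.na(tab$n_unique_uris)] <- 0L
  }
  attr(tab, "averages") <- c(
    mean_hits = if (nrow(tab)) mean(tab$n_hits) else 0,
    mean_unique_uris = if (nrow(tab)) mean(tab$n_unique_uris) else 0,
    share_without_hits = if (nrow(tab)) mean(tab$n_hits == 0) else 0
  )
  tab
}

#' Write / read annotation hits as TSV
#'
#' Columns `object_id`, `key`, `uri`, `offset`; rows sorted by `object_id`
#' for byte-stable output.
#'
#' @param hits annotation tibble.
#' @param path file path.
#' @return `path` (write) or the tibble (read).
#' @export
write_annotations <- function(hits, path) {
  readr::write_tsv(hits, path, na = "")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    offset = readr::col_integer(), .default = readr::col_character()
  ))
}
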