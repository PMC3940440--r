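# Corpus data model and I/O: taxon pages and their narrative text objects.

#' Ecology subchapter labels
#'
#' The four topical subchapter labels under which taxon pages carry text that
#' specifically describes ecological interactions. Association extraction
#' restricts itself to these by default.
#'
#' @return character vector of four labels.
#' @export
ecology_subchapters <- function() {
  c("Associations", "TrophicStrategy", "GeneralEcology", "Habitat")
}

# Subchapter labels appear both spaced ("Trophic Strategy") and unspaced
# ("TrophicStrategy") in the wild; compare after dropping spaces and case.
normalize_subchapter <- function(x) {
  tolower(gsub("[[:space:]]+", "", x))
}

#' Strip markup from narrative text
#'
#' Removes HTML tags, decodes character entities, collapses whitespace runs
#' to single spaces and trims. Tolerant of malformed markup (best-effort
#' strip via an HTML parser); plain text passes through unchanged apart from
#' whitespace normalization. Idempotent.
#'
#' @param x character vector, possibly containing markup.
#' @return character vector of plain text, NFC-normalized.
#' @export
#' @examples
#' clean_markup("<p>Eats <i>fish</i></p>")
#' clean_markup("crabs &amp; shrimp")
clean_markup <- function(x) {
  out <- vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    if (!nzchar(s)) return("")
    if (grepl("[<&]", s)) {
      # pad tags so adjacent block elements do not fuse words
      padded <- gsub("<", " <", s, fixed = TRUE)
      s <- tryCatch(
        xml2::xml_text(xml2::read_html(paste0(
          "<html><body>", padded, "</body></html>"
        ))),
        error = function(e) gsub("<[^>]*>", " ", s)
      )
    }
    s
  }, character(1), USE.NAMES = FALSE)
  squish_nfc(out)
}

#' Construct a corpus of taxon pages and text objects
#'
#' A corpus couples a table of taxa with a table of text objects attached to
#' them. Bodies are passed through [clean_markup()] and all invariants are
#' checked: unique `taxon_id` and `object_id`, every object's `taxon_id`
#' present in `taxa`, non-empty canonical names and bodies.
#'
#' @param taxa data frame with columns `taxon_id`, `canonical_name` and
#'   optionally `rank`, `parent_id`, `synonyms`, `common_names` (the last two
#'   either list-columns of character vectors or `|`-separated strings).
#' @param objects data frame with columns `object_id`, `taxon_id`,
#'   `subchapter`, `body` and optionally `language` (default `"en"`),
#'   `trusted` (default `TRUE`), `source`.
#' @param clean should bodies be passed through [clean_markup()]? Set
#'   `FALSE` only for already-clean round-trip loads.
#' @return an object of class `taxatext_corpus`: a list with tibbles `taxa`
#'   and `objects`.
#' @export
corpus <- function(taxa, objects, clean = TRUE) {
  taxa <- tibble::as_tibble(taxa)
  objects <- tibble::as_tibble(objects)

  need_t <- setdiff(c("taxon_id", "canonical_name"), names(taxa))
  if (length(need_t)) {
    abort_parse(paste("taxa table missing column(s):",
                      paste(need_t, collapse = ", ")))
  }
  need_o <- setdiff(c("object_id", "taxon_id", "subchapter", "body"),
                    names(objects))
  if (length(need_o) && nrow(objects) > 0) {
    abort_parse(paste("objects table missing column(s):",
                      paste(need_o, collapse = ", ")))
  }

  taxa$taxon_id <- as.character(taxa$taxon_id)
  taxa$canonical_name <- squish_nfc(as.character(taxa$canonical_name))
  if (!"rank" %in% names(taxa)) taxa$rank <- NA_character_
  if (!"parent_id" %in% names(taxa)) taxa$parent_id <- NA_character_
  taxa$parent_id <- as.character(taxa$parent_id)
  taxa$synonyms <- as_name_list(
    if ("synonyms" %in% names(taxa)) taxa$synonyms else list(), nrow(taxa))
  taxa$common_names <- as_name_list(
    if ("common_names" %in% names(taxa)) taxa$common_names else list(),
    nrow(taxa))

  if (anyDuplicated(taxa$taxon_id)) {
    abort_integrity(paste("duplicate taxon_id:",
                          taxa$taxon_id[duplicated(taxa$taxon_id)][1]))
  }
  if (any(!nzchar(taxa$canonical_name))) {
    abort_integrity(paste("empty canonical_name for taxon_id:",
                          taxa$taxon_id[!nzchar(taxa$canonical_name)][1]))
  }

  if (nrow(objects) == 0) {
    objects <- tibble::tibble(
      object_id = character(), taxon_id = character(),
      subchapter = character(), body = character(),
      language = character(), trusted = logical(), source = character()
    )
  } else {
    objects$object_id <- as.character(objects$object_id)
    objects$taxon_id <- as.character(objects$taxon_id)
    objects$subchapter <- as.character(objects$subchapter)
    objects$language <- as.character(
      if ("language" %in% names(objects)) objects$language else "en")
    objects$trusted <- as.logical(
      if ("trusted" %in% names(objects)) objects$trusted else TRUE)
    objects$source <- as.character(
      if ("source" %in% names(objects)) objects$source else NA_character_)
    objects$body <- if (clean) clean_markup(objects$body) else
      squish_nfc(objects$body)

    dup <- duplicated(objects$object_id)
    if (any(dup)) {
      abort_integrity(paste("duplicate object_id:", objects$object_id[dup][1]))
    }
    unknown <- setdiff(objects$taxon_id, taxa$taxon_id)
    if (length(unknown)) {
      abort_integrity(paste("object references unknown taxon_id:",
                            unknown[1]))
    }
    empty <- !nzchar(objects$body)
    if (any(empty)) {
      abort_integrity(paste("empty body after cleaning for object_id:",
                            objects$object_id[empty][1]))
    }
  }

  objects <- dplyr::arrange(objects, .data$taxon_id, .data$object_id)
  structure(list(taxa = taxa, objects = objects), class = "taxatext_corpus")
}

# coerce a synonyms/common_names column into a list of character vectors
as_name_list <- function(x, n) {
  if (length(x) == 0 && n > 0) return(rep(list(character()), n))
  if (is.list(x)) {
    return(lapply(x, function(v) {
      v <- as.character(v %||% character())
      squish_nfc(v[nzchar(v) & !is.na(v)])
    }))
  }
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    squish_nfc(strsplit(s, "|", fixed = TRUE)[[1]])
  })
}

#' @export
print.taxatext_corpus <- function(x, ...) {
  cat("<taxatext_corpus> ", nrow(x$taxa), " taxa, ",
      nrow(x$objects), " text objects\n", sep = "")
  invisible(x)
}

#' Load a corpus bundle
#'
#' Reads either a single JSON bundle (`taxa` and `objects` arrays) or a
#' directory holding `taxa.tsv` and `objects.tsv`. Bodies are cleaned with
#' [clean_markup()] and all corpus invariants are enforced.
#'
#' @param path path to a `.json` bundle or to a directory with the TSV pair.
#' @return a [corpus()] object.
#' @export
load_corpus <- function(path) {
  if (!file.exists(path)) abort_usage(paste("no such corpus path:", path))
  if (dir.exists(path)) {
    tpath <- file.path(path, "taxa.tsv")
    opath <- file.path(path, "objects.tsv")
    if (!file.exists(tpath) || !file.exists(opath)) {
      abort_parse("corpus directory must contain taxa.tsv and objects.tsv")
    }
    taxa <- readr::read_tsv(tpath, col_types = readr::cols(.default = "c"),
                            quote = "")
    objects <- readr::read_tsv(opath,
                               col_types = readr::cols(.default = "c"),
                               quote = "")
    if (nrow(objects) && "trusted" %in% names(objects)) {
      objects$trusted <- tolower(objects$trusted) %in%
        c("true", "t", "1", "yes")
    }
    return(corpus(taxa, objects))
  }
  bundle <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE),
    error = function(e) abort_parse(paste("malformed corpus bundle:",
                                          conditionMessage(e)))
  )
  taxa <- bundle$taxa
  if (is.null(taxa) || NROW(taxa) == 0) {
    taxa <- tibble::tibble(taxon_id = character(),
                           canonical_name = character())
  }
  objects <- bundle$objects
  if (is.null(objects) || NROW(objects) == 0) objects <- tibble::tibble()
  corpus(tibble::as_tibble(taxa), tibble::as_tibble(objects))
}

#' Write a corpus bundle
#'
#' Serializes a corpus either as a single JSON bundle or as `taxa.tsv` +
#' `objects.tsv` in a directory. `load_corpus()` on the result round-trips
#' to an equal corpus.
#'
#' @param x a [corpus()] object.
#' @param path output `.json` file (format `"json"`) or directory (`"tsv"`).
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "taxatext_corpus"))
  if (format == "json") {
    taxa <- x$taxa
    taxa$synonyms <- lapply(taxa$synonyms, as.character)
    taxa$common_names <- lapply(taxa$common_names, as.character)
    jsonlite::write_json(
      list(taxa = taxa, objects = x$objects),
      path, dataframe = "rows", auto_unbox = TRUE, na = "null", digits = NA
    )
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    taxa <- x$taxa
    taxa$synonyms <- vapply(taxa$synonyms, paste, "", collapse = "|")
    taxa$common_names <- vapply(taxa$common_names, paste, "", collapse = "|")
    # bodies are whitespace-squished, so tabs/newlines cannot occur and
    # quoting can be disabled for an exact textual round trip
    readr::write_tsv(taxa, file.path(path, "taxa.tsv"), na = "",
                     quote = "none", escape = "none")
    readr::write_tsv(x$objects, file.path(path, "objects.tsv"), na = "",
                     quote = "none", escape = "none")
  }
  invisible(path)
}

#' Filter text objects by subchapter, language and trust
#'
#' Returns exactly the text objects whose subchapter is in `subchapters`
#' (labels compared after stripping spaces and case, so `"Trophic Strategy"`
#' matches `"TrophicStrategy"`), whose language matches, and — when
#' `trusted_only` — whose trust flag is set. Deterministic order:
#' `taxon_id`, then `object_id`. Defaults mirror the study inclusion
#' criteria: English, trusted, the four ecology subchapters.
#'
#' @param x a [corpus()] object (or its `objects` tibble).
#' @param subchapters non-empty character vector of subchapter labels.
#' @param language two-letter language code.
#' @param trusted_only keep only objects flagged trusted?
#' @return tibble of text objects (possibly zero rows).
#' @export
filter_objects <- function(x, subchapters = ecology_subchapters(),
                           language = "en", trusted_only = TRUE) {
  if (length(subchapters) == 0) {
    abort_usage("subchapters must be non-empty")
  }
  objects <- if (inherits(x, "taxatext_corpus")) x$objects else
    tibble::as_tibble(x)
  if (nrow(objects) == 0) return(objects)
  keep <- normalize_subchapter(objects$subchapter) %in%
    normalize_subchapter(subchapters)
  keep <- keep & objects$language == language
  if (trusted_only) keep <- keep & objects$trusted
  dplyr::arrange(objects[keep, , drop = FALSE],
                 .data$taxon_id, .data$object_id)
}
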