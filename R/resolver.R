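# Name resolution: reconcile found names to accepted names and taxon ids
# against a chosen authority table.

#' Coerce a data frame to a names table
#'
#' The authority table for name verification and synonym resolution. One
#' row per name with columns `name`, `accepted_name`, `taxon_id`, `status`
#' (one of `current`, `synonym`, `common`) and optional `rank`,
#' `parent_id`. Invariants enforced: names unique (after case/whitespace
#' normalization), and every synonym or common row's `accepted_name` must
#' exist as a `current` row — a synonym always resolves in one hop to a
#' current record, whose `taxon_id` it inherits.
#'
#' @param x data frame with the columns above.
#' @return tibble of class `taxatext_names`.
#' @export
as_names_table <- function(x) {
  if (inherits(x, "taxatext_names")) return(x)
  x <- tibble::as_tibble(x)
  need <- setdiff(c("name", "accepted_name", "taxon_id", "status"), names(x))
  if (length(need)) {
    abort_parse(paste("names table missing column(s):",
                      paste(need, collapse = ", ")))
  }
  if (!"rank" %in% names(x)) x$rank <- NA_character_
  if (!"parent_id" %in% names(x)) x$parent_id <- NA_character_
  x <- x[c("name", "accepted_name", "taxon_id", "status", "rank",
           "parent_id")]
  x$name <- squish_nfc(as.character(x$name))
  x$accepted_name <- squish_nfc(as.character(x$accepted_name))
  x$taxon_id <- as.character(x$taxon_id)
  x$status <- as.character(x$status)
  x$rank <- as.character(x$rank)
  x$parent_id <- as.character(x$parent_id)

  bad_status <- !x$status %in% c("current", "synonym", "common")
  if (any(bad_status)) {
    abort_parse(paste0("unknown status '", x$status[bad_status][1],
                       "' (use current/synonym/common)"))
  }
  dup <- duplicated(norm_name(x$name))
  if (any(dup)) {
    abort_integrity(paste0("duplicate name row: '", x$name[dup][1], "'"))
  }
  current <- x[x$status == "current", ]
  if (any(!nzchar(current$taxon_id) | is.na(current$taxon_id))) {
    abort_integrity("current name row with empty taxon_id")
  }
  noncur <- x[x$status != "current", ]
  if (nrow(noncur)) {
    missing <- !norm_name(noncur$accepted_name) %in% norm_name(current$name)
    if (any(missing)) {
      abort_integrity(paste0("synonym '", noncur$name[missing][1],
                             "' points to accepted name '",
                             noncur$accepted_name[missing][1],
                             "' with no current row"))
    }
    # synonyms inherit the accepted record's taxon id
    idx <- match(norm_name(noncur$accepted_name), norm_name(current$name))
    x$taxon_id[x$status != "current"] <- current$taxon_id[idx]
  }
  structure(x, class = c("taxatext_names", class(tibble::tibble())))
}

#' Read a names table from TSV
#'
#' Columns `name`, `accepted_name`, `taxon_id`, `status` and optional
#' `rank`, `parent_id`; UTF-8; `#` comment lines ignored.
#'
#' @param path path to the TSV file.
#' @return a [as_names_table()] tibble.
#' @export
read_names_table <- function(path) {
  if (!file.exists(path)) abort_usage(paste("no such names table:", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#")
  if (nrow(tab) == 0) {
    rlang::warn(paste("empty names table:", path))
    return(as_names_table(tibble::tibble(
      name = character(), accepted_name = character(),
      taxon_id = character(), status = character()
    )))
  }
  as_names_table(tab)
}

#' Write a names table to TSV
#'
#' @param table a names table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_names_table <- function(table, path) {
  readr::write_tsv(as_names_table(table), path, na = "")
  invisible(path)
}

#' Resolve names against the authority table
#'
#' Case-insensitive, whitespace-normalized exact lookup — no fuzzy or
#' partial-genus matching, which keeps resolution deterministic and
#' auditable. A current name resolves to itself; a synonym resolves in one
#' hop to its accepted record (with `was_synonym = TRUE` and the accepted
#' record's taxon id — the behavior of a resolver returning the id of the
#' new name for an old one); a name absent from the table comes back
#' `matched = FALSE` with empty fields.
#'
#' @param names character vector of canonical name strings.
#' @param table a names table.
#' @return tibble with one row per input: `input`, `matched`,
#'   `accepted_name`, `taxon_id`, `was_synonym`.
#' @export
#' @examples
#' tab <- as_names_table(data.frame(
#'   name = c("Panthera leo", "Felis leo"),
#'   accepted_name = c("Panthera leo", "Panthera leo"),
#'   taxon_id = c("328672", ""),
#'   status = c("current", "synonym")))
#' resolve_names(c("Felis leo", "Unknownia absentis"), tab)
resolve_names <- function(names, table) {
  table <- as_names_table(table)
  names <- as.character(names)
  idx <- match(norm_name(names), norm_name(table$name))
  matched <- !is.na(idx)
  status <- ifelse(matched, table$status[idx], NA_character_)
  current <- table[table$status == "current", ]
  accepted <- ifelse(matched & status == "current",
                     table$name[idx], table$accepted_name[idx])
  # canonicalize accepted spelling to the current row's own casing
  cur_idx <- match(norm_name(accepted), norm_name(current$name))
  tibble::tibble(
    input = names,
    matched = matched,
    accepted_name = ifelse(matched, current$name[cur_idx], ""),
    taxon_id = ifelse(matched, table$taxon_id[idx], ""),
    was_synonym = matched & !is.na(status) & status == "synonym"
  )
}

#' @rdname resolve_names
#' @param name a single name string.
#' @export
resolve_name <- function(name, table) {
  stopifnot(length(name) == 1, nzchar(name))
  resolve_names(name, table)
}

# ancestor taxon ids of `taxon_id` via the parent_id chain of current rows
ancestor_ids <- function(taxon_id, table) {
  current <- table[table$status == "current", ]
  parent_of <- stats::setNames(current$parent_id, current$taxon_id)
  out <- character()
  cur <- parent_of[[taxon_id]] %||% NA_character_
  steps <- 0
  while (!is.na(cur) && nzchar(cur) && steps < 50) {
    out <- c(out, cur)
    cur <- parent_of[[cur]] %||% NA_character_
    steps <- steps + 1
  }
  out
}
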