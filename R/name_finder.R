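# Scientific-name mention finding: a local, rule-based recognizer with a
# binomial grammar, abbreviated-genus expansion, and table verification.

# Capitalized English words that collide with the binomial grammar at
# sentence starts ("This species ...", "Many crabs ..."); applied to
# unverified heuristic candidates only.
name_blacklist <- function() {
  c("The", "This", "That", "These", "Those", "There", "Some", "Many",
    "Most", "Several", "Both", "Each", "Other", "Another", "Their", "Its",
    "When", "Where", "While", "After", "Before", "During", "However",
    "Although", "Unlike", "Like", "Adult", "Adults", "Young", "Juveniles",
    "Large", "Small", "New", "No", "Not", "It", "They", "He", "She", "We",
    "In", "On", "At", "As", "An", "Our", "Such", "Only", "Often", "All",
    "Observers", "Individuals", "Field", "Dense", "Nearby", "Reports",
    "Because", "Since", "Despite", "Within", "Among", "Across")
}

norm_name <- function(x) stringr::str_to_lower(stringr::str_squish(x))

# latinate token patterns; hyphen allowed ("Pseudo-nitzschia")
re_genus <- "[A-Z][a-z]+(?:-[a-z]+)?"
re_epithet <- "[a-z]{2,}(?:-[a-z]+)?"

empty_mentions <- function() {
  tibble::tibble(offset = integer(), verbatim = character(),
                 canonical = character(), form = character())
}

#' Find scientific-name mentions in plain text
#'
#' A rule-based recognizer standing in for a names-discovery service.
#' Candidates come from four sources: (1) the binomial grammar — a
#' capitalized latinate token followed by a lowercase latinate token
#' (hyphens allowed, covering genera like "Pseudo-nitzschia"); (2)
#' abbreviated binomials ("C. pipiens"), expanded to the nearest preceding
#' genus in the same text with a matching initial; (3) genus/uninomial
#' names listed in the table; (4) table-exact matches for names that do not
#' fit the binomial shape, such as virus names ("Tobacco mosaic virus") —
#' these are only ever found by exact listing, since free-form grammar
#' rules are routinely confounded by such nomenclature.
#'
#' In `"strict"` mode only candidates verified against the names table
#' (accepted names, synonyms, listed uninomials and non-latinate names)
#' are returned; this is the default because for downstream curation high
#' precision matters far more than high recall, and it keeps results
#' deterministic. `"heuristic"` mode additionally returns unverified
#' binomial-grammar candidates, with a blacklist suppressing
#' sentence-initial English collisions ("This species").
#'
#' Common names are not matched unless `include_common = TRUE` and the
#' table carries `status = "common"` rows (off by default: scientific-name
#' finders do not see common names, a known recall gap).
#'
#' Overlapping candidates are resolved longest-match-first; reported
#' mentions are sorted by offset and never overlap. Heuristic results are
#' always a superset of strict results on the same input.
#'
#' @param text a single plain-text string (markup already stripped).
#' @param table a names table ([as_names_table()]); may be `NULL`/empty in
#'   heuristic mode only.
#' @param mode `"strict"` (default) or `"heuristic"`.
#' @param include_common also table-exact-match common names?
#' @return tibble `offset` (0-based), `verbatim`, `canonical` (expanded
#'   genus, single spaces), `form` (one of `binomial`, `uninomial`,
#'   `abbreviated-binomial`, `table-exact`).
#' @export
#' @examples
#' tab <- as_names_table(data.frame(
#'   name = "Carcharodon carcharias",
#'   accepted_name = "Carcharodon carcharias",
#'   taxon_id = "213726", status = "current"))
#' find_names("Carcharodon carcharias often attacks dolphins.", tab)
find_names <- function(text, table = NULL, mode = c("strict", "heuristic"),
                       include_common = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1)
  n_table <- if (is.null(table)) 0L else nrow(table)
  if (mode == "strict" && n_table == 0L) {
    abort_usage("strict mode requires a non-empty names table")
  }
  if (is.na(text) || !nzchar(text)) return(empty_mentions())
  if (n_table > 0) table <- as_names_table(table)

  table_names <- if (n_table > 0) {
    if (include_common) table$name else table$name[table$status != "common"]
  } else character()
  known <- norm_name(table_names)

  cands <- list()

  # (1) full binomials
  bin <- locate_all(text, paste0("\\b", re_genus, "\\s+", re_epithet, "\\b"))
  if (nrow(bin)) {
    bin$canonical <- stringr::str_squish(bin$verbatim)
    bin$form <- "binomial"
    bin$verified <- norm_name(bin$canonical) %in% known
    cands$binomial <- bin
  }

  # genus tokens the table knows about: first tokens of listed names plus
  # single-token listed names; only these anchor abbreviation expansion,
  # so capitalized English words cannot hijack "R. alis"
  known_genera <- unique(c(
    stringr::str_extract(table_names, "^\\S+"),
    table_names[!grepl("\\s", table_names)]
  ))

  # (3) table-listed uninomials (genus-level and other single-token names)
  uninames <- table_names[!grepl("\\s", table_names)]
  uni <- locate_all(text, paste0("\\b", re_genus, "\\b"))
  genus_occ <- tibble::tibble(genus = character(), start = integer())
  if (nrow(uni)) {
    is_gen <- norm_name(uni$verbatim) %in% norm_name(known_genera)
    genus_occ <- tibble::tibble(genus = uni$verbatim[is_gen],
                                start = uni$start[is_gen])
    uni <- uni[norm_name(uni$verbatim) %in% norm_name(uninames), ,
               drop = FALSE]
    if (nrow(uni)) {
      uni$canonical <- uni$verbatim
      uni$form <- "uninomial"
      uni$verified <- TRUE
      cands$uninomial <- uni
    }
  }

  # (2) abbreviated binomials, expanded to nearest preceding genus
  abb <- locate_all(text, paste0("\\b[A-Z]\\.\\s*", re_epithet, "\\b"))
  if (nrow(abb)) {
    initial <- substr(abb$verbatim, 1, 1)
    epithet <- stringr::str_extract(abb$verbatim, paste0(re_epithet, "$"))
    abb$canonical <- purrr::map2_chr(initial, abb$start, function(ini, st) {
      prior <- genus_occ[genus_occ$start < st &
                           substr(genus_occ$genus, 1, 1) == ini, ]
      if (nrow(prior) == 0) return(NA_character_)
      prior$genus[which.max(prior$start)]
    })
    ok <- !is.na(abb$canonical)
    abb <- abb[ok, , drop = FALSE]
    if (nrow(abb)) {
      abb$canonical <- paste(abb$canonical, epithet[ok])
      abb$form <- "abbreviated-binomial"
      abb$verified <- norm_name(abb$canonical) %in% known
      cands$abbreviated <- abb
    }
  }

  # (4) table-exact matches for names outside the binomial shape
  irregular <- table_names[!grepl(
    paste0("^", re_genus, "(\\s", re_epithet, ")?$"), table_names
  )]
  if (length(irregular)) {
    exact <- purrr::map(irregular, function(nm) {
      hits <- locate_all(
        text,
        stringr::regex(paste0("\\b", stringr::str_escape(nm), "\\b"),
                       ignore_case = TRUE)
      )
      if (nrow(hits)) {
        hits$canonical <- nm
        hits$form <- "table-exact"
        hits$verified <- TRUE
      }
      hits
    })
    exact <- dplyr::bind_rows(exact)
    if (nrow(exact)) cands$exact <- exact
  }

  cands <- dplyr::bind_rows(cands)
  if (NROW(cands) == 0) return(empty_mentions())

  keep_strict <- cands[cands$verified, , drop = FALSE]
  accepted <- resolve_overlaps(keep_strict)
  if (mode == "heuristic") {
    extra <- cands[!cands$verified & cands$form == "binomial", , drop = FALSE]
    if (nrow(extra)) {
      genus_tok <- stringr::str_extract(extra$canonical, "^\\S+")
      extra <- extra[!genus_tok %in% name_blacklist(), , drop = FALSE]
    }
    accepted <- resolve_overlaps(extra, fixed = accepted)
  }
  if (nrow(accepted) == 0) return(empty_mentions())

  accepted <- accepted[order(accepted$start), ]
  tibble::tibble(offset = accepted$start - 1L,
                 verbatim = accepted$verbatim,
                 canonical = accepted$canonical,
                 form = accepted$form)
}

# locate all matches of a pattern; returns start/end (1-based) + verbatim
locate_all <- function(text, pattern) {
  loc <- stringr::str_locate_all(text, pattern)[[1]]
  tibble::tibble(start = as.integer(loc[, 1]), end = as.integer(loc[, 2]),
                 verbatim = stringr::str_sub(text, loc[, 1], loc[, 2]))
}

# greedy longest-match-first overlap resolution; `fixed` rows are already
# accepted and cannot be displaced (guarantees heuristic >= strict)
resolve_overlaps <- function(cands, fixed = NULL) {
  base <- if (is.null(fixed)) cands[0, , drop = FALSE] else fixed
  if (NROW(cands) == 0) return(base)
  cands <- cands[order(-(cands$end - cands$start), cands$start), ]
  acc_start <- base$start
  acc_end <- base$end
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    s <- cands$start[i]; e <- cands$end[i]
    if (!any(s <= acc_end & e >= acc_start)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
    }
  }
  dplyr::bind_rows(base, cands[keep, , drop = FALSE])
}

#' Find name mentions across a table of text objects
#'
#' @param objects tibble with `object_id` and `body` columns.
#' @inheritParams find_names
#' @return tibble `object_id`, `offset`, `verbatim`, `canonical`, `form`,
#'   sorted by `object_id` then `offset`.
#' @export
find_names_in_objects <- function(objects, table = NULL,
                                  mode = c("strict", "heuristic"),
                                  include_common = FALSE) {
  mode <- match.arg(mode)
  objects <- tibble::as_tibble(objects)
  res <- purrr::map2(objects$object_id, objects$body, function(id, body) {
    m <- find_names(body, table, mode, include_common)
    if (nrow(m)) m$object_id <- id
    m
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(object_id = character(), offset = integer(),
                          verbatim = character(), canonical = character(),
                          form = character()))
  }
  out <- out[order(out$object_id, out$offset),
             c("object_id", "offset", "verbatim", "canonical", "form")]
  out
}

#' Write name mentions as TSV
#'
#' Columns `object_id`, `offset`, `verbatim`, `canonical`, `form`.
#'
#' @param mentions mention tibble from [find_names_in_objects()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  readr::write_tsv(mentions, path, na = "")
  invisible(path)
}
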