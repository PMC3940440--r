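# Species association network: subject-taxon -> mentioned-taxon edges from
# ecology-subchapter text, with filtering, deduplication and graph export.

#' Construct an association set from an edge table
#'
#' An association set is a deduplicated directed edge list: the page's
#' subject taxon points to each taxon mentioned in that page's ecology
#' text. Edge multiplicity collapses to a single edge with a
#' supporting-object count.
#'
#' @param edges data frame with columns `subject_taxon_id`,
#'   `object_taxon_id` and optionally `n_supporting_objects` (default 1).
#' @param mentions optional mention-level provenance tibble kept as an
#'   attribute (`object_id`, `offset`, `verbatim`, ... per mention).
#' @return tibble of class `association_set`, arranged by subject then
#'   object.
#' @export
association_set <- function(edges, mentions = NULL) {
  edges <- tibble::as_tibble(edges)
  need <- setdiff(c("subject_taxon_id", "object_taxon_id"), names(edges))
  if (length(need)) {
    abort_parse(paste("edge table missing column(s):",
                      paste(need, collapse = ", ")))
  }
  if (!"n_supporting_objects" %in% names(edges)) {
    edges$n_supporting_objects <- 1L
  }
  edges$subject_taxon_id <- as.character(edges$subject_taxon_id)
  edges$object_taxon_id <- as.character(edges$object_taxon_id)
  edges$n_supporting_objects <- as.integer(edges$n_supporting_objects)
  if (nrow(edges) > 0) {
    edges <- edges |>
      dplyr::group_by(.data$subject_taxon_id, .data$object_taxon_id) |>
      dplyr::summarise(
        n_supporting_objects = max(.data$n_supporting_objects),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$subject_taxon_id, .data$object_taxon_id)
  } else {
    edges <- edges[c("subject_taxon_id", "object_taxon_id",
                     "n_supporting_objects")]
  }
  structure(edges, class = c("association_set", class(tibble::tibble())),
            mentions = mentions)
}

#' Extract the species association network from a corpus
#'
#' The per-subject pipeline: restrict to the configured ecology
#' subchapters with [filter_objects()], find scientific-name mentions with
#' [find_names()], resolve each canonical mention with [resolve_names()],
#' drop mentions that resolve to the page's own subject taxon (including
#' via synonyms) when `self_filter` is on, optionally drop edges to a
#' taxon that is an ancestor (via the table's `parent_id` chain) of
#' another resolved mention on the same page (`higher_taxon_filter` —
#' targets the dominant false-positive mode where a species and its family
#' are both mentioned but the interaction is with the species), then
#' deduplicate into an [association_set()].
#'
#' `higher_taxon_filter` defaults off, matching the plain
#' mentioned-on-page reading of an association; it needs `rank`/`parent_id`
#' data in the table to do anything. Unresolved mentions are excluded
#' unless `retain_unresolved`, in which case they are kept keyed by their
#' canonical string.
#'
#' @param x a [corpus()] object.
#' @param table a names table ([as_names_table()]).
#' @param subchapters subchapter labels to mine (default the four ecology
#'   labels).
#' @param mode name-finder mode, `"strict"` (default) or `"heuristic"`.
#' @param self_filter drop mentions resolving to the subject itself?
#'   Default `TRUE`.
#' @param higher_taxon_filter drop ancestor-taxon edges as described?
#'   Default `FALSE`.
#' @param retain_unresolved keep unresolved mentions keyed by canonical
#'   string? Default `FALSE`.
#' @param language,trusted_only passed to [filter_objects()].
#' @return an [association_set()]; its `mentions` attribute holds
#'   mention-level provenance (`subject_taxon_id`, `object_taxon_id`,
#'   `object_id`, `subchapter`, `offset`, `verbatim`, `canonical`).
#' @export
extract_associations <- function(x, table,
                                 subchapters = ecology_subchapters(),
                                 mode = c("strict", "heuristic"),
                                 self_filter = TRUE,
                                 higher_taxon_filter = FALSE,
                                 retain_unresolved = FALSE,
                                 language = "en", trusted_only = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "taxatext_corpus"))
  table <- as_names_table(table)

  objs <- filter_objects(x, subchapters, language, trusted_only)
  mentions <- find_names_in_objects(objs, table, mode)
  if (nrow(mentions) == 0) {
    return(association_set(
      tibble::tibble(subject_taxon_id = character(),
                     object_taxon_id = character()),
      mentions = empty_provenance()
    ))
  }
  mentions <- dplyr::left_join(
    mentions, objs[c("object_id", "taxon_id", "subchapter")],
    by = "object_id"
  ) |>
    dplyr::rename(subject_taxon_id = "taxon_id")

  res <- resolve_names(mentions$canonical, table)
  mentions$object_taxon_id <- res$taxon_id
  mentions$matched <- res$matched
  mentions$was_synonym <- res$was_synonym

  if (retain_unresolved) {
    mentions$object_taxon_id <- ifelse(
      mentions$matched, mentions$object_taxon_id, mentions$canonical
    )
  } else {
    mentions <- mentions[mentions$matched, , drop = FALSE]
  }

  if (self_filter) {
    mentions <- mentions[
      !(mentions$matched &
          mentions$object_taxon_id == mentions$subject_taxon_id), ,
      drop = FALSE]
  }

  if (higher_taxon_filter && nrow(mentions)) {
    mentions <- mentions |>
      dplyr::group_by(.data$subject_taxon_id) |>
      dplyr::group_modify(function(df, key) {
        ids <- unique(df$object_taxon_id[df$matched])
        anc <- unique(unlist(lapply(ids, ancestor_ids, table = table)))
        df[!(df$matched & df$object_taxon_id %in% anc), , drop = FALSE]
      }) |>
      dplyr::ungroup()
  }

  prov <- mentions[c("subject_taxon_id", "object_taxon_id", "object_id",
                     "subchapter", "offset", "verbatim", "canonical",
                     "matched", "was_synonym")]
  edges <- mentions |>
    dplyr::group_by(.data$subject_taxon_id, .data$object_taxon_id) |>
    dplyr::summarise(
      n_supporting_objects = dplyr::n_distinct(.data$object_id),
      .groups = "drop"
    )
  association_set(edges, mentions = prov)
}

empty_provenance <- function() {
  tibble::tibble(subject_taxon_id = character(),
                 object_taxon_id = character(), object_id = character(),
                 subchapter = character(), offset = integer(),
                 verbatim = character(), canonical = character(),
                 matched = logical(), was_synonym = logical())
}

#' Node and edge counts of an association set
#'
#' @param a an [association_set()].
#' @return one-row tibble `n_nodes`, `n_edges`.
#' @export
network_summary <- function(a) {
  tibble::tibble(
    n_nodes = length(unique(c(a$subject_taxon_id, a$object_taxon_id))),
    n_edges = nrow(a)
  )
}

#' Mention-level provenance of an association set
#'
#' @param a an [association_set()].
#' @return the mention tibble recorded at extraction, or `NULL`.
#' @export
association_mentions <- function(a) attr(a, "mentions")

#' Write an association network for downstream graph tools
#'
#' Formats: `"tsv"` — header `subject_taxon_id`, `object_taxon_id`,
#' `n_supporting_objects` (read back with [read_network()]); `"sif"` —
#' simple interaction format with relation label `assoc`; `"graphml"` —
#' via igraph, with `n_supporting_objects` as an edge attribute. Edges are
#' stored directed (page subject to mentioned taxon); set
#' `directed = FALSE` to collapse reciprocal pairs for undirected
#' visualization.
#'
#' @param a an [association_set()].
#' @param path output file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @param directed keep edge direction? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_network <- function(a, path, format = c("tsv", "sif", "graphml"),
                          directed = TRUE) {
  if (!is.character(format) ||
      !all(format %in% c("tsv", "sif", "graphml"))) {
    abort_usage("unsupported network format (use tsv, sif or graphml)")
  }
  format <- match.arg(format)
  edges <- tibble::as_tibble(a)[
    c("subject_taxon_id", "object_taxon_id", "n_supporting_objects")]
  if (!directed && nrow(edges)) {
    lo <- pmin(edges$subject_taxon_id, edges$object_taxon_id)
    hi <- pmax(edges$subject_taxon_id, edges$object_taxon_id)
    edges$subject_taxon_id <- lo
    edges$object_taxon_id <- hi
    edges <- edges |>
      dplyr::group_by(.data$subject_taxon_id, .data$object_taxon_id) |>
      dplyr::summarise(
        n_supporting_objects = sum(.data$n_supporting_objects),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$subject_taxon_id, .data$object_taxon_id)
  }
  if (format == "tsv") {
    readr::write_tsv(edges, path, na = "")
  } else if (format == "sif") {
    writeLines(
      paste(edges$subject_taxon_id, "assoc", edges$object_taxon_id,
            sep = "\t"),
      path, useBytes = TRUE
    )
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = directed)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a TSV association network back into an association set
#'
#' @param path path written by [write_network()] with `format = "tsv"`.
#' @return an [association_set()].
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    n_supporting_objects = readr::col_integer(),
    .default = readr::col_character()
  ))
  association_set(edges)
}

#' @exportS3Method generics::tidy
tidy.association_set <- function(x, ...) {
  tibble::as_tibble(unclass_keep(x))
}

#' @exportS3Method generics::glance
glance.association_set <- function(x, ...) network_summary(x)

#' @exportS3Method ggplot2::autoplot
autoplot.association_set <- function(object, seed = 42, label = TRUE, ...) {
  edges <- tibble::as_tibble(unclass_keep(object))
  if (nrow(edges) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "empty association network") +
             ggplot2::theme_void())
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  lay <- withr::with_seed(seed, igraph::layout_nicely(g))
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = lay[, 1], y = lay[, 2])
  el <- igraph::as_edgelist(g)
  seg <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$name)],
    y = nodes$y[match(el[, 1], nodes$name)],
    xend = nodes$x[match(el[, 2], nodes$name)],
    yend = nodes$y[match(el[, 2], nodes$name)]
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 3, colour = "steelblue") +
    ggplot2::theme_void()
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -1, size = 3
    )
  }
  p
}

#' Plot an association network
#'
#' Convenience wrapper around the `autoplot()` method for association
#' sets: nodes laid out with igraph, directed edges drawn as arrows.
#'
#' @param a an [association_set()].
#' @param ... passed to the autoplot method (`seed`, `label`).
#' @return a ggplot object.
#' @export
plot_network <- function(a, ...) autoplot.association_set(a, ...)

# strip custom class but keep tibble classes
unclass_keep <- function(x) {
  class(x) <- class(tibble::tibble())
  x
}
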