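# Evaluation harness: confusion counts, precision/recall/F1 (per-unit and
# micro), Fleiss' kappa, relative improvement, error-category reporting.

#' F1 score as the harmonic mean of precision and recall
#'
#' `f1 = 2 p r / (p + r)`, with the convention that the score is 0 when
#' `p + r = 0`. Always computed from unrounded precision and recall.
#'
#' @param precision,recall numeric vectors in `[0, 1]`.
#' @return numeric vector of F1 scores.
#' @export
#' @examples
#' f1_from_pr(0.889, 1)   # 0.941 at 3 decimals
#' f1_from_pr(0.523, 1)   # 0.687
f1_from_pr <- function(precision, recall) {
  if (any(is.na(precision)) || any(is.na(recall)) ||
      any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1)) {
    abort_usage("precision and recall must be in [0, 1]")
  }
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, `f1` the
#' harmonic mean of the two (from unrounded values). Any 0/0 ratio
#' evaluates to 0 by convention, so an all-zero row yields an all-zero
#' metric set rather than NaN.
#'
#' @param counts data frame with numeric columns `tp`, `fp`, `fn`
#'   (additional columns such as `tn` or a unit label pass through).
#' @return the input tibble with `precision`, `recall`, `f1` columns
#'   appended (unrounded).
#' @export
#' @examples
#' compute_metrics(data.frame(tp = 9, fp = 2, fn = 2))
compute_metrics <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- setdiff(c("tp", "fp", "fn"), names(counts))
  if (length(need)) {
    abort_parse(paste("counts need column(s):", paste(need, collapse = ", ")))
  }
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0, na.rm = TRUE)) {
    abort_usage("confusion counts must be non-negative")
  }
  dplyr::mutate(
    counts,
    precision = ifelse(.data$tp + .data$fp == 0, 0,
                       .data$tp / (.data$tp + .data$fp)),
    recall = ifelse(.data$tp + .data$fn == 0, 0,
                    .data$tp / (.data$tp + .data$fn)),
    f1 = f1_from_pr(.data$precision, .data$recall)
  )
}

#' Relative improvement of one F1 score over a baseline
#'
#' `(new - base) / base`; the baseline must be positive.
#'
#' @param new_f1,base_f1 F1 scores (fractions).
#' @return the relative improvement as a fraction.
#' @export
#' @examples
#' relative_improvement(0.885, 0.636)  # about 0.39
relative_improvement <- function(new_f1, base_f1) {
  if (any(base_f1 <= 0)) abort_usage("base_f1 must be > 0")
  (new_f1 - base_f1) / base_f1
}

#' Score predicted URI annotations against a gold standard
#'
#' Per object, over unique-URI sets: `tp = |pred & gold|`,
#' `fp = |pred \\ gold|`, `fn = |gold \\ pred|`; `tn = 0` throughout (there
#' is no candidate universe for URIs). Gold rows carrying a non-missing
#' `error_category` are planted expected false positives (trap records)
#' and are excluded from the gold set proper; [trap_summary()] tallies how
#' many of them the annotator actually fired on.
#'
#' @param pred annotation tibble (`object_id`, `uri`), e.g. from
#'   [annotate_objects()].
#' @param gold gold tibble (`object_id`, `uri`, optional
#'   `error_category`).
#' @param object_ids optional full universe of object ids so objects with
#'   neither predictions nor gold appear as all-zero rows.
#' @return tibble of class `uri_comparison`: one row per object with
#'   `object_id`, `tp`, `fp`, `fn`, `tn`; `glance()` gives the micro
#'   (summed) counts with metrics.
#' @export
compare_uri_annotations <- function(pred, gold, object_ids = NULL) {
  pred <- tibble::as_tibble(pred)
  gold <- tibble::as_tibble(gold)
  if ("error_category" %in% names(gold)) {
    gold <- gold[is.na(gold$error_category) | gold$error_category == "", ]
  }
  pred_sets <- dplyr::distinct(pred[c("object_id", "uri")])
  gold_sets <- dplyr::distinct(gold[c("object_id", "uri")])
  ids <- union(union(pred_sets$object_id, gold_sets$object_id),
               as.character(object_ids %||% character()))
  ids <- sort(ids)
  both <- dplyr::inner_join(pred_sets, gold_sets,
                            by = c("object_id", "uri"))
  per <- tibble::tibble(object_id = ids) |>
    dplyr::left_join(dplyr::count(both, .data$object_id, name = "tp"),
                     by = "object_id") |>
    dplyr::left_join(dplyr::count(pred_sets, .data$object_id, name = "n_pred"),
                     by = "object_id") |>
    dplyr::left_join(dplyr::count(gold_sets, .data$object_id, name = "n_gold"),
                     by = "object_id") |>
    dplyr::mutate(dplyr::across(c("tp", "n_pred", "n_gold"),
                                ~ tidyr::replace_na(.x, 0L))) |>
    dplyr::mutate(fp = .data$n_pred - .data$tp,
                  fn = .data$n_gold - .data$tp, tn = 0L) |>
    dplyr::select("object_id", "tp", "fp", "fn", "tn")
  structure(per, class = c("uri_comparison", class(tibble::tibble())))
}

#' @exportS3Method generics::tidy
tidy.uri_comparison <- function(x, ...) {
  compute_metrics(tibble::as_tibble(unclass_keep(x)))
}

#' @exportS3Method generics::glance
glance.uri_comparison <- function(x, ...) {
  micro <- tibble::tibble(tp = sum(x$tp), fp = sum(x$fp),
                          fn = sum(x$fn), tn = sum(x$tn))
  compute_metrics(micro)
}

#' Tally which planted traps actually fired
#'
#' A trap is a gold row with a non-missing `error_category`: a URI the
#' annotator is expected to assign incorrectly (negation, related taxa,
#' word part, generality, homonym). A trap "fires" when the predicted
#' annotations contain that (object, URI) pair — every firing is a false
#' positive of the corresponding category, which is how the error taxonomy
#' of a run is reconstructed on synthetic data.
#'
#' @param pred annotation tibble (`object_id`, `uri`).
#' @param gold gold tibble including trap rows (`error_category` set).
#' @return tibble `error_category`, `n_planted`, `n_fired`.
#' @export
trap_summary <- function(pred, gold) {
  gold <- tibble::as_tibble(gold)
  if (!"error_category" %in% names(gold)) {
    return(tibble::tibble(error_category = character(),
                          n_planted = integer(), n_fired = integer()))
  }
  traps <- gold[!is.na(gold$error_category) & gold$error_category != "", ]
  pred_sets <- dplyr::distinct(tibble::as_tibble(pred)[c("object_id", "uri")])
  traps$fired <- vapply(seq_len(nrow(traps)), function(i) {
    any(pred_sets$object_id == traps$object_id[i] &
          pred_sets$uri == traps$uri[i])
  }, logical(1))
  traps |>
    dplyr::group_by(error_category = .data$error_category) |>
    dplyr::summarise(n_planted = dplyr::n(),
                     n_fired = sum(.data$fired), .groups = "drop")
}

#' Score a predicted association network against gold pairs
#'
#' Over (subject, object) pairs: `tp = |pred & gold|`,
#' `fp = |pred \\ gold|`, `fn = |gold \\ pred|`,
#' `tn = |universe \\ (pred | gold)|`. True negatives require a candidate
#' universe, which no natural definition pins down for this task; the
#' package default (see [association_universe()]) is every (subject,
#' resolved-mention) pair the name finder produces anywhere on each page,
#' any subchapter — an interpretive choice, so the universe is always an
#' explicit argument here.
#'
#' @param pred an [association_set()] or tibble with `subject_taxon_id`,
#'   `object_taxon_id`.
#' @param gold tibble of gold pairs with the same two columns.
#' @param universe tibble of candidate pairs; must contain every predicted
#'   and gold pair.
#' @return one-row tibble `tp`, `fp`, `fn`, `tn`.
#' @export
compare_associations <- function(pred, gold, universe) {
  key <- function(x) {
    x <- tibble::as_tibble(x)
    unique(paste(x$subject_taxon_id, x$object_taxon_id, sep = "\r"))
  }
  p <- key(pred); g <- key(gold); u <- key(universe)
  stray <- setdiff(union(p, g), u)
  if (length(stray)) {
    abort_usage(paste0("universe is missing ", length(stray),
                       " predicted or gold pair(s), e.g. '",
                       gsub("\r", " -> ", stray[1]), "'"))
  }
  tibble::tibble(
    tp = length(intersect(p, g)),
    fp = length(setdiff(p, g)),
    fn = length(setdiff(g, p)),
    tn = length(setdiff(u, union(p, g)))
  )
}

#' Default candidate-pair universe for association scoring
#'
#' All (subject taxon, resolved mention) pairs the name finder produces on
#' each page over all subchapters — not just the ecology ones — with
#' self-pairs removed. This is the widest set of pairs the pipeline could
#' conceivably have asserted, and hence a defensible (but interpretive)
#' denominator for true negatives.
#'
#' @param x a [corpus()] object.
#' @param table a names table.
#' @param mode name-finder mode.
#' @param gold optional gold pair tibble unioned in, so scoring never
#'   fails the universe-coverage precondition on missed gold pairs.
#' @return tibble `subject_taxon_id`, `object_taxon_id`.
#' @export
association_universe <- function(x, table, mode = c("strict", "heuristic"),
                                 gold = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "taxatext_corpus"))
  all_sub <- unique(x$objects$subchapter)
  pairs <- if (length(all_sub) == 0) {
    tibble::tibble(subject_taxon_id = character(),
                   object_taxon_id = character())
  } else {
    a <- extract_associations(x, table, subchapters = all_sub, mode = mode,
                              self_filter = TRUE)
    tibble::as_tibble(a)[c("subject_taxon_id", "object_taxon_id")]
  }
  if (!is.null(gold)) {
    pairs <- dplyr::bind_rows(
      pairs,
      tibble::as_tibble(gold)[c("subject_taxon_id", "object_taxon_id")]
    )
  }
  dplyr::distinct(pairs)
}

#' Fleiss' kappa for a fixed-rater rating matrix
#'
#' Chance-corrected agreement for `n` raters assigning `N` items to
#' categories: `kappa = (Pbar - Pe) / (1 - Pe)` with the usual per-item
#' agreement `P_i = (sum_j n_ij^2 - n) / (n (n - 1))` and chance agreement
#' `Pe = sum_j p_j^2` from the category marginals. Undefined (error) when
#' every rating falls in a single category (`Pe = 1`).
#'
#' @param m numeric matrix or data frame, items in rows and categories in
#'   columns, entries the number of raters assigning that item to that
#'   category; all row sums must be equal and at least 2.
#' @return kappa, a single number in `[-1, 1]`.
#' @export
#' @examples
#' m <- rbind(c(3, 0), c(2, 1), c(1, 2), c(0, 3), c(3, 0))
#' fleiss_kappa(m)
fleiss_kappa <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || any(m < 0)) {
    abort_usage("rating matrix must be non-negative numeric")
  }
  n_raters <- unique(rowSums(m))
  if (length(n_raters) != 1) {
    abort_usage("all items must have the same number of ratings")
  }
  if (n_raters < 2) abort_usage("need at least 2 raters per item")
  n <- n_raters
  p_i <- (rowSums(m^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(m) / sum(m)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps^0.5) {
    rlang::abort("kappa undefined: all ratings fall in one category",
                 class = "taxatext_undefined_kappa")
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Per-unit metrics table with a micro-averaged TOTAL row
#'
#' Reproduces the standard layout of published information-extraction
#' evaluations: one row per unit (species, corpus, run) with its confusion
#' counts and 3-decimal precision/recall/F1, and a final `TOTAL` row whose
#' metrics are computed from the summed counts (micro-averaging). Units
#' whose `tp`, `fp` and `fn` are all zero get blank (NA) metrics, matching
#' the blank cells such tables print for species without scoreable
#' output. Metrics are rounded half-up at 3 decimals for display; the
#' unrounded values are kept in the `"unrounded"` attribute and returned
#' by `tidy()`/`glance()`.
#'
#' @param counts data frame with a unit-label column (named `unit`, or the
#'   first character column) plus `tp`, `fp`, `fn` and optional `tn`.
#' @return tibble of class `metrics_report`.
#' @export
#' @examples
#' metrics_report(data.frame(unit = c("a", "b"),
#'                           tp = c(9, 1), fp = c(2, 0), fn = c(2, 0)))
metrics_report <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (!"unit" %in% names(counts)) {
    chr <- names(counts)[vapply(counts, is.character, logical(1))]
    if (length(chr) == 0 && nrow(counts) > 0) {
      abort_parse("counts need a 'unit' label column")
    }
    if (length(chr)) names(counts)[names(counts) == chr[1]] <- "unit"
  }
  if (nrow(counts) == 0) {
    counts <- tibble::tibble(unit = character(), tp = integer(),
                             fp = integer(), fn = integer())
  }
  has_tn <- "tn" %in% names(counts)
  keep <- c("unit", "tp", "fp", "fn", if (has_tn) "tn")
  counts <- counts[keep]
  total <- tibble::tibble(
    unit = "TOTAL", tp = sum(counts$tp), fp = sum(counts$fp),
    fn = sum(counts$fn)
  )
  if (has_tn) total$tn <- sum(counts$tn)
  full <- dplyr::bind_rows(counts, total)
  unrounded <- compute_metrics(full)
  out <- unrounded |>
    dplyr::mutate(dplyr::across(c("precision", "recall", "f1"),
                                ~ round_half_up(.x, 3)))
  blank <- out$tp == 0 & out$fp == 0 & out$fn == 0 & out$unit != "TOTAL"
  out$precision[blank] <- NA_real_
  out$recall[blank] <- NA_real_
  out$f1[blank] <- NA_real_
  structure(out, class = c("metrics_report", class(tibble::tibble())),
            unrounded = unrounded)
}

#' @exportS3Method generics::tidy
tidy.metrics_report <- function(x, ...) {
  un <- attr(x, "unrounded")
  un[un$unit != "TOTAL", ]
}

#' @exportS3Method generics::glance
glance.metrics_report <- function(x, ...) {
  un <- attr(x, "unrounded")
  un[un$unit == "TOTAL", ]
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  for (col in c("precision", "recall", "f1")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        formatC(df[[col]], format = "f", digits = digits))
  }
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.metrics_report <- function(object, ...) {
  un <- attr(object, "unrounded")
  df <- un[un$unit != "TOTAL", ] |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  df$metric <- factor(df$metric, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a metrics report as TSV (blank cells for NA metrics)
#'
#' @param x a [metrics_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(x, path) {
  df <- tibble::as_tibble(unclass_keep(x))
  for (col in c("precision", "recall", "f1")) {
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        formatC(df[[col]], format = "f", digits = 3))
  }
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' Summarize an error-category table
#'
#' Takes per-unit counts of manually categorized false positives (the
#' five-way error taxonomy: negation, describing related taxa, word part,
#' generalities, homonym) and returns per-category totals with each
#' category's share of all errors, as a rounded whole-number percentage.
#'
#' @param errors data frame in long form (`unit`, `category`, `n`) or wide
#'   form (`unit` plus one numeric column per category); NA counts are
#'   treated as zero.
#' @return tibble `category`, `n`, `share_pct`, with attribute
#'   `total_errors`.
#' @export
error_summary <- function(errors) {
  errors <- tibble::as_tibble(errors)
  if (!all(c("category", "n") %in% names(errors))) {
    errors <- tidyr::pivot_longer(
      errors, -dplyr::any_of(c("unit")),
      names_to = "category", values_to = "n"
    )
  }
  errors$n[is.na(errors$n)] <- 0
  out <- errors |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  total <- sum(out$n)
  out$share_pct <- if (total > 0) round_half_up(100 * out$n / total, 0) else
    rep(NA_real_, nrow(out))
  attr(out, "total_errors") <- total
  out
}

#' Read / write gold annotation and gold association files
#'
#' Gold annotations: TSV `object_id`, `uri`, optional `error_category`
#' (set only on planted trap rows). Gold associations: TSV
#' `subject_taxon_id`, `object_taxon_id`.
#'
#' @param path file path.
#' @param x tibble to write.
#' @return a tibble (read) or `path` invisibly (write).
#' @export
read_gold_annotations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}

#' @rdname read_gold_annotations
#' @export
write_gold_annotations <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}

#' @rdname read_gold_annotations
#' @export
read_gold_associations <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}

#' @rdname read_gold_annotations
#' @export
write_gold_associations <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "")
  invisible(path)
}
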