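test_that("compute_metrics matches published confusion-count arithmetic", {
  m <- compute_metrics(tibble::tibble(tp = 9, fp = 2, fn = 2))
  expect_equal(round_half_up(m$precision, 3), 0.818)
  expect_equal(round_half_up(m$recall, 3), 0.818)
  expect_equal(round_half_up(m$f1, 3), 0.818)

  b <- compute_metrics(tibble::tibble(tp = 510, fp = 560, fn = 24))
  expect_equal(round_half_up(b$precision, 3), 0.477)
  expect_equal(round_half_up(b$f1, 3), 0.636)

  z <- compute_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_error(compute_metrics(tibble::tibble(tp = -1, fp = 0, fn = 0)),
               class = "taxatext_usage_error")
})

test_that("f1_from_pr is the harmonic mean with sane conventions", {
  expect_equal(round_half_up(f1_from_pr(0.889, 1), 3), 0.941)
  expect_equal(round_half_up(f1_from_pr(0.523, 1), 3), 0.687)
  expect_equal(f1_from_pr(1, 1), 1)
  expect_equal(f1_from_pr(0, 0), 0)
  for (p in c(0.1, 0.25, 0.5, 0.836, 1)) {
    expect_equal(f1_from_pr(p, p), p)
  }
  expect_error(f1_from_pr(1.2, 0.5), class = "taxatext_usage_error")
})

test_that("relative_improvement computes (new - base) / base", {
  expect_equal(round_half_up(relative_improvement(0.885, 0.636), 2), 0.39)
  expect_equal(relative_improvement(0.7, 0.7), 0)
  expect_equal(relative_improvement(0.6, 0.3), 1)
  expect_error(relative_improvement(0.5, 0), class = "taxatext_usage_error")
})

test_that("URI comparison does per-object set arithmetic and micro totals", {
  pred <- tibble::tibble(object_id = c("o1", "o1", "o2", "o2"),
                         uri = c("U1", "U2", "U1", "U2"))
  gold <- tibble::tibble(object_id = c("o1", "o1", "o2", "o2"),
                         uri = c("U1", "U2", "U2", "U3"))
  cmp <- compare_uri_annotations(pred, gold)
  o1 <- cmp[cmp$object_id == "o1", ]
  expect_equal(c(o1$tp, o1$fp, o1$fn, o1$tn), c(2, 0, 0, 0))
  o2 <- cmp[cmp$object_id == "o2", ]
  expect_equal(c(o2$tp, o2$fp, o2$fn, o2$tn), c(1, 1, 1, 0))
  micro <- glance(cmp)
  expect_equal(c(micro$tp, micro$fp, micro$fn), c(3, 1, 1))

  # swapping pred and gold swaps fp with fn and preserves tp
  rev <- glance(compare_uri_annotations(gold, pred))
  expect_equal(rev$tp, micro$tp)
  expect_equal(rev$fp, micro$fn)
  expect_equal(rev$fn, micro$fp)

  # micro totals equal independently summed per-object counts
  sim <- generate_corpus(synth_config(n_taxa = 5,
                                      objects_per_taxon = c(2, 6),
                                      seed = 3))
  hits <- annotate_objects(sim$corpus$objects, sim$dictionary)
  cmp2 <- compare_uri_annotations(hits, sim$gold_annotations)
  by_hand <- tibble::tibble(tp = sum(cmp2$tp), fp = sum(cmp2$fp),
                            fn = sum(cmp2$fn))
  micro2 <- glance(cmp2)
  expect_equal(micro2[c("tp", "fp", "fn")], by_hand)
})

test_that("association comparison uses an explicit candidate universe", {
  pair <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(subject_taxon_id = m[, 1], object_taxon_id = m[, 2])
  }
  universe <- pair("A", "B", "A", "C", "B", "A", "B", "C")
  same <- compare_associations(pair("A", "B"), pair("A", "B"), universe)
  expect_equal(unlist(same), c(tp = 1, fp = 0, fn = 0, tn = 3))
  diff <- compare_associations(pair("A", "B"), pair("A", "C"), universe)
  expect_equal(unlist(diff), c(tp = 0, fp = 1, fn = 1, tn = 2))
  expect_error(
    compare_associations(pair("Z", "Q"), pair("A", "B"), universe),
    class = "taxatext_usage_error"
  )
})

test_that("fleiss_kappa matches a hand-computed oracle and its edge cases", {
  # perfect agreement
  expect_equal(fleiss_kappa(rbind(c(3, 0), c(0, 3), c(3, 0))), 1)
  # all ratings in one category: chance agreement is 1, kappa undefined
  expect_error(fleiss_kappa(rbind(c(3, 0), c(3, 0))),
               class = "taxatext_undefined_kappa")
  # 5 items x 3 raters x 2 categories, evaluated by hand:
  # P_i = (1, 1/3, 1/3, 1, 1), Pbar = 11/15; p = (0.6, 0.4), Pe = 0.52;
  # kappa = (11/15 - 0.52) / 0.48 = 0.4444444
  m <- rbind(c(3, 0), c(2, 1), c(1, 2), c(0, 3), c(3, 0))
  expect_equal(fleiss_kappa(m), (11 / 15 - 0.52) / 0.48)
  expect_equal(fleiss_kappa(m), 0.4444444, tolerance = 1e-6)
  # invariant under permutation of category columns and item rows
  expect_equal(fleiss_kappa(m[, c(2, 1)]), fleiss_kappa(m))
  expect_equal(fleiss_kappa(m[c(4, 2, 5, 1, 3), ]), fleiss_kappa(m))
  expect_error(fleiss_kappa(rbind(c(2, 1), c(2, 0))),
               class = "taxatext_usage_error")
})

test_that("metrics_report reproduces per-unit rows and the micro TOTAL", {
  counts <- readr::read_tsv(taxatext_example("assoc_workflow_counts.tsv"),
                            show_col_types = FALSE)
  rep <- metrics_report(counts)
  row <- function(u) rep[rep$unit == u, ]
  shark <- row("Carcharodon carcharias")
  expect_equal(c(shark$precision, shark$recall, shark$f1),
               c(0.818, 0.818, 0.818))
  lion <- row("Panthera leo")
  expect_equal(c(lion$precision, lion$recall, lion$f1),
               c(0.938, 0.882, 0.909))
  expect_equal(row("Apis mellifera")$precision, 0.809)
  expect_equal(c(row("Harrisia simpsonii")$precision,
                 row("Harrisia simpsonii")$f1), c(1, 1))
  total <- row("TOTAL")
  expect_equal(total$tp, 494)
  expect_equal(total$precision, 0.844)
  # blank metrics for rows with no scoreable output
  moss <- row("Hypnum fauriei")
  expect_true(is.na(moss$precision) && is.na(moss$f1))
  # micro-aggregation consistency
  micro <- compute_metrics(tibble::tibble(
    tp = sum(counts$tp), fp = sum(counts$fp), fn = sum(counts$fn)))
  expect_equal(glance(rep)$precision, micro$precision)
  expect_equal(glance(rep)$f1, micro$f1)
  # empty input still yields the TOTAL row
  empty <- metrics_report(tibble::tibble(unit = character(),
                                         tp = integer(), fp = integer(),
                                         fn = integer()))
  expect_equal(empty$unit, "TOTAL")
  expect_equal(empty$tp, 0)
})

test_that("metrics reports serialize with blank cells for NA metrics", {
  rep <- metrics_report(tibble::tibble(
    unit = c("a", "b"), tp = c(1, 0), fp = c(0, 0), fn = c(0, 0)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_report(rep, path)
  lines <- readLines(path)
  expect_equal(length(lines), 4)  # header + 2 units + TOTAL
  expect_true(grepl("b\t0\t0\t0\t\t\t", lines[3]))
})

test_that("error_summary reproduces the error-taxonomy arithmetic", {
  errors <- readr::read_tsv(taxatext_example("uri_annotation_errors.tsv"),
                            show_col_types = FALSE)
  s <- error_summary(errors)
  expect_equal(attr(s, "total_errors"), 57)
  expect_equal(s$n[s$category == "related_taxa"], 21)
  expect_equal(s$share_pct[s$category == "related_taxa"], 37)
  expect_equal(s$share_pct[s$category == "negation"], 7)
  expect_equal(s$share_pct[s$category == "word_part"], 19)
})

test_that("planted traps surface as categorized false positives", {
  sim <- generate_corpus(synth_config(
    n_taxa = 12, objects_per_taxon = c(4, 10),
    trap_rates = c(negation = 0.3, related_taxa = 0.3, word_part = 0.3,
                   generality = 0.3, homonym = 0.3),
    seed = 17
  ))
  hits <- annotate_objects(sim$corpus$objects, sim$dictionary)
  traps <- trap_summary(hits, sim$gold_annotations)
  # every planted trap stem occurs verbatim, so every trap fires
  expect_equal(traps$n_fired, traps$n_planted)
  # total false positives equal total trap firings
  micro <- glance(compare_uri_annotations(hits, sim$gold_annotations))
  expect_equal(micro$fp, sum(traps$n_fired))
  expect_setequal(traps$error_category,
                  c("negation", "related_taxa", "word_part", "generality",
                    "homonym"))
})
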