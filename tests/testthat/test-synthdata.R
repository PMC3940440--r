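test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_taxa = 5, objects_per_taxon = c(2, 6), seed = 42)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_equal(a$corpus$objects, b$corpus$objects)
  expect_equal(a$gold_annotations, b$gold_annotations)
  expect_equal(a$gold_associations, b$gold_associations)
  # and the serialized bundles are byte-identical
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_corpus(a$corpus, p1)
  write_corpus(b$corpus, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # a different seed changes the corpus
  c2 <- generate_corpus(synth_config(n_taxa = 5,
                                     objects_per_taxon = c(2, 6),
                                     seed = 43))
  expect_false(identical(a$corpus$objects$body, c2$corpus$objects$body))
})

test_that("generation does not disturb the session RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_corpus(synth_config(n_taxa = 2,
                                         objects_per_taxon = c(1, 2))))
  expect_identical(.Random.seed, before)
})

test_that("trap-free corpora give the annotator perfect precision and recall", {
  sim <- generate_corpus(trap_free_config(n_taxa = 8,
                                          objects_per_taxon = c(2, 8),
                                          seed = 7))
  hits <- annotate_objects(sim$corpus$objects, sim$dictionary)
  micro <- glance(compare_uri_annotations(hits, sim$gold_annotations))
  expect_equal(micro$precision, 1)
  expect_equal(micro$recall, 1)
  expect_equal(micro$fp, 0)
  expect_equal(micro$fn, 0)
})

test_that("a word-part rate of one plants a collision in every object", {
  sim <- generate_corpus(synth_config(
    n_taxa = 4, objects_per_taxon = c(3, 5),
    trap_rates = c(negation = 0, related_taxa = 0, word_part = 1,
                   generality = 0, homonym = 0),
    terms_per_object = 0, seed = 13
  ))
  traps <- sim$gold_annotations[!is.na(sim$gold_annotations$error_category), ]
  expect_equal(unique(traps$error_category), "word_part")
  expect_equal(nrow(traps), nrow(sim$corpus$objects))
  # the planted collision embeds the surface inside a larger phrase
  expect_true(all(grepl("kelp ", sim$corpus$objects$body, fixed = TRUE)))
  # and each trap is an expected false positive of the annotator
  hits <- annotate_objects(sim$corpus$objects, sim$dictionary)
  ts <- trap_summary(hits, sim$gold_annotations)
  expect_equal(ts$n_fired, ts$n_planted)
})

test_that("trap rates are recovered empirically at large n", {
  rates <- c(negation = 0.05, related_taxa = 0.12, word_part = 0.08,
             generality = 0.08, homonym = 0.08)
  sim <- generate_corpus(synth_config(
    n_taxa = 30, objects_per_taxon = c(15, 20), trap_rates = rates,
    seed = 19
  ))
  n_obj <- nrow(sim$corpus$objects)
  expect_gt(n_obj, 400)
  traps <- sim$gold_annotations[!is.na(sim$gold_annotations$error_category), ]
  counts <- table(factor(traps$error_category, levels = names(rates)))
  for (cat in names(rates)) {
    p <- rates[[cat]]
    tol <- 3 * sqrt(p * (1 - p) / n_obj) + 1e-9
    expect_lt(abs(counts[[cat]] / n_obj - p), tol)
  }
})

test_that("planted associations never leave the ecology subchapters", {
  sim <- generate_corpus(trap_free_config(n_taxa = 8,
                                          objects_per_taxon = c(2, 6),
                                          seed = 23))
  eco_ids <- filter_objects(sim$corpus)$object_id
  mentions <- find_names_in_objects(sim$corpus$objects, sim$names_table)
  resolved <- resolve_names(mentions$canonical, sim$names_table)
  mentions$taxon <- resolved$taxon_id
  obj_map <- sim$corpus$objects
  mentions$subject <- obj_map$taxon_id[match(mentions$object_id,
                                             obj_map$object_id)]
  planted <- mentions[resolved$matched & mentions$taxon != mentions$subject, ]
  gold_key <- paste(sim$gold_associations$subject_taxon_id,
                    sim$gold_associations$object_taxon_id)
  in_gold <- paste(planted$subject, planted$taxon) %in% gold_key
  # every gold pair is supported only by mentions in ecology objects
  expect_true(all(planted$object_id[in_gold] %in% eco_ids))
  # with no ecology objects there are no gold associations at all
  none <- generate_corpus(trap_free_config(n_taxa = 4,
                                           objects_per_taxon = c(2, 4),
                                           ecology_fraction = 0, seed = 2))
  expect_equal(nrow(none$gold_associations), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_taxa = 0), class = "taxatext_usage_error")
  expect_error(synth_config(trap_rates = c(negation = 1.5)),
               class = "taxatext_usage_error")
  expect_error(
    synth_config(
      dictionary = as_dictionary(tibble::tibble(key = character(),
                                                uri = character())),
      name_pool_size = 0, n_taxa = 1
    ),
    class = "taxatext_usage_error"
  )
})
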