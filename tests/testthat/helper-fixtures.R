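# shared in-code fixtures for the test suite

tiny_dictionary <- function() {
  as_dictionary(tibble::tibble(
    key = c("predat", "marine", "forest", "migrat"),
    uri = c("http://dbpedia.org/resource/Predation",
            "http://dbpedia.org/resource/Ocean",
            "http://dbpedia.org/resource/Forest",
            "http://dbpedia.org/resource/Animal_migration")
  ))
}

tiny_names_table <- function() {
  as_names_table(tibble::tibble(
    name = c("Panthera", "Panthera leo", "Felis leo",
             "Carcharodon", "Carcharodon carcharias",
             "Culex", "Culex pipiens", "Tobacco mosaic virus"),
    accepted_name = c("Panthera", "Panthera leo", "Panthera leo",
                      "Carcharodon", "Carcharodon carcharias",
                      "Culex", "Culex pipiens", "Tobacco mosaic virus"),
    taxon_id = c("g1", "328672", "", "g2", "213726", "g3", "740671",
                 "8615186"),
    status = c("current", "current", "synonym", "current", "current",
               "current", "current", "current"),
    rank = c("genus", "species", "species", "genus", "species", "genus",
             "species", "virus"),
    parent_id = c(NA, "g1", NA, NA, "g2", NA, "g3", NA)
  ))
}

# a 2-taxon corpus whose ecology text mentions a pool taxon
tiny_corpus <- function() {
  corpus(
    taxa = tibble::tibble(
      taxon_id = c("328672", "213726"),
      canonical_name = c("Panthera leo", "Carcharodon carcharias")
    ),
    objects = tibble::tibble(
      object_id = c("o1", "o2", "o3"),
      taxon_id = c("328672", "328672", "213726"),
      subchapter = c("TrophicStrategy", "Description", "Habitat"),
      body = c(
        "It often preys on Carcharodon carcharias near the coast.",
        "Carcharodon carcharias is mentioned here for comparison only.",
        "This species patrols open water beyond Culex pipiens habitat."
      )
    )
  )
}

# a 10-object mixed corpus: exactly 4 objects under ecology subchapters
mixed_corpus <- function() {
  subs <- c("Habitat", "Description", "Associations", "Distribution",
            "Trophic Strategy", "Morphology", "General Ecology",
            "Reproduction", "Behaviour", "Uses")
  corpus(
    taxa = tibble::tibble(taxon_id = "t1", canonical_name = "Morius alis"),
    objects = tibble::tibble(
      object_id = sprintf("o%02d", 1:10),
      taxon_id = "t1",
      subchapter = subs,
      body = paste("Object body number", 1:10)
    )
  )
}

trap_free_config <- function(...) {
  args <- list(
    trap_rates = c(negation = 0, related_taxa = 0, word_part = 0,
                   generality = 0, homonym = 0),
    synonym_rate = 0, self_reference_rate = 0, higher_taxon_rate = 0,
    common_name_rate = 0
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

# independent double-loop substring oracle for the annotator
annotation_oracle <- function(objects, d) {
  hits <- list()
  for (i in seq_len(nrow(objects))) {
    body <- tolower(objects$body[i])
    for (j in seq_len(nrow(d))) {
      if (grepl(d$key[j], body, fixed = TRUE)) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          object_id = objects$object_id[i], key = d$key[j]
        )
      }
    }
  }
  if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(object_id = character(), key = character())
}
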