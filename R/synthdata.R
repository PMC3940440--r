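# Seeded synthetic corpora with planted gold annotations, gold associations,
# and the five documented URI-error modes plus the two association-error
# modes, so every downstream stage is testable with no download.

trap_categories <- function() {
  c("negation", "related_taxa", "word_part", "generality", "homonym")
}

# surface forms for the packaged stems (each contains its own stem and no
# other packaged stem); unknown stems fall back to the stem itself
stem_surfaces <- c(
  "predat" = "predation", "herbivor" = "herbivory",
  "parasit" = "parasitism", "pollinat" = "pollination",
  "migrat" = "migration", "hibernat" = "hibernation",
  "nocturn" = "nocturnal habits", "symbio" = "symbiosis",
  "carnivor" = "carnivory", "omnivor" = "omnivory",
  "scaveng" = "scavenging", "burrow" = "burrowing",
  "venom" = "venom use", "spawn" = "spawning",
  "forest" = "forest", "marine" = "marine conditions",
  "estuar" = "estuaries", "plankt" = "plankton",
  "echolocat" = "echolocation", "cannibal" = "cannibalism",
  "gestat" = "gestation", "ovovivipar" = "ovoviviparity",
  "camoufl" = "camouflage",
  "uterine cannibalism" = "uterine cannibalism"
)

stem_surface <- function(key) {
  unname(ifelse(key %in% names(stem_surfaces), stem_surfaces[key], key))
}

#' Configuration for the synthetic-corpus generator
#'
#' Defaults emulate the conditions of the motivating study: 21 subject
#' taxa whose pages carry between 2 and 45 English, trusted text objects
#' (averaging in the twenties); roughly two planted dictionary terms per
#' object (matching the observed ~2.1 URIs per object); about 40% of
#' objects under the four ecology subchapters; two planted associations
#' per ecology object; a 6% synonym-mention rate (the observed old-name
#' share); and low per-object trap rates whose relative sizes follow the
#' observed error taxonomy (related-taxa errors largest, negation
#' smallest). Sentence templates, not a language model, generate the
#' prose: deterministic, dependency-free, auditable gold.
#'
#' @param n_taxa number of subject taxa (pages) to generate.
#' @param objects_per_taxon integer range `c(lo, hi)` of objects per page.
#' @param dictionary annotation dictionary to plant terms from; default
#'   the packaged ecology dictionary.
#' @param name_pool_size number of mentionable species in the name pool
#'   (subjects are the first `n_taxa` of these).
#' @param association_density expected planted associations per ecology
#'   object (Poisson mean).
#' @param terms_per_object expected planted dictionary terms per object
#'   (Poisson mean).
#' @param synonym_rate probability a planted mention uses the partner's
#'   synonym rather than its accepted name.
#' @param abbrev_rate probability a planted mention is followed by an
#'   abbreviated-genus repeat mention ("C. pipiens").
#' @param common_name_rate probability a planted association is expressed
#'   with the partner's common name only (an expected recall miss for a
#'   scientific-name finder; default 0).
#' @param trap_rates named probabilities in `[0, 1]` for the five
#'   URI-error categories: `negation`, `related_taxa`, `word_part`,
#'   `generality`, `homonym`; per object.
#' @param self_reference_rate probability an ecology object mentions its
#'   own subject (an expected association false positive unless
#'   self-filtering is on).
#' @param higher_taxon_rate probability a planted mention is accompanied
#'   by a bare genus mention (the dominant association false-positive
#'   mode).
#' @param ecology_fraction fraction of objects given ecology subchapters.
#' @param seed integer seed; a fixed seed makes the output bit-identical.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_taxa = 21,
                         objects_per_taxon = c(2, 45),
                         dictionary = NULL,
                         name_pool_size = 120,
                         association_density = 2,
                         terms_per_object = 2,
                         synonym_rate = 0.06,
                         abbrev_rate = 0.15,
                         common_name_rate = 0,
                         trap_rates = c(negation = 0.01,
                                        related_taxa = 0.04,
                                        word_part = 0.02,
                                        generality = 0.02,
                                        homonym = 0.02),
                         self_reference_rate = 0.05,
                         higher_taxon_rate = 0.05,
                         ecology_fraction = 0.4,
                         seed = 1L) {
  if (is.null(dictionary)) dictionary <- default_dictionary()
  dictionary <- as_dictionary(dictionary)
  if (n_taxa < 1) abort_usage("n_taxa must be >= 1")
  if (nrow(dictionary) == 0 && name_pool_size == 0) {
    abort_usage(paste("configuration error: dictionary and name pool",
                      "cannot both be empty"))
  }
  full <- stats::setNames(rep(0, 5), trap_categories())
  full[names(trap_rates)] <- trap_rates
  probs <- c(full, synonym_rate, abbrev_rate, common_name_rate,
             self_reference_rate, higher_taxon_rate, ecology_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort_usage("all rates must be probabilities in [0, 1]")
  }
  stopifnot(length(objects_per_taxon) == 2,
            objects_per_taxon[1] >= 1,
            objects_per_taxon[2] >= objects_per_taxon[1],
            association_density >= 0, terms_per_object >= 0)
  structure(list(
    n_taxa = as.integer(n_taxa),
    objects_per_taxon = as.integer(objects_per_taxon),
    dictionary = dictionary,
    name_pool_size = as.integer(max(name_pool_size, n_taxa)),
    association_density = association_density,
    terms_per_object = terms_per_object,
    synonym_rate = synonym_rate,
    abbrev_rate = abbrev_rate,
    common_name_rate = common_name_rate,
    trap_rates = full,
    self_reference_rate = self_reference_rate,
    higher_taxon_rate = higher_taxon_rate,
    ecology_fraction = ecology_fraction,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# deterministic latinate name pool; syllables chosen so that no packaged
# dictionary stem can occur inside a generated name
make_name_pool <- function(n, stems) {
  genus_a <- c("Bra", "Cor", "Del", "Fel", "Gal", "Lum", "Mor", "Nex",
               "Pol", "Rhi", "Sal", "Tar", "Vel", "Xan", "Zor", "Quel",
               "Thal", "Vor", "Mel", "Dru")
  genus_b <- c("ius", "ella", "odon", "ops", "ura", "ix", "ander", "una",
               "ex", "ax")
  ep_a <- c("al", "ber", "cun", "dor", "fex", "gil", "ham", "lor", "mun",
            "nar", "pes", "quin", "rus", "tal", "vex", "zon")
  ep_b <- c("is", "us", "ens", "icus", "ata", "ella", "oides", "ifer")
  genera <- unique(as.vector(outer(genus_a, genus_b, paste0)))
  epithets <- unique(as.vector(outer(ep_a, ep_b, paste0)))
  # drop anything that happens to contain a dictionary stem
  clean <- function(x) {
    x[!vapply(tolower(x), function(s) {
      any(stringr::str_detect(s, stringr::fixed(stems)))
    }, logical(1))]
  }
  genera <- clean(genera)
  epithets <- clean(epithets)
  n_gen <- max(ceiling(n / 3), 1)
  if (n_gen >= length(genera)) {
    abort_usage("name pool too large for the syllable inventory")
  }
  use_gen <- sample(genera, n_gen)
  syn_gen <- setdiff(genera, use_gen)
  species <- tibble::tibble(
    taxon_id = sprintf("s%04d", seq_len(n)),
    genus = sample(use_gen, n, replace = TRUE),
    epithet = sample(epithets, n, replace = TRUE)
  )
  species$canonical_name <- paste(species$genus, species$epithet)
  # enforce unique binomials
  dup <- duplicated(species$canonical_name)
  tries <- 0
  while (any(dup) && tries < 100) {
    species$epithet[dup] <- sample(epithets, sum(dup), replace = TRUE)
    species$canonical_name <- paste(species$genus, species$epithet)
    dup <- duplicated(species$canonical_name)
    tries <- tries + 1
  }
  if (any(dup)) abort_usage("could not generate enough unique names")
  # every species carries one synonym (an older name in a different
  # genus), so the synonym-use rate of planted mentions is exactly the
  # configured synonym_rate in expectation
  has_syn <- rep(TRUE, n)
  species$synonym <- NA_character_
  if (any(has_syn)) {
    species$synonym[has_syn] <- paste(
      sample(syn_gen, sum(has_syn), replace = TRUE),
      species$epithet[has_syn]
    )
    clash <- !is.na(species$synonym) &
      (species$synonym %in% species$canonical_name |
         duplicated(species$synonym, incomparables = NA))
    species$synonym[clash] <- NA_character_
  }
  genus_tab <- tibble::tibble(
    genus = sort(unique(species$genus)),
    genus_id = sprintf("g%03d", seq_along(sort(unique(species$genus))))
  )
  species$genus_id <- genus_tab$genus_id[match(species$genus,
                                               genus_tab$genus)]
  list(species = species, genera = genus_tab)
}

pool_names_table <- function(pool, common_names = NULL) {
  sp <- pool$species
  rows <- list(
    tibble::tibble(
      name = pool$genera$genus, accepted_name = pool$genera$genus,
      taxon_id = pool$genera$genus_id, status = "current",
      rank = "genus", parent_id = NA_character_
    ),
    tibble::tibble(
      name = sp$canonical_name, accepted_name = sp$canonical_name,
      taxon_id = sp$taxon_id, status = "current",
      rank = "species", parent_id = sp$genus_id
    )
  )
  syn <- sp[!is.na(sp$synonym), ]
  if (nrow(syn)) {
    rows$syn <- tibble::tibble(
      name = syn$synonym, accepted_name = syn$canonical_name,
      taxon_id = "", status = "synonym",
      rank = "species", parent_id = NA_character_
    )
  }
  if (!is.null(common_names) && nrow(common_names)) {
    rows$common <- tibble::tibble(
      name = common_names$common_name,
      accepted_name = common_names$canonical_name,
      taxon_id = "", status = "common",
      rank = NA_character_, parent_id = NA_character_
    )
  }
  as_names_table(dplyr::bind_rows(rows))
}

#' Generate a synthetic corpus with planted gold
#'
#' Builds a corpus of taxon pages from sentence templates, planting (a)
#' dictionary terms, recorded in the gold annotation set; (b) species
#' mentions in ecology-subchapter objects, recorded in the gold
#' association set; and (c) trap sentences at the configured rates —
#' negated terms ("does not engage in ..."), terms describing a relative,
#' word-part collisions ("kelp forest"), generalities, homonyms, plus
#' self-references and bare higher-taxon mentions — each recorded with its
#' error-category label so the expected false positives and negatives of
#' every downstream stage are known in advance. The same config and seed
#' reproduce identical output, bit for bit.
#'
#' After assembly every body is re-scanned with the annotator and the
#' generator stops with an internal error if the scan disagrees with the
#' planted record: the gold files are guaranteed consistent with the
#' corpus by construction, not by trust.
#'
#' @param config a [synth_config()].
#' @return list with elements `corpus` (a [corpus()]), `dictionary`,
#'   `names_table`, `gold_annotations` (`object_id`, `uri`,
#'   `error_category` — NA on true gold rows, the category label on
#'   planted expected false positives), `gold_associations`
#'   (`subject_taxon_id`, `object_taxon_id`), `association_traps`
#'   (expected association errors with category labels), `expected_misses`
#'   (gold associations the strict finder is expected to miss, e.g.
#'   common-name mentions), and `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  d <- cfg$dictionary
  stems <- d$key
  pool <- make_name_pool(cfg$name_pool_size, stems)
  sp <- pool$species

  common_names <- NULL
  if (cfg$common_name_rate > 0) {
    adj <- c("blue", "spotted", "dusky", "golden", "banded", "lesser",
             "greater", "pale", "ridge", "cliff")
    noun <- c("walker", "drifter", "digger", "glider", "creeper", "skimmer",
              "weaver", "dweller", "runner", "climber")
    common_names <- tibble::tibble(
      canonical_name = sp$canonical_name,
      common_name = paste(sample(adj, nrow(sp), replace = TRUE),
                          sample(noun, nrow(sp), replace = TRUE))
    )
    common_names <- common_names[!duplicated(common_names$common_name), ]
  }
  names_table <- pool_names_table(pool, common_names)

  # entries safe to plant: surface contains its own stem and no other stem
  surf <- stem_surface(stems)
  plantable <- which(vapply(seq_along(stems), function(i) {
    others <- stems[-i]
    stringr::str_detect(tolower(surf[i]), stringr::fixed(stems[i])) &&
      (length(others) == 0 ||
         !any(stringr::str_detect(tolower(surf[i]),
                                  stringr::fixed(others))))
  }, logical(1)))

  subjects <- sp[seq_len(cfg$n_taxa), ]
  taxa <- tibble::tibble(
    taxon_id = subjects$taxon_id,
    canonical_name = subjects$canonical_name,
    rank = "species",
    parent_id = subjects$genus_id,
    synonyms = lapply(subjects$synonym,
                      function(s) if (is.na(s)) character() else s),
    common_names = rep(list(character()), nrow(subjects))
  )

  openers <- c(
    "This species occupies a wide native range.",
    "Populations persist across much of the region.",
    "This taxon is recorded from scattered localities.",
    "Field surveys find this species year after year."
  )
  fillers <- c(
    "Numbers vary between years without clear pattern.",
    "Local abundance depends on shelter and season.",
    "Further study of these populations is ongoing.",
    "Records from older surveys agree with recent counts.",
    "Adults and juveniles occupy similar ground."
  )
  term_templates <- c(
    "Observers frequently report %s in this species.",
    "Local studies describe %s throughout the year.",
    "Seasonal records highlight %s at this site."
  )
  assoc_templates <- c(
    "It frequently feeds on %s during summer.",
    "Adults are often found alongside %s in shallow water.",
    "It competes with %s for space.",
    "Juveniles are eaten by %s in most years."
  )
  eco_labels <- ecology_subchapters()
  other_labels <- c("Description", "Distribution", "Reproduction",
                    "Morphology")

  objects <- list()
  gold_ann <- list()
  gold_assoc <- list()
  assoc_traps <- list()
  expected_misses <- list()
  obj_counter <- 0L

  for (si in seq_len(nrow(subjects))) {
    subj <- subjects[si, ]
    n_obj <- sample(seq(cfg$objects_per_taxon[1],
                        cfg$objects_per_taxon[2]), 1)
    for (oi in seq_len(n_obj)) {
      obj_counter <- obj_counter + 1L
      oid <- sprintf("o%05d", obj_counter)
      is_eco <- stats::runif(1) < cfg$ecology_fraction
      subchapter <- if (is_eco) sample(eco_labels, 1) else
        sample(other_labels, 1)
      sentences <- sample(openers, 1)
      used_entries <- integer()

      # planted dictionary terms (true gold)
      if (length(plantable)) {
        k <- min(stats::rpois(1, cfg$terms_per_object), length(plantable))
        if (k > 0) {
          picks <- sample(plantable, k)
          used_entries <- picks
          for (p in picks) {
            sentences <- c(sentences,
                           sprintf(sample(term_templates, 1), surf[p]))
            gold_ann[[length(gold_ann) + 1L]] <- tibble::tibble(
              object_id = oid, uri = d$uri[p],
              error_category = NA_character_
            )
          }
        }
      }

      # trap sentences: expected annotation false positives
      for (cat in trap_categories()) {
        if (stats::runif(1) >= cfg$trap_rates[[cat]]) next
        avail <- setdiff(plantable, used_entries)
        if (length(avail) == 0) next
        p <- if (length(avail) == 1) avail else sample(avail, 1)
        used_entries <- c(used_entries, p)
        s <- switch(
          cat,
          negation = sprintf("This species does not engage in %s.", surf[p]),
          related_taxa = sprintf(
            "Unlike this species, a close relative is known for %s.",
            surf[p]),
          word_part = sprintf(
            "It drifts along the kelp %s margins without entering them.",
            surf[p]),
          generality = sprintf(
            "In general, %s is rare among unrelated groups elsewhere.",
            surf[p]),
          homonym = sprintf(
            "Here the word %s carries a different sense entirely.", surf[p])
        )
        sentences <- c(sentences, s)
        gold_ann[[length(gold_ann) + 1L]] <- tibble::tibble(
          object_id = oid, uri = d$uri[p], error_category = cat
        )
      }

      # planted associations (ecology objects only)
      if (is_eco && nrow(sp) > 1) {
        m <- min(stats::rpois(1, cfg$association_density), nrow(sp) - 1)
        if (m > 0) {
          partners <- sp[sp$taxon_id != subj$taxon_id, ]
          partners <- partners[sample(nrow(partners), m), ]
          for (pi in seq_len(nrow(partners))) {
            part <- partners[pi, ]
            by_common <- !is.null(common_names) &&
              stats::runif(1) < cfg$common_name_rate &&
              part$canonical_name %in% common_names$canonical_name
            if (by_common) {
              cn <- common_names$common_name[
                match(part$canonical_name, common_names$canonical_name)]
              sentences <- c(sentences, sprintf(
                "Residents report that the %s shares this ground.", cn))
              expected_misses[[length(expected_misses) + 1L]] <-
                tibble::tibble(subject_taxon_id = subj$taxon_id,
                               object_taxon_id = part$taxon_id,
                               category = "common_name")
            } else {
              use_syn <- !is.na(part$synonym) &&
                stats::runif(1) < cfg$synonym_rate
              nm <- if (use_syn) part$synonym else part$canonical_name
              sentences <- c(sentences,
                             sprintf(sample(assoc_templates, 1), nm))
              if (stats::runif(1) < cfg$abbrev_rate) {
                bits <- strsplit(nm, " ", fixed = TRUE)[[1]]
                sentences <- c(sentences, sprintf(
                  "Records of %s. %s are frequent at this site.",
                  substr(bits[1], 1, 1), bits[2]))
              }
              if (stats::runif(1) < cfg$higher_taxon_rate) {
                sentences <- c(sentences, sprintf(
                  "Members of %s occur throughout the area.", part$genus))
                assoc_traps[[length(assoc_traps) + 1L]] <-
                  tibble::tibble(subject_taxon_id = subj$taxon_id,
                                 object_taxon_id = part$genus_id,
                                 category = "higher_taxon")
              }
            }
            gold_assoc[[length(gold_assoc) + 1L]] <-
              tibble::tibble(subject_taxon_id = subj$taxon_id,
                             object_taxon_id = part$taxon_id)
          }
        }
        if (stats::runif(1) < cfg$self_reference_rate) {
          sentences <- c(sentences, sprintf(
            "%s adults gather with conspecifics near cover.",
            subj$canonical_name))
          assoc_traps[[length(assoc_traps) + 1L]] <-
            tibble::tibble(subject_taxon_id = subj$taxon_id,
                           object_taxon_id = subj$taxon_id,
                           category = "self_reference")
        }
      }

      sentences <- c(sentences,
                     sample(fillers, sample(1:2, 1)))
      objects[[obj_counter]] <- tibble::tibble(
        object_id = oid, taxon_id = subj$taxon_id,
        subchapter = subchapter,
        body = paste(sentences, collapse = " "),
        language = "en", trusted = TRUE, source = "synthetic"
      )
    }
  }

  objects <- dplyr::bind_rows(objects)
  gold_annotations <- if (length(gold_ann)) dplyr::bind_rows(gold_ann) else
    tibble::tibble(object_id = character(), uri = character(),
                   error_category = character())
  gold_associations <- if (length(gold_assoc)) {
    dplyr::distinct(dplyr::bind_rows(gold_assoc))
  } else {
    tibble::tibble(subject_taxon_id = character(),
                   object_taxon_id = character())
  }
  association_traps <- if (length(assoc_traps)) {
    dplyr::distinct(dplyr::bind_rows(assoc_traps))
  } else {
    tibble::tibble(subject_taxon_id = character(),
                   object_taxon_id = character(), category = character())
  }
  expected_misses <- if (length(expected_misses)) {
    dplyr::distinct(dplyr::bind_rows(expected_misses))
  } else {
    tibble::tibble(subject_taxon_id = character(),
                   object_taxon_id = character(), category = character())
  }

  out_corpus <- corpus(taxa, objects, clean = FALSE)

  # consistency guarantee: the annotator's hits on every body must be
  # exactly the planted gold + trap URIs for that object
  check <- annotate_objects(out_corpus$objects, d)
  planted <- dplyr::distinct(gold_annotations[c("object_id", "uri")])
  found <- dplyr::distinct(check[c("object_id", "uri")])
  if (!identical(
    dplyr::arrange(planted, .data$object_id, .data$uri),
    dplyr::arrange(found, .data$object_id, .data$uri)
  )) {
    rlang::abort("internal generator error: planted gold disagrees with scan")
  }

  list(corpus = out_corpus, dictionary = d, names_table = names_table,
       gold_annotations = gold_annotations,
       gold_associations = gold_associations,
       association_traps = association_traps,
       expected_misses = expected_misses,
       config = cfg)
}
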