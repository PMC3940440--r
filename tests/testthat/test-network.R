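test_that("extraction builds edges only from ecology subchapters", {
  x <- tiny_corpus()
  tab <- tiny_names_table()
  a <- extract_associations(x, tab)
  # lion's TrophicStrategy object mentions the shark -> one edge; the
  # Description-only mention and the shark's unlisted-habitat text give
  # the shark page one edge to the mosquito
  edges <- tibble::as_tibble(a)
  shark_edges <- edges[edges$subject_taxon_id == "213726", ]
  expect_equal(shark_edges$object_taxon_id, "740671")
  lion_edges <- edges[edges$subject_taxon_id == "328672", ]
  expect_equal(lion_edges$object_taxon_id, "213726")
  # the comparison mention in the "Description" object added nothing
  expect_equal(lion_edges$n_supporting_objects, 1L)
  prov <- association_mentions(a)
  expect_true(all(normalize_subchapter(prov$subchapter) %in%
                    normalize_subchapter(ecology_subchapters())))
})

test_that("self mentions are dropped when self_filter is on", {
  tab <- tiny_names_table()
  x <- corpus(
    tibble::tibble(taxon_id = "328672", canonical_name = "Panthera leo"),
    tibble::tibble(object_id = "o1", taxon_id = "328672",
                   subchapter = "GeneralEcology",
                   body = "Panthera leo hunts; Felis leo is the old name.")
  )
  a_on <- extract_associations(x, tab, self_filter = TRUE)
  expect_equal(nrow(a_on), 0)
  # synonym mentions of the subject are also self references
  a_off <- extract_associations(x, tab, self_filter = FALSE)
  expect_equal(tibble::as_tibble(a_off)$object_taxon_id, "328672")
})

test_that("higher-taxon filter drops ancestor edges of mentioned species", {
  tab <- tiny_names_table()
  x <- corpus(
    tibble::tibble(taxon_id = "740671", canonical_name = "Culex pipiens"),
    tibble::tibble(object_id = "o1", taxon_id = "740671",
                   subchapter = "Associations",
                   body = paste("Often taken by Carcharodon carcharias.",
                                "Members of Carcharodon roam widely."))
  )
  plain <- tibble::as_tibble(extract_associations(x, tab))
  expect_setequal(plain$object_taxon_id, c("213726", "g2"))
  filtered <- tibble::as_tibble(
    extract_associations(x, tab, higher_taxon_filter = TRUE))
  expect_equal(filtered$object_taxon_id, "213726")
})

test_that("network_summary counts nodes and edges after deduplication", {
  empty <- association_set(tibble::tibble(subject_taxon_id = character(),
                                          object_taxon_id = character()))
  expect_equal(network_summary(empty), tibble::tibble(n_nodes = 0L,
                                                      n_edges = 0L))
  two <- association_set(tibble::tibble(
    subject_taxon_id = c("A", "A"), object_taxon_id = c("B", "C")))
  expect_equal(network_summary(two)$n_nodes, 3)
  expect_equal(network_summary(two)$n_edges, 2)
  dup <- association_set(tibble::tibble(
    subject_taxon_id = c("A", "A"), object_taxon_id = c("B", "B")))
  expect_equal(network_summary(dup), tibble::tibble(n_nodes = 2L,
                                                    n_edges = 1L))
  expect_equal(glance(dup), network_summary(dup))
})

test_that("network export round-trips and supports sif/graphml", {
  a <- association_set(tibble::tibble(
    subject_taxon_id = c("A", "A"), object_taxon_id = c("B", "C"),
    n_supporting_objects = c(2L, 1L)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(a, tsv, format = "tsv")
  expect_equal(length(readLines(tsv)), 3)  # header + 2 edges
  back <- read_network(tsv)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(a))

  empty <- association_set(tibble::tibble(subject_taxon_id = character(),
                                          object_taxon_id = character()))
  write_network(empty, tsv, format = "tsv")
  expect_equal(length(readLines(tsv)), 1)  # header only

  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(a, sif, format = "sif")
  expect_equal(readLines(sif), c("A\tassoc\tB", "A\tassoc\tC"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(a, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), 2)
  expect_true("n_supporting_objects" %in%
                igraph::edge_attr_names(g))

  expect_error(write_network(a, tsv, format = "edgelist"),
               class = "taxatext_usage_error")
})

test_that("undirected export collapses reciprocal pairs", {
  a <- association_set(tibble::tibble(
    subject_taxon_id = c("A", "B"), object_taxon_id = c("B", "A"),
    n_supporting_objects = c(1L, 2L)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(a, tsv, format = "tsv", directed = FALSE)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), 1)
  expect_equal(back$n_supporting_objects, 3)
})

test_that("extraction is deterministic and serializes byte-identically", {
  sim <- generate_corpus(trap_free_config(n_taxa = 6,
                                          objects_per_taxon = c(2, 6),
                                          seed = 5))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(extract_associations(sim$corpus, sim$names_table), p1)
  write_network(extract_associations(sim$corpus, sim$names_table), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("trap-free synthetic extraction has perfect precision and recall", {
  sim <- generate_corpus(trap_free_config(n_taxa = 10,
                                          objects_per_taxon = c(3, 10),
                                          seed = 9))
  a <- extract_associations(sim$corpus, sim$names_table)
  universe <- association_universe(sim$corpus, sim$names_table,
                                   gold = sim$gold_associations)
  counts <- compare_associations(a, sim$gold_associations, universe)
  m <- compute_metrics(counts)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
})
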