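test_that("triple-TSV reader transcribes, collapses duplicates, handles empties", {
  p <- write_model_fixture(c("RM\tR1\tm1", "RM\tR2\tm1", "RG\tR1\tgA",
                             "RG\tR2\tgB"))
  m <- read_metabolic_model(p)
  expect_equal(length(m$reactions), 2)
  expect_equal(m$metabolites, "m1")
  expect_equal(model_genes(m), c("gA", "gB"))

  empty <- write_model_fixture(character())
  m0 <- read_metabolic_model(empty)
  expect_equal(length(m0$metabolites), 0)
  expect_equal(nrow(m0$incidence), 0)

  dup <- write_model_fixture(c("RM\tR1\tm1", "RM\tR1\tm1"))
  expect_equal(nrow(suppressWarnings(read_metabolic_model(dup))$incidence), 1)

  bad <- write_model_fixture(c("RM\tR1"))
  expect_error(read_metabolic_model(bad), "line 2")
  badkind <- write_model_fixture(c("XX\tR1\tm1"))
  expect_error(read_metabolic_model(badkind), "RM or RG")
})

test_that("model validation catches undeclared references and namespace clashes", {
  expect_error(
    metabolic_model(metabolites = "m1", reactions = "R1",
                    incidence = data.frame(reaction = "R9", metabolite = "m1")),
    "undeclared reactions")
  expect_error(
    metabolic_model(metabolites = "m1", reactions = "R1",
                    incidence = data.frame(reaction = "R1", metabolite = "m1"),
                    gene_map = data.frame(reaction = "R1", gene = "m1")),
    "namespaces overlap")
  expect_warning(
    metabolic_model(metabolites = "m1", reactions = c("R1", "R2"),
                    incidence = data.frame(reaction = "R1", metabolite = "m1")),
    "no incident metabolite")
})

test_that("currency removal: identity at 0, ceil arithmetic, hub targeting, tie-break", {
  m <- random_model(1)
  out <- remove_currency_metabolites(m, 0)
  expect_identical(out$model$incidence, m$incidence)
  expect_equal(nrow(out$report$removed), 0)

  # 10 metabolites at fraction 0.05 -> ceil(0.5) = 1 removed
  m10 <- random_model(2, n_metabolites = 10)
  out10 <- remove_currency_metabolites(m10, 0.05)
  expect_equal(nrow(out10$report$removed), 1)
  expect_equal(length(out10$model$metabolites), 9)

  # star model: hub touches all 20 reactions, 19 others touch 1 each
  rxns <- paste0("R", 1:20)
  star <- suppressWarnings(metabolic_model(
    metabolites = c("m_hub", paste0("m", 1:19)), reactions = rxns,
    incidence = rbind(data.frame(reaction = rxns, metabolite = "m_hub"),
                      data.frame(reaction = rxns[1:19],
                                 metabolite = paste0("m", 1:19)))))
  out_star <- remove_currency_metabolites(star, 0.05)
  expect_equal(out_star$report$removed$metabolite, "m_hub")
  expect_equal(out_star$report$removed$degree, 20L)

  # degree ties broken lexicographically -> nested removal sets
  tie <- suppressWarnings(metabolic_model(
    metabolites = c("mB", "mA", "mC"), reactions = c("R1", "R2"),
    incidence = data.frame(reaction = c("R1", "R1", "R2", "R2"),
                           metabolite = c("mA", "mB", "mA", "mB"))))
  r1 <- remove_currency_metabolites(tie, 0.3)$report$removed$metabolite
  r2 <- remove_currency_metabolites(tie, 0.5)$report$removed$metabolite
  expect_equal(r1, "mA")
  expect_equal(r2, c("mA", "mB"))
  expect_true(all(r1 %in% r2))

  expect_error(remove_currency_metabolites(m, 1), "\\[0, 1\\)")
  expect_error(remove_currency_metabolites(m, -0.1), "\\[0, 1\\)")
})

test_that("projection: shared metabolite connects, disjoint isolates, same-reaction rule", {
  m <- suppressWarnings(metabolic_model(
    metabolites = "m1", reactions = c("R1", "R2"),
    incidence = data.frame(reaction = c("R1", "R2"), metabolite = "m1"),
    gene_map = data.frame(reaction = c("R1", "R2"), gene = c("gA", "gB"))))
  net <- project_gene_network(m)
  expect_equal(nrow(net$edges), 1)
  expect_equal(unname(net$edges[1, ]), c("gA", "gB"))

  iso <- metabolic_model(
    metabolites = c("m1", "m2"), reactions = c("R1", "R2"),
    incidence = data.frame(reaction = c("R1", "R2"),
                           metabolite = c("m1", "m2")),
    gene_map = data.frame(reaction = c("R1", "R2"), gene = c("gA", "gB")))
  expect_equal(nrow(project_gene_network(iso)$edges), 0)
  expect_equal(project_gene_network(iso)$nodes, c("gA", "gB"))

  # isoenzymes on one reaction: adjacent iff the reaction has a metabolite
  iso2 <- metabolic_model(
    metabolites = "m1", reactions = "R1",
    incidence = data.frame(reaction = "R1", metabolite = "m1"),
    gene_map = data.frame(reaction = c("R1", "R1"), gene = c("gA", "gB")))
  expect_equal(nrow(project_gene_network(iso2)$edges), 1)
  nomet <- suppressWarnings(metabolic_model(
    metabolites = character(), reactions = "R1",
    gene_map = data.frame(reaction = c("R1", "R1"), gene = c("gA", "gB"))))
  expect_equal(nrow(project_gene_network(nomet)$edges), 0)

  expect_equal(length(project_gene_network(metabolic_model())$nodes), 0)
})

test_that("projection equals the brute-force reaction-pair oracle on 100 random models", {
  for (s in 1:100) {
    m <- random_model(s)
    got <- project_gene_network(m)
    want <- brute_force_project(m)
    expect_identical(got$nodes, want$nodes)
    expect_identical(got$edges, want$edges)
  }
})

test_that("projection is invariant under reaction/metabolite relabeling", {
  m <- random_model(7)
  relab <- suppressWarnings(metabolic_model(
    metabolites = paste0("X_", m$metabolites),
    reactions = paste0("Y_", m$reactions),
    incidence = data.frame(reaction = paste0("Y_", m$incidence$reaction),
                           metabolite = paste0("X_", m$incidence$metabolite)),
    gene_map = data.frame(reaction = paste0("Y_", m$gene_map$reaction),
                          gene = m$gene_map$gene)))
  expect_identical(project_gene_network(m)$edges,
                   project_gene_network(relab)$edges)
})

test_that("edge monotonicity under nested currency removal", {
  for (s in 1:20) {
    m <- random_model(s, n_reactions = 10, n_metabolites = 8)
    e1 <- project_gene_network(remove_currency_metabolites(m, 0.1)$model)$edges
    e2 <- project_gene_network(remove_currency_metabolites(m, 0.4)$model)$edges
    key <- function(e) paste(e[, 1], e[, 2])
    expect_true(all(key(e2) %in% key(e1)))
  }
})

test_that("restrict_to_measured: identity, empty, induction, and projection commutes", {
  tri <- triangle_plus_isolate()
  expect_identical(restrict_to_measured(tri, tri$nodes), tri)
  expect_equal(length(restrict_to_measured(tri, character())$nodes), 0)
  sub <- restrict_to_measured(tri, c("gA", "gB"))
  expect_equal(nrow(sub$edges), 1)
  expect_equal(unname(sub$edges[1, ]), c("gA", "gB"))

  # restrict(project(m)) == project(m with those gene_map rows deleted)
  for (s in 1:20) {
    m <- random_model(s)
    keep <- sample(model_genes(m), 3)
    a <- restrict_to_measured(project_gene_network(m), keep)
    m2 <- suppressWarnings(metabolic_model(
      metabolites = m$metabolites, reactions = m$reactions,
      incidence = m$incidence,
      gene_map = m$gene_map[m$gene_map$gene %in% keep, , drop = FALSE]))
    b <- project_gene_network(m2)
    expect_identical(a$nodes, b$nodes)
    expect_identical(a$edges, b$edges)
  }
})

test_that("network round-trips through edge-list TSV and exports GraphML", {
  net <- random_network(3)
  p <- tempfile(fileext = ".tsv")
  write_gene_network(net, p)
  back <- read_gene_network(p, nodes = net$nodes)
  expect_identical(back$edges, net$edges)
  g <- tempfile(fileext = ".graphml")
  write_gene_network(net, g, format = "graphml")
  expect_true(file.size(g) > 0)
})

test_that("SBML-subset reader flattens species/reactions/gene products", {
  skip_if_not_installed("xml2")
  sbml <- tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
<model id="toy"><listOfSpecies>
<species id="m1"/><species id="m2"/></listOfSpecies>
<listOfReactions>
<reaction id="R1"><listOfReactants><speciesReference species="m1"/></listOfReactants>
<geneProductAssociation><geneProductRef geneProduct="gA"/></geneProductAssociation></reaction>
<reaction id="R2"><listOfProducts><speciesReference species="m1"/>
<speciesReference species="m2"/></listOfProducts>
<geneProductAssociation><geneProductRef geneProduct="gB"/></geneProductAssociation></reaction>
</listOfReactions></model></sbml>', sbml)
  m <- read_metabolic_model(sbml, format = "sbml")
  expect_equal(m$metabolites, c("m1", "m2"))
  expect_equal(model_genes(m), c("gA", "gB"))
  net <- project_gene_network(m)
  expect_equal(nrow(net$edges), 1)  # share m1
})
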