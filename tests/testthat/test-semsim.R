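test_that("evidence filtering removes excluded codes and flags emptied genes", {
  ann <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g3"),
    term = c("T1", "T2", "T1", "T3"),
    evidence = c("EXP", "IEA", "IEA", "IPI")
  )
  out <- suppressMessages(filter_evidence(ann))
  expect_equal(out$gene, "g1")
  expect_equal(out$term, "T1")
  expect_setequal(attr(out, "flagged_genes"), c("g2", "g3"))
  expect_identical(filter_evidence(ann, excluded = character(0))$term, ann$term)
})

test_that("S-values propagate with relation weights and the max rule", {
  dag <- chain_dag()
  root_only <- svalues("R", dag)
  expect_equal(root_only, c(R = 1))
  s <- svalues("G", dag)
  expect_equal(s[c("G", "C", "R")], c(G = 1, C = 0.8, R = 0.64))
  expect_equal(sum(s), 2.44)
  # diamond-shaped DAG: two root paths, max (not sum) at the join
  dd <- diamond_shaped_dag()
  sdd <- svalues("G", dd)
  expect_equal(sdd[["R"]], 0.64)  # is_a path 0.8*0.8 beats part_of path 0.6*0.6
  expect_error(svalues("nope", dag), "not in DAG")
})

test_that("Wang term similarity reproduces the chain worked example", {
  dag <- chain_dag()
  expect_equal(term_sim_wang("G", "G", dag), 1)
  expect_equal(term_sim_wang("G", "C", dag), (0.8 + 1 + 0.64 + 0.8) / (2.44 + 1.8))
  expect_equal(term_sim_wang("G", "C", dag), term_sim_wang("C", "G", dag))
  # terms sharing only the root stay positive
  wide <- generate_toy_ontology(2, 3)
  leaves <- setdiff(wide$terms$id, wide$edges$parent)
  sim <- term_sim_wang(leaves[1], leaves[length(leaves)], wide)
  expect_gt(sim, 0)
  expect_lt(sim, 1)
})

test_that("similarity decays with ancestor distance along a chain", {
  dag <- chain_dag()
  expect_gt(term_sim_wang("G", "C", dag), term_sim_wang("G", "R", dag))
})

test_that("different namespaces refuse to be compared", {
  terms <- tibble::tibble(id = c("A", "B"), name = c("A", "B"),
                          namespace = c("biological_process", "molecular_function"))
  dag <- go_dag(terms, tibble::tibble(child = character(0), parent = character(0),
                                      relation = character(0)))
  expect_error(term_sim_wang("A", "B", dag), "namespace")
})

test_that("BMA combines row and column maxima", {
  m21 <- matrix(c(0.8, 0.4), nrow = 2)
  expect_equal(axonmod:::bma(m21), (0.8 + 0.4 + 0.8) / 3)
  expect_equal(axonmod:::bma(matrix(0.37, 1, 1)), 0.37)
  dag <- chain_dag()
  ann <- tibble::tibble(gene = c("x", "x", "y", "y"),
                        term = c("G", "C", "G", "C"),
                        evidence = "EXP")
  expect_equal(gene_sim_bma("x", "y", ann, dag), 1)  # identical term sets
  single <- tibble::tibble(gene = c("u", "v"), term = c("G", "C"), evidence = "EXP")
  expect_equal(gene_sim_bma("u", "v", single, dag), term_sim_wang("G", "C", dag))
  expect_error(gene_sim_bma("u", "ghost", single, dag), "ghost")
})

test_that("semsim matrices stay in [0,1], symmetric, with unit diagonal", {
  set.seed(17)
  for (rep in 1:5) {
    dag <- generate_toy_ontology(sample(2:4, 1), sample(2:3, 1),
                                 p_part_of = runif(1, 0, 0.5),
                                 extra_edges = sample(0:3, 1),
                                 rng_seed = rep)
    genes <- paste0("gene", 1:6)
    ann <- generate_annotations(genes, dag, rng_seed = rep)
    m <- semsim_matrix(genes, genes, ann, dag)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
  }
})

test_that("clustering separates planted similarity blocks", {
  block <- matrix(0.05, 6, 6)
  block[1:3, 1:3] <- 0.9
  block[4:6, 4:6] <- 0.9
  diag(block) <- 1
  rownames(block) <- colnames(block) <- paste0("g", 1:6)
  cl <- cluster_semsim(block, k = 2)
  expect_length(unique(cl$clusters), 2)
  expect_length(unique(cl$clusters[1:3]), 1)
  expect_length(unique(cl$clusters[4:6]), 1)
  # all-identical similarities collapse to one cluster at height 0
  ones <- matrix(1, 4, 4, dimnames = list(paste0("a", 1:4), paste0("a", 1:4)))
  expect_length(unique(cluster_semsim(ones)$clusters), 1)
  # orthogonal genes each get their own cluster
  eye <- diag(4)
  dimnames(eye) <- dimnames(ones)
  expect_length(unique(cluster_semsim(eye)$clusters), 4)
  expect_error(cluster_semsim(matrix(0, 2, 3)), "square")
})

test_that("OBO and GAF files round-trip through the readers", {
  dag <- generate_toy_ontology(3, 2, p_part_of = 0.3, rng_seed = 2)
  f <- tempfile(fileext = ".obo")
  write_obo(dag, f)
  back <- read_obo(f)
  expect_equal(back$terms$id, dag$terms$id)
  expect_equal(dplyr::arrange(back$edges, child, parent),
               dplyr::arrange(dag$edges, child, parent))
  ann <- generate_annotations(paste0("gene", 1:4), dag, rng_seed = 3)
  fg <- tempfile(fileext = ".gaf")
  write_gaf(ann, fg)
  back_ann <- read_gaf(fg)
  expect_equal(back_ann$gene, ann$gene)
  expect_equal(back_ann$term, ann$term)
  expect_equal(back_ann$evidence, ann$evidence)
})

test_that("read_obo skips obsolete terms and unsupported relationships", {
  f <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: T:2", "name: child", "namespace: biological_process",
    "is_a: T:1 ! root",
    "relationship: regulates T:1 ! root", "",
    "[Term]", "id: T:3", "name: gone", "is_obsolete: true", ""
  ), f)
  dag <- suppressMessages(read_obo(f))
  expect_equal(nrow(dag$terms), 2)
  expect_equal(nrow(dag$edges), 1)
  expect_equal(dag$roots, "T:1")
})

test_that("cyclic term graphs are rejected", {
  terms <- tibble::tibble(id = c("A", "B"), name = c("A", "B"), namespace = "bp")
  edges <- tibble::tibble(child = c("A", "B"), parent = c("B", "A"), relation = "is_a")
  expect_error(go_dag(terms, edges), "cycle")
})
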