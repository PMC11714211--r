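# Shared synthetic fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

# the standard study fixture: 1000-node scale-free net, 25-gene planted
# module, 3 planted drugs + 47 decoys, ontology, expression matrix
study_fixture <- function() {
  if (is.null(.fixture_env$study)) {
    spec <- fixture_spec(master_seed = 7)
    net <- make_interactome(spec)
    dl <- make_drug_library(net$graph, net$planted, spec)
    onto <- make_ontology_and_annotations(igraph::V(net$graph)$name,
                                          net$planted, spec)
    expr <- make_expression(igraph::V(net$graph)$name, spec)
    .fixture_env$study <- list(
      spec = spec, graph = net$graph, planted = net$planted,
      seed_gene = net$seed_gene, library = dl$library, truth = dl$truth,
      dag = onto$dag, annot = onto$annot, expression = expr,
      bins = degree_bins(net$graph),
      D = distance_matrix(net$graph))
  }
  .fixture_env$study
}

# tiny hand DAG: one root r with children a, b via is_a (w = 0.8);
# sim(a, b) = (0.8 + 0.8) / (1.8 + 1.8) = 4/9
hand_dag <- function() {
  go_dag(terms = c("r", "a", "b"),
         namespace = c(r = "BP", a = "BP", b = "BP"),
         parents = data.frame(term = c("a", "b"), parent = c("r", "r"),
                              relation = c("is_a", "is_a")))
}

path_graph <- function(nodes = c("a", "b", "c")) {
  interactome(data.frame(from = nodes[-length(nodes)], to = nodes[-1]))
}
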