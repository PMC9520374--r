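test_that("modified cosine: self-similarity, disjoint pairs, empty errors", {
  a <- toy_spectrum("a", 400, c(100, 150, 200, 250), c(5, 10, 20, 40))
  expect_equal(modified_cosine(a, a)$similarity, 1, tolerance = 1e-12)
  expect_equal(modified_cosine(a, a)$matched_peaks, 4L)
  # no pairable peaks, directly or under the precursor shift
  b <- toy_spectrum("b", 403, c(120, 170, 220), c(1, 1, 1))
  res <- modified_cosine(a, b)
  expect_equal(res$similarity, 0)
  expect_equal(res$matched_peaks, 0L)
  expect_error(modified_cosine(a, toy_spectrum("e", 100, numeric(0))),
               "empty")
})

test_that("shifted pairing connects a spectrum with its modified analogue", {
  a <- toy_spectrum("parent", 400, c(100, 150, 200), c(10, 20, 30))
  # all fragments shifted by the precursor difference -> pairs only via shift
  b <- toy_spectrum("child", 562.052824,
                    c(100, 150, 200) + 162.052824, c(10, 20, 30))
  res <- modified_cosine(a, b)
  expect_equal(res$similarity, 1, tolerance = 1e-12)
  expect_equal(res$matched_peaks, 3L)
})

test_that("optimal assignment equals the brute-force oracle on toy spectra", {
  # deliberately ambiguous 3-peak pair: one a-peak has two candidates
  a <- toy_spectrum("a", 300, c(100.000, 100.015, 210.0), c(50, 60, 70))
  b <- toy_spectrum("b", 300.005, c(100.005, 100.020, 209.99), c(55, 45, 80))
  expect_equal(modified_cosine(a, b)$similarity, brute_modified_cosine(a, b),
               tolerance = 1e-12)
  set.seed(91)
  for (k in 1:40) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    base <- runif(1, 200, 600)
    x <- random_spectrum("x", na, precursor = base)
    y <- random_spectrum("y", nb, precursor = base + runif(1, -30, 30),
                         near = x$peaks$mz)
    expect_equal(modified_cosine(x, y)$similarity, brute_modified_cosine(x, y),
                 tolerance = 1e-9)
  }
})

test_that("modified cosine is symmetric", {
  set.seed(17)
  for (k in 1:10) {
    x <- random_spectrum("x", 5)
    y <- random_spectrum("y", 6, near = x$peaks$mz)
    expect_equal(modified_cosine(x, y)$similarity,
                 modified_cosine(y, x)$similarity, tolerance = 1e-9)
  }
})

test_that("entropy similarity matches its closed-form anchors", {
  a <- toy_spectrum("a", 400, c(100, 150, 200), c(10, 20, 30))
  expect_equal(entropy_similarity(a, a), 1, tolerance = 1e-12)
  # two single-peak spectra at different m/z: S_A=S_B=0, S_AB=ln 2 -> 0
  p <- toy_spectrum("p", 300, 120, 5)
  q <- toy_spectrum("q", 310, 180, 7)
  expect_equal(entropy_similarity(p, q), 0, tolerance = 1e-12)
  # symmetric and bounded on random pairs
  set.seed(23)
  for (k in 1:10) {
    x <- random_spectrum("x", 6)
    y <- random_spectrum("y", 7, near = x$peaks$mz)
    sxy <- entropy_similarity(x, y)
    expect_equal(sxy, entropy_similarity(y, x), tolerance = 1e-12)
    expect_gte(sxy, 0); expect_lte(sxy, 1)
  }
})

test_that("build_network forms edges above threshold with enough matches", {
  a <- toy_spectrum("a", 400, c(100, 120, 140, 160, 180, 200, 220, 240),
                    rep(1000, 8))
  twin <- toy_spectrum("twin", 420, a$peaks$mz, a$peaks$intensity)
  net <- build_network(list(a, twin), threshold = 0.7, min_matched = 6)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(length(unique(net$components)), 1L)
  # sharing only 3 fragments: matched_peaks < 6 -> no edge
  few <- toy_spectrum("few", 440, c(a$peaks$mz[1:3], 301, 321, 341, 361, 381),
                      rep(1000, 8))
  net2 <- build_network(list(a, few), threshold = 0.7, min_matched = 6)
  expect_equal(nrow(net2$edges), 0L)
  expect_equal(length(unique(net2$components)), 2L)
})

test_that("near-duplicate nodes are absorbed by precursor tolerance", {
  a <- toy_spectrum("a", 400.0000, c(100, 150, 200, 250, 300, 350),
                    rep(1000, 6))
  dup <- toy_spectrum("dup", 400.005, a$peaks$mz, a$peaks$intensity * 2)
  far <- toy_spectrum("far", 400.5, a$peaks$mz, a$peaks$intensity)
  net <- build_network(list(a, dup, far), threshold = 0.7, min_matched = 6)
  expect_false("a" %in% net$nodes$id)       # lower-intensity twin absorbed
  expect_true(all(c("dup", "far") %in% net$nodes$id))
  expect_equal(unname(net$merged["a"]), "dup")
})

test_that("degree and component caps hold by construction", {
  # 14 spectra sharing one 8-peak skeleton -> dense similarity graph
  set.seed(31)
  skel <- sort(runif(8, 60, 180))
  sps <- lapply(1:14, function(i)
    toy_spectrum(sprintf("n%02d", i), 200 + 7 * i, skel, runif(8, 500, 1500)))
  net <- build_network(sps, threshold = 0.5, min_matched = 6,
                       max_neighbors = 3, max_component = 5)
  deg <- network_degrees(net)
  expect_true(all(deg <= 3))
  expect_true(all(table(net$components) <= 5))
  # membership really is the connected components of the edge set
  recomputed <- pathprobe:::compute_components(net$nodes$id, net$edges)
  expect_identical(net$components, recomputed[names(net$components)])
})

test_that("pathway-cluster filtering implements the qualification rule", {
  reg <- default_registry()
  base <- c(100, 120, 140, 160, 180, 200, 220, 240)
  probe <- toy_spectrum("probe_A", 400, base, rep(1000, 8))
  # modified metabolite connected to the probe, carrying a generic hit
  methox <- reg$mass[reg$name == "Methoxylation"]
  modsp <- toy_spectrum("mod_A", 400 + methox, c(base, 400), rep(1000, 9))
  # isolated pair carrying a pathway-specific alcohol-conjugation hit
  conif <- reg$mass[reg$name == "Non-condensed coniferyl alcohol"]
  spec1 <- toy_spectrum("spec_1", 700, c(300, 320, 340, 360, 380, 390, 700 - conif),
                        rep(1000, 7))
  spec2 <- toy_spectrum("spec_2", 700 + 14.01565, spec1$peaks$mz, rep(1000, 7))
  # lone probe component
  lone <- toy_spectrum("probe_lone", 555, c(70, 80, 90, 95, 105, 115),
                       rep(1000, 6))
  hits <- list(
    mod_A = detect_modifications(modsp, reg),
    spec_1 = detect_modifications(spec1, reg))
  net <- build_network(list(modsp, spec1, spec2),
                       probes = list(probe, lone), hits = hits)
  clusters <- filter_pathway_clusters(net, modified_ids = c("mod_A", "spec_1"),
                                      registry = reg)
  quals <- vapply(clusters, `[[`, character(1), "qualification")
  members <- lapply(clusters, `[[`, "members")
  expect_length(clusters, 2L)
  expect_true(any(quals == "probe+modified" &
                    vapply(members, function(m) "probe_A" %in% m, logical(1))))
  spec_cl <- clusters[[which(quals == "specific-modification-only")]]
  expect_setequal(spec_cl$members, c("spec_1", "spec_2"))
  expect_true("Non-condensed coniferyl alcohol" %in%
                spec_cl$specific_modifications)
  # the lone probe component never qualifies
  expect_false(any(vapply(members, function(m)
    identical(m, "probe_lone"), logical(1))))
})

test_that("adding a probe to a component never removes qualification", {
  reg <- default_registry()
  conif <- reg$mass[reg$name == "Non-condensed coniferyl alcohol"]
  base <- c(300, 320, 340, 360, 380, 390)
  s1 <- toy_spectrum("s1", 700, c(base, 700 - conif), rep(1000, 7))
  s2 <- toy_spectrum("s2", 714.01565, s1$peaks$mz, rep(1000, 7))
  hits <- list(s1 = detect_modifications(s1, reg))
  without <- build_network(list(s1, s2), hits = hits)
  with_probe <- build_network(list(s1, s2),
                              probes = list(toy_spectrum("p", 707,
                                                         s1$peaks$mz,
                                                         rep(1000, 7))),
                              hits = hits)
  q1 <- filter_pathway_clusters(without, c("s1"), reg)
  q2 <- filter_pathway_clusters(with_probe, c("s1"), reg)
  in_cluster <- function(cl, id) any(vapply(cl, function(c)
    id %in% c$members, logical(1)))
  expect_true(in_cluster(q1, "s1"))
  expect_true(in_cluster(q2, "s1"))
})

test_that("GraphML export writes a Cytoscape-readable graph", {
  w <- synthetic_world()
  scr <- screen_modified_metabolome(w$dataset$features, w$dataset$spectra,
                                    w$registry)
  net <- build_network(lapply(scr$metabolites[1:10], `[[`, "spectrum"),
                       probes = w$probes)
  tmp <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_graphml(net, tmp, edge_tsv = tsv)
  g <- igraph::read_graph(tmp, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$kind, unique(net$nodes$kind))
  edges_back <- utils::read.delim(tsv)
  expect_equal(nrow(edges_back), nrow(net$edges))
})
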