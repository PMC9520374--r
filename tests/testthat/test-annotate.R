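test_that("library_match ranks identical spectra first and gates on precursor", {
  w <- synthetic_world()
  lib <- w$probes
  query <- lib$records[[3]]$spectrum
  hits <- library_match(query, lib)
  expect_equal(hits$probe_id[1], query$id)
  expect_equal(hits$similarity[1], 1, tolerance = 1e-9)
  # 50 ppm precursor offset excludes the record regardless of similarity
  off <- msms_spectrum("off", query$precursor_mz * (1 + 50e-6), query$peaks,
                       polarity = query$polarity)
  expect_false(query$id %in% library_match(off, lib)$probe_id)
  # a modified derivative (shifted precursor) finds no library hit
  deriv <- msms_spectrum("deriv", query$precursor_mz + 162.052824,
                         query$peaks, polarity = query$polarity)
  expect_equal(nrow(library_match(deriv, lib)), 0L)
  # polarity mismatch is an error
  neg <- msms_spectrum("neg", query$precursor_mz, query$peaks,
                       polarity = "negative")
  expect_error(library_match(neg, lib), "polarity")
})

test_that("propagation reproduces the methoxylation worked example", {
  reg <- default_registry()
  base <- c(151.04, 265.07, 341.1012, 405.1, 523.16, 535.18)
  seedsp <- toy_spectrum("seed_probe", 667.2180, base, rep(1000, 6),
                         polarity = "positive")
  neigh <- toy_spectrum("node_697", 697.2286, c(base, 551.1929),
                        rep(1000, 7), polarity = "positive")
  net <- build_network(list(neigh), probes = list(seedsp))
  expect_equal(nrow(net$edges), 1L)
  ev <- propagate(net, "seed_probe", reg, tol_ppm = 15)
  e <- ev[[which(vapply(ev, `[[`, character(1), "node") == "node_697")]]
  expect_equal(e$status, "propagated")
  expect_equal(e$seed, "seed_probe")
  expect_equal(e$depth, 1L)
  expect_equal(e$chain$modification, "Methoxylation")
  expect_equal(e$chain$direction, "gain")
  expect_equal(e$chain$observed_delta, 697.2286 - 667.2180, tolerance = 1e-9)
  # corroborated: the neighbor's own MS/MS contains the coumaroyl loss, and
  # the methoxylation delta is not required for corroboration of itself here
  expect_true(is.logical(e$chain$corroborated))
})

test_that("two-step chains are recovered at depth 2 with the mass-sum invariant", {
  reg <- default_registry()
  hex <- reg$mass[reg$name == "Hexosylation"]
  mal <- reg$mass[reg$name == "Malonyl"]
  base <- c(120.05, 180.08, 240.11, 300.14, 360.17, 420.2)
  p <- toy_spectrum("probe_x", 500.25, base, rep(1000, 6))
  step1 <- toy_spectrum("step1", 500.25 + hex, c(base, 500.25), rep(1000, 7))
  step2 <- toy_spectrum("step2", 500.25 + hex + mal,
                        c(base, 500.25 + hex), rep(1000, 7))
  net <- build_network(list(step1, step2), probes = list(p))
  ev <- propagate(net, "probe_x", reg, tol_ppm = 15, max_depth = 3)
  by_node <- stats::setNames(ev, vapply(ev, `[[`, character(1), "node"))
  e2 <- by_node[["step2"]]
  expect_equal(e2$status, "propagated")
  expect_equal(e2$depth, 2L)
  expect_equal(e2$chain$modification, c("Hexosylation", "Malonyl"))
  expect_equal(e2$chain$direction, c("gain", "gain"))
  # signed chain-mass sum reproduces the precursor difference from the seed
  resid <- abs((500.25 + hex + mal) - 500.25 - chain_mass_sum(e2$chain))
  expect_lt(resid, 15e-6 * (hex + mal) + 1e-9)
  # depth cap: max_depth = 1 leaves step2 unannotated
  ev1 <- propagate(net, "probe_x", reg, max_depth = 1)
  st <- vapply(ev1, `[[`, character(1), "status")
  names(st) <- vapply(ev1, `[[`, character(1), "node")
  expect_equal(unname(st["step2"]), "unannotated")
})

test_that("a neighbor whose delta matches nothing stays unannotated", {
  reg <- default_registry()
  base <- c(100, 150, 200, 250, 300, 350)
  p <- toy_spectrum("p", 400, base, rep(1000, 6))
  odd <- toy_spectrum("odd", 400 + 3.333, base, rep(1000, 6))
  net <- build_network(list(odd), probes = list(p))
  expect_equal(nrow(net$edges), 1L)
  ev <- propagate(net, "p", reg)
  st <- stats::setNames(vapply(ev, `[[`, character(1), "status"),
                        vapply(ev, `[[`, character(1), "node"))
  expect_equal(unname(st["odd"]), "unannotated")
})

test_that("propagation is deterministic under competing seeds", {
  reg <- default_registry()
  hex <- reg$mass[reg$name == "Hexosylation"]
  base <- c(110, 160, 210, 260, 310, 360)
  pa <- toy_spectrum("probe_a", 420, base, rep(1000, 6))
  pb <- toy_spectrum("probe_b", 420, base, rep(1000, 6))
  # same precursor would deduplicate; nudge outside the merge tolerance
  pb$precursor_mz <- 420.02
  target <- toy_spectrum("target", 420 + hex, c(base, 420), rep(1000, 7))
  ev <- replicate(3, {
    net <- build_network(list(target), probes = list(pa, pb))
    e <- propagate(net, c("probe_a", "probe_b"), reg)
    e[[which(vapply(e, `[[`, character(1), "node") == "target")]]$seed
  })
  expect_true(all(ev == ev[1]))
})

test_that("annotate_fragments explains the dadahol A spectrum", {
  reg <- default_registry()
  sp <- toy_spectrum("dadahol", 697.2286,
                     c(163.039, 341.1012, 551.1929), c(300, 800, 1000),
                     polarity = "positive")
  fa <- annotate_fragments(sp, reg, tol_ppm = 15)
  cou <- fa[fa$assigned == "Coumaryl" & fa$kind == "neutral-loss" &
              fa$ion1 == 697.2286, ]
  expect_gte(nrow(cou), 1L)
  sin <- fa[fa$assigned == "Non-condensed sinapyl alcohol" &
              fa$ion1 == 551.1929 & fa$ion2 == 341.1012, ]
  expect_equal(nrow(sin), 1L)
  expect_equal(sin$adjustment, "0")
  expect_equal(sin$observed_delta, 551.1929 - 341.1012, tolerance = 1e-9)
  # no assignment ever exceeds the tolerance after adjustment
  expect_true(all(abs(fa$ppm_error) <= 15))
})

test_that("annotate_fragments flags -2H matches and characteristic ions", {
  reg <- default_registry()
  ions <- load_characteristic_ions()
  sp <- toy_spectrum("lignan", 551.1915, c(163.0377, 371.1112), c(500, 800),
                     polarity = "negative")
  fa <- annotate_fragments(sp, reg, ions, tol_ppm = 15,
                           allow_h2_adjustment = TRUE)
  conif <- fa[fa$assigned == "Non-condensed coniferyl alcohol" &
                fa$ion1 == 551.1915, ]
  expect_equal(nrow(conif), 1L)
  sinap <- fa[fa$assigned == "Non-condensed sinapyl alcohol", ]
  expect_equal(sinap$adjustment, "-2H")
  expect_equal(sinap$ion1, 371.1112)
  expect_equal(sinap$ion2, 163.0377)
  ci <- fa[fa$kind == "characteristic-ion", ]
  expect_true("coumaric acid" %in% ci$assigned)
  # single far-from-everything fragment -> no assignment
  bare <- toy_spectrum("bare", 1200.777, 1100.333, 1000)
  expect_equal(nrow(annotate_fragments(bare, reg, ions)), 0L)
})

test_that("de-novo annotation recovers planted compositions", {
  reg <- default_registry()
  conif <- reg$mass[reg$name == "Non-condensed coniferyl alcohol"]
  hex <- reg$mass[reg$name == "Hexosylation"]
  prec <- conif + hex
  sp <- toy_spectrum("built2", prec, c(prec - conif, prec - hex),
                     c(900, 900), polarity = "positive")
  other <- toy_spectrum("other", prec + 14.01565, sp$peaks$mz + 0.5,
                        c(900, 900), polarity = "positive")
  net <- build_network(list(sp, other), min_matched = 1, threshold = 0)
  cl <- structure(list(component = "built2", members = c("built2", "other"),
                       qualification = "specific-modification-only",
                       probes = character(0),
                       specific_modifications = "Non-condensed coniferyl alcohol"),
                  class = "pathway_cluster")
  ev <- de_novo_annotate(cl, net, reg, tol_ppm = 15)
  e <- ev[[which(vapply(ev, `[[`, character(1), "node") == "built2")]]
  expect_equal(e$status, "de-novo")
  comps <- lapply(e$composition, sort)
  expect_true(list(sort(c("Hexosylation", "Non-condensed coniferyl alcohol")))
              %in% comps ||
                any(vapply(comps, function(cp)
                  setequal(cp, c("Hexosylation",
                                 "Non-condensed coniferyl alcohol")),
                  logical(1))))
  # a node with no assignments gets empty composition, not an error
  e2 <- ev[[which(vapply(ev, `[[`, character(1), "node") == "other")]]
  expect_equal(e2$status, "de-novo")
})

test_that("export_annotations round-trips the evidence table", {
  reg <- default_registry()
  base <- c(100, 150, 200, 250, 300, 350)
  p <- toy_spectrum("p", 400, base, rep(1000, 6))
  hexd <- toy_spectrum("hexd", 400 + 162.052824, c(base, 400), rep(1000, 7))
  net <- build_network(list(hexd), probes = list(p))
  ev <- propagate(net, "p", reg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_annotations(ev, net, tsv, graphml = gml)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), length(ev))
  expect_equal(sort(table(back$status), decreasing = TRUE),
               sort(table(vapply(ev, `[[`, character(1), "status")),
                    decreasing = TRUE))
  expect_true(file.exists(gml))
})
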