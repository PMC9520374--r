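test_that("feature/MS2 matching honours both windows and picks closest RT", {
  features <- data.frame(id = "F1", mz = 300.1000, rt = 120, intensity = 1e4)
  in_both <- list(toy_spectrum("s1", 300.1001, c(100, 200), rt = 125))
  out_rt <- list(toy_spectrum("s2", 300.1001, c(100, 200), rt = 140))
  expect_equal(match_features_to_msms(features, in_both)$pairs$spectrum_id, "s1")
  res <- match_features_to_msms(features, out_rt)
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(res$unmatched, "F1")
  # several spectra in window: closest RT wins, tie broken by closest m/z
  multi <- list(toy_spectrum("far", 300.1001, c(100), rt = 130),
                toy_spectrum("near", 300.1020, c(100), rt = 121),
                toy_spectrum("tie_worse_mz", 300.1030, c(100), rt = 121))
  expect_equal(match_features_to_msms(features, multi)$pairs$spectrum_id, "near")
})

test_that("detect_modifications reproduces the coumaroyl-loss reading", {
  reg <- default_registry()
  sp <- toy_spectrum("dadahol", 697.2286, c(341.1012, 551.1929),
                     c(800, 1000), polarity = "positive")
  hits <- detect_modifications(sp, reg, tol_ppm = 15,
                               min_fragment_intensity = 100)
  cou <- hits[hits$modification == "Coumaryl", ]
  expect_equal(nrow(cou), 1L)
  expect_equal(cou$observed_delta, 697.2286 - 551.1929, tolerance = 1e-9)
  expect_equal(cou$ion2, 551.1929)
  expect_lt(abs(cou$ppm_error), 15)
})

test_that("detect_modifications enforces the intensity floor and tolerance", {
  reg <- default_registry()
  # same fragment below the floor never yields a hit
  lo <- toy_spectrum("lo", 697.2286, 551.1929, 99)
  expect_equal(nrow(detect_modifications(lo, reg)), 0L)
  # every precursor-fragment delta below the smallest registry mass -> empty
  tiny <- toy_spectrum("tiny", 100.05, c(95.0, 98.0), c(500, 500))
  expect_equal(nrow(detect_modifications(tiny, reg)), 0L)
  expect_error(detect_modifications(toy_spectrum("e", 100, numeric(0)), reg),
               "no peaks")
})

test_that("fragment-fragment deltas are opt-in", {
  reg <- default_registry()
  sp <- toy_spectrum("ff", 900, c(341.1012, 551.1929), c(800, 1000))
  default_hits <- detect_modifications(sp, reg)
  expect_false("fragment-fragment" %in% default_hits$delta_kind)
  both <- detect_modifications(sp, reg,
                               delta_kinds = c("precursor-fragment",
                                               "fragment-fragment"))
  ff <- both[both$delta_kind == "fragment-fragment", ]
  expect_true("Non-condensed sinapyl alcohol" %in% ff$modification)
})

test_that("ion fusion merges within both windows and is idempotent", {
  reg <- default_registry()
  mk <- function(id, mz, rt, inten) {
    sp <- toy_spectrum(id, mz, mz - 146.03678, 1000, rt = rt)
    feat <- data.frame(id = id, mz = mz, rt = rt, intensity = inten)
    pathprobe:::modified_metabolite(feat, sp, detect_modifications(sp, reg))
  }
  close_pair <- list(mk("a", 300.1000, 120, 5e3), mk("b", 300.1002, 125, 8e3))
  fused <- fuse_ions(close_pair)
  expect_length(fused, 1L)
  expect_equal(fused[[1]]$feature$id, "b")  # highest intensity representative
  expect_setequal(fused[[1]]$fused_from, c("a", "b"))
  expect_length(fuse_ions(fused), 1L)       # idempotent
  # 50 ppm apart -> no fusion
  far_pair <- list(mk("a", 300.1000, 120, 5e3), mk("b", 300.1150, 121, 8e3))
  expect_length(fuse_ions(far_pair), 2L)
})

test_that("screening recovers a zero-noise synthetic world exactly", {
  w <- synthetic_world()
  scr <- screen_modified_metabolome(w$dataset$features, w$dataset$spectra,
                                    w$registry)
  expect_equal(length(scr$metabolites), nrow(w$dataset$features))
  # every planted (derivative, modification) pair is recovered by name
  truth <- w$dataset$truth$derivatives
  hit_names <- stats::setNames(
    lapply(scr$metabolites, function(m) m$hits$modification),
    vapply(scr$metabolites, function(m) m$spectrum$id, character(1)))
  for (i in seq_len(nrow(truth)))
    for (mod in strsplit(truth$chain[i], ";")[[1]])
      expect_true(mod %in% hit_names[[truth$id[i]]])
  expect_equal(scr$summary$n_with_hits, 50L)
  expect_equal(scr$summary$n_fused, 50L)
})

test_that("a dataset without planted losses screens to nothing", {
  set.seed(5)
  reg <- default_registry()
  sps <- lapply(1:5, function(i)
    toy_spectrum(sprintf("n%d", i), 500 + i,
                 c(60.01, 70.02, 80.03) + i * 0.111, rep(1000, 3),
                 rt = 100 * i))
  feats <- data.frame(id = sprintf("n%d", 1:5),
                      mz = 500 + 1:5, rt = 100 * (1:5), intensity = 1000)
  scr <- screen_modified_metabolome(feats, sps, reg)
  expect_length(scr$metabolites, 0L)
})

test_that("metabolites with two modifications count in the multi-type fraction", {
  reg <- default_registry()
  hex <- reg$mass[reg$name == "Hexosylation"]
  mal <- reg$mass[reg$name == "Malonyl"]
  sp <- toy_spectrum("two", 700, c(700 - hex, 700 - mal), c(1000, 1000),
                     rt = 100)
  feats <- data.frame(id = "two", mz = 700, rt = 100, intensity = 1000)
  scr <- screen_modified_metabolome(feats, list(sp), reg)
  expect_equal(scr$summary$frac_multi_type, 1)
  expect_gte(scr$summary$n_types_observed, 2L)
})
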