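# Synthetic probe libraries and modified-metabolome datasets with ground truth.

.PHENYLPROPANOID_SUBCLASSES <- c(
  "flavonoids", "isoflavonoids", "coumarins and derivatives",
  "cinnamic acids and derivatives", "lignans", "hydroxycinnamic acid amides")

#' Generate a synthetic probe library
#'
#' Reproducible reference spectra standing in for public-library pathway
#' compounds: distinct precursors drawn over `mz_range`, random fragment
#' peaks below the precursor, and class labels from a fixed
#' phenylpropanoid-subclass list.
#'
#' @param n Number of probe spectra.
#' @param peaks_per_spectrum Fragments per spectrum (default 12).
#' @param mz_range Precursor m/z range (default 250-800).
#' @param polarity Spectrum polarity.
#' @param rt_range Retention-time range in seconds (default 0-1500, a typical
#'   25-30 min gradient).
#' @param seed RNG seed; identical seeds give identical libraries.
#' @return A `probe_library` of `n` records with ids `probe_001`, ...
#' @export
generate_probes <- function(n, peaks_per_spectrum = 12,
                            mz_range = c(250, 800),
                            polarity = c("positive", "negative"),
                            rt_range = c(0, 1500), seed = 1) {
  polarity <- match.arg(polarity)
  stopifnot(n >= 0, peaks_per_spectrum >= 1)
  set.seed(seed)
  records <- vector("list", n)
  precursors <- numeric(0)
  for (i in seq_len(n)) {
    repeat {
      prec <- stats::runif(1, mz_range[1], mz_range[2])
      if (!length(precursors) || min(abs(precursors - prec)) > 0.5) break
    }
    precursors <- c(precursors, prec)
    frag_mz <- sort(stats::runif(peaks_per_spectrum, 50, prec - 20))
    frag_int <- round(stats::runif(peaks_per_spectrum, 500, 10000))
    id <- sprintf("probe_%03d", i)
    sp <- msms_spectrum(id, prec,
                        data.frame(mz = frag_mz, intensity = frag_int),
                        rt = stats::runif(1, rt_range[1], rt_range[2]),
                        polarity = polarity)
    records[[i]] <- list(
      spectrum = sp, compound_name = sprintf("synthetic compound %03d", i),
      chemical_class = sample(.PHENYLPROPANOID_SUBCLASSES, 1),
      instrument = "synthetic-TOF", library_source = "synthetic")
  }
  structure(list(records = records, polarity = polarity,
                 class_counts = if (n) table(vapply(records, `[[`, character(1),
                                                    "chemical_class"))
                                else table(character(0)),
                 instrument_counts = if (n) table(rep("synthetic-TOF", n))
                                     else table(character(0)),
                 n_dropped_no_class = 0L),
            class = "probe_library")
}

#' Derive a synthetic modified metabolome from probes
#'
#' Each derivative takes a parent probe, gains a chain of modifications drawn
#' from the registry (precursor = parent + sum of modification masses), keeps
#' a stated fraction of the parent's fragments (so modified cosine connects
#' parent and derivative through direct and shifted pairs), and carries one
#' planted fragment at `precursor - mass` per chain modification so the
#' neutral loss is detectable. Planted masses are exact to < 1e-6 Da; jitter
#' belongs to [add_noise()].
#'
#' @param probes A `probe_library` (e.g. from [generate_probes()]).
#' @param registry A `modification_registry` to draw modifications from.
#' @param n_derived Number of derivatives.
#' @param steps_distribution Named numeric vector of probabilities over chain
#'   lengths, e.g. `c("1" = 1)` (default: all single-step). `"0"` produces an
#'   unmodified copy of the parent.
#' @param shared_fragment_fraction Fraction of parent fragments retained
#'   (default 0.8; >= 6/peaks to guarantee network connectivity at the default
#'   matched-peak minimum).
#' @param rt_offset_s Max |RT offset| of a derivative from its parent.
#' @param seed RNG seed.
#' @return List with `spectra` (list of [msms_spectrum], ids `mod_001`, ...),
#'   `features` (data.frame `id`, `mz`, `rt`, `intensity`, one row per
#'   derivative; `id` equals the spectrum id), and `truth` (list:
#'   `derivatives` data.frame with parent, chain string, planted fragment
#'   m/z; `per_type` counts).
#' @export
derive_modified <- function(probes, registry, n_derived = 50,
                            steps_distribution = c("1" = 1),
                            shared_fragment_fraction = 0.8,
                            rt_offset_s = 60, seed = 1) {
  stopifnot(inherits(probes, "probe_library"), n_derived >= 0,
            shared_fragment_fraction >= 0, shared_fragment_fraction <= 1)
  set.seed(seed + 1L)
  sps <- probe_spectra(probes)
  if (!length(sps) && n_derived > 0) stop("cannot derive from an empty probe library")
  spectra <- vector("list", n_derived)
  rows <- vector("list", n_derived)
  truth_rows <- vector("list", n_derived)
  steps_k <- as.integer(names(steps_distribution))
  seen_combo <- character(0)
  for (d in seq_len(n_derived)) {
    parent <- sps[[((d - 1L) %% length(sps)) + 1L]]
    k <- if (length(steps_k) == 1L) steps_k
         else sample(steps_k, 1, prob = steps_distribution)
    # a parent + chain combination is one metabolite; never emit it twice
    for (try in 1:100) {
      mods <- if (k > 0) registry[sample(nrow(registry), k, replace = TRUE), ,
                                  drop = FALSE] else registry[0, ]
      combo <- paste(parent$id, paste(sort(mods$name), collapse = ";"))
      if (k == 0 || !combo %in% seen_combo) break
    }
    seen_combo <- c(seen_combo, combo)
    prec <- parent$precursor_mz + sum(mods$mass)
    n_keep <- min(nrow(parent$peaks),
                  ceiling(shared_fragment_fraction * nrow(parent$peaks)))
    keep_idx <- if (n_keep > 0)
      order(-parent$peaks$intensity)[seq_len(n_keep)] else integer(0)
    frag <- parent$peaks[keep_idx, , drop = FALSE]
    # planted neutral-loss fragments: loss of each chain modification from the
    # derivative precursor (exact masses; detectable at arbitrarily tight ppm)
    planted <- if (k > 0) prec - mods$mass else numeric(0)
    planted <- planted[planted > 50]
    if (length(planted))
      frag <- rbind(frag, data.frame(mz = planted,
                                     intensity = rep(2000, length(planted))))
    id <- sprintf("mod_%03d", d)
    rt <- max(0, parent$rt + stats::runif(1, -rt_offset_s, rt_offset_s))
    sp <- msms_spectrum(id, prec, frag, rt = rt, polarity = parent$polarity)
    spectra[[d]] <- sp
    rows[[d]] <- data.frame(id = id, mz = prec, rt = rt,
                            intensity = max(sp$peaks$intensity),
                            stringsAsFactors = FALSE)
    truth_rows[[d]] <- data.frame(
      id = id, parent = parent$id, n_steps = k,
      chain = paste(mods$name, collapse = ";"),
      chain_mass = sum(mods$mass),
      planted_fragments = paste(sprintf("%.6f", planted), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  truth_df <- do.call(rbind, truth_rows)
  if (is.null(truth_df))
    truth_df <- data.frame(id = character(0), parent = character(0),
                           n_steps = integer(0), chain = character(0),
                           chain_mass = numeric(0),
                           planted_fragments = character(0))
  all_mods <- unlist(strsplit(truth_df$chain[truth_df$chain != ""], ";",
                              fixed = TRUE))
  features <- do.call(rbind, rows)
  if (is.null(features))
    features <- data.frame(id = character(0), mz = numeric(0), rt = numeric(0),
                           intensity = numeric(0))
  list(spectra = spectra, features = features,
       truth = list(derivatives = truth_df,
                    per_type = if (length(all_mods)) table(all_mods)
                               else table(character(0))))
}

#' Perturb a synthetic dataset with noise
#'
#' Adds reproducible noise to a [derive_modified()] dataset: random noise
#' peaks per spectrum, a per-spectrum systematic m/z calibration offset (drawn
#' uniformly within `mz_jitter_ppm`, applied multiplicatively to the precursor
#' and every fragment, so within-spectrum mass differences keep only ~ppm
#' errors of the difference — the behaviour of real calibration drift), an
#' independent m/z offset and RT jitter for the MS1 feature rows, and optional
#' decoy features/spectra carrying no planted losses. With all rates zero the
#' dataset is returned unchanged.
#'
#' @param dataset List as returned by [derive_modified()].
#' @param noise_peak_rate Noise peaks added per spectrum, as a fraction of its
#'   peak count (default 0.1).
#' @param mz_jitter_ppm Max |systematic m/z offset| in ppm (default 5).
#' @param rt_jitter_s Max |RT jitter| of feature rows in seconds (default 2).
#' @param decoy_feature_count Number of decoy feature+spectrum pairs appended.
#' @param seed RNG seed.
#' @return Perturbed dataset; `truth` gains `noise` bookkeeping (per-spectrum
#'   noise-peak m/z, applied ppm offsets, decoy ids).
#' @export
add_noise <- function(dataset, noise_peak_rate = 0.1, mz_jitter_ppm = 5,
                      rt_jitter_s = 2, decoy_feature_count = 0, seed = 1) {
  stopifnot(noise_peak_rate >= 0, mz_jitter_ppm >= 0, rt_jitter_s >= 0,
            decoy_feature_count >= 0)
  if (noise_peak_rate == 0 && mz_jitter_ppm == 0 && rt_jitter_s == 0 &&
      decoy_feature_count == 0) return(dataset)
  set.seed(seed + 2L)
  spectra <- dataset$spectra
  features <- dataset$features
  noise_log <- list()
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    offset_ppm <- stats::runif(1, -mz_jitter_ppm, mz_jitter_ppm)
    fac <- 1 + offset_ppm * 1e-6
    pk <- sp$peaks
    pk$mz <- pk$mz * fac
    n_noise <- round(noise_peak_rate * nrow(pk))
    noise_mz <- numeric(0)
    if (n_noise > 0) {
      noise_mz <- stats::runif(n_noise, 50, sp$precursor_mz * fac - 1)
      pk <- rbind(pk, data.frame(mz = noise_mz,
                                 intensity = round(stats::runif(n_noise, 100, 3000))))
    }
    spectra[[i]] <- msms_spectrum(sp$id, sp$precursor_mz * fac, pk, rt = sp$rt,
                                  polarity = sp$polarity)
    noise_log[[sp$id]] <- list(offset_ppm = offset_ppm, noise_mz = noise_mz)
  }
  if (nrow(features)) {
    feat_offset <- stats::runif(nrow(features), -mz_jitter_ppm, mz_jitter_ppm)
    features$mz <- features$mz * (1 + feat_offset * 1e-6)
    features$rt <- pmax(0, features$rt +
                          stats::runif(nrow(features), -rt_jitter_s, rt_jitter_s))
  }
  decoy_ids <- character(0)
  if (decoy_feature_count > 0) {
    pol <- if (length(spectra)) spectra[[1]]$polarity else "positive"
    for (d in seq_len(decoy_feature_count)) {
      id <- sprintf("decoy_%03d", d)
      prec <- stats::runif(1, 250, 800)
      np <- 8L
      sp <- msms_spectrum(id, prec,
                          data.frame(mz = sort(stats::runif(np, 50, prec - 20)),
                                     intensity = round(stats::runif(np, 100, 5000))),
                          rt = stats::runif(1, 0, 1500), polarity = pol)
      spectra[[length(spectra) + 1L]] <- sp
      features <- rbind(features,
                        data.frame(id = id, mz = prec, rt = sp$rt,
                                   intensity = max(sp$peaks$intensity)))
      decoy_ids <- c(decoy_ids, id)
    }
  }
  dataset$spectra <- spectra
  dataset$features <- features
  dataset$truth$noise <- list(per_spectrum = noise_log, decoys = decoy_ids,
                              noise_peak_rate = noise_peak_rate,
                              mz_jitter_ppm = mz_jitter_ppm,
                              rt_jitter_s = rt_jitter_s)
  dataset
}

#' Write a synthetic dataset to disk
#'
#' Emits `probes.mgf`, `msms.mgf`, `features.csv` and `truth.json` under
#' `out_dir` (the simulate CLI entry point).
#'
#' @param probes A `probe_library`.
#' @param dataset Output of [derive_modified()] / [add_noise()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_dataset <- function(probes, dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_mgf(lapply(probes$records, `[[`, "spectrum"),
            file.path(out_dir, "probes.mgf"))
  write_mgf(dataset$spectra, file.path(out_dir, "msms.mgf"))
  utils::write.csv(dataset$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  truth <- dataset$truth
  truth$per_type <- as.list(truth$per_type)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
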