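# Modified-metabolome screening: feature<->MS/MS matching, neutral-loss
# detection, ion fusion, summary statistics.

#' Match MS1 features to MS/MS spectra
#'
#' Pairs each feature with the acquired MS/MS spectrum whose precursor lies
#' within `tol_ppm` of the feature m/z and whose retention time lies within
#' `rt_window_s`. When several spectra qualify, the one closest in RT wins
#' (ties broken by closest m/z).
#'
#' @param features data.frame from [read_feature_table()].
#' @param spectra List of [msms_spectrum] with RT in seconds.
#' @param tol_ppm Mass accuracy window (ppm, computed on the feature m/z).
#' @param rt_window_s Retention-time window in seconds (`|dRT| <= rt_window_s`).
#' @return List with `pairs` (data.frame `feature_id`, `spectrum_id`,
#'   `ppm_error`, `rt_diff_s`) and `unmatched` (feature ids without a spectrum).
#' @export
match_features_to_msms <- function(features, spectra, tol_ppm = 15,
                                   rt_window_s = 12) {
  stopifnot(tol_ppm > 0, rt_window_s >= 0)
  sp_mz <- vapply(spectra, `[[`, numeric(1), "precursor_mz")
  sp_rt <- vapply(spectra, `[[`, numeric(1), "rt")
  sp_id <- vapply(spectra, `[[`, character(1), "id")
  pairs <- vector("list", nrow(features))
  unmatched <- character(0)
  for (i in seq_len(nrow(features))) {
    dmz <- abs(sp_mz - features$mz[i])
    drt <- abs(sp_rt - features$rt[i])
    ok <- which(dmz / features$mz[i] * 1e6 <= tol_ppm & !is.na(drt) & drt <= rt_window_s)
    if (!length(ok)) { unmatched <- c(unmatched, features$id[i]); next }
    best <- ok[order(drt[ok], dmz[ok])][1]
    pairs[[i]] <- data.frame(
      feature_id = features$id[i], spectrum_id = sp_id[best],
      ppm_error = (sp_mz[best] - features$mz[i]) / features$mz[i] * 1e6,
      rt_diff_s = sp_rt[best] - features$rt[i],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(feature_id = character(0), spectrum_id = character(0),
                        ppm_error = numeric(0), rt_diff_s = numeric(0))
  list(pairs = pairs, unmatched = unmatched)
}

#' Detect modification neutral losses in one spectrum
#'
#' Screens precursor-fragment (and optionally fragment-fragment) mass
#' differences against the modification registry. Only fragments at or above
#' the absolute intensity floor are considered; each qualifying difference
#' within `tol_ppm` of a registry mass yields one hit.
#'
#' @param spectrum An [msms_spectrum] with at least one peak.
#' @param registry A `modification_registry`.
#' @param tol_ppm Mass window in ppm (relative to the registry mass).
#' @param min_fragment_intensity Minimum absolute fragment intensity.
#' @param delta_kinds Subset of `c("precursor-fragment", "fragment-fragment")`.
#'   Fragment-fragment differences are opt-in (used during annotation, not
#'   screening).
#' @return data.frame of hits sorted by absolute ppm error: `modification`,
#'   `category`, `subcategory`, `delta_kind`, `ion1`, `ion2`, `observed_delta`,
#'   `ref_mass`, `ppm_error`, `fragment_intensity`.
#' @export
detect_modifications <- function(spectrum, registry, tol_ppm = 15,
                                 min_fragment_intensity = 100,
                                 delta_kinds = "precursor-fragment") {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  delta_kinds <- match.arg(delta_kinds,
                           c("precursor-fragment", "fragment-fragment"),
                           several.ok = TRUE)
  if (nrow(spectrum$peaks) == 0L) stop("spectrum has no peaks")
  pk <- spectrum$peaks[spectrum$peaks$intensity >= min_fragment_intensity, ,
                       drop = FALSE]
  hits <- list()
  add_hit <- function(kind, ion1, ion2, delta, inten) {
    m <- match_mass_delta(delta, registry, tol_ppm = tol_ppm)
    if (!nrow(m)) return()
    hits[[length(hits) + 1L]] <<- data.frame(
      modification = m$name, category = m$category, subcategory = m$subcategory,
      delta_kind = kind, ion1 = ion1, ion2 = ion2, observed_delta = delta,
      ref_mass = m$ref_mass, ppm_error = m$ppm_error, fragment_intensity = inten,
      stringsAsFactors = FALSE)
  }
  if ("precursor-fragment" %in% delta_kinds && nrow(pk)) {
    for (i in seq_len(nrow(pk))) {
      delta <- spectrum$precursor_mz - pk$mz[i]
      if (delta > 0) add_hit("precursor-fragment", spectrum$precursor_mz,
                             pk$mz[i], delta, pk$intensity[i])
    }
  }
  if ("fragment-fragment" %in% delta_kinds && nrow(pk) >= 2L) {
    for (i in seq_len(nrow(pk) - 1L)) for (j in (i + 1L):nrow(pk)) {
      delta <- pk$mz[j] - pk$mz[i]   # peaks sorted ascending
      if (delta > 0) add_hit("fragment-fragment", pk$mz[j], pk$mz[i], delta,
                             min(pk$intensity[i], pk$intensity[j]))
    }
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(modification = character(0), category = character(0),
                       subcategory = character(0), delta_kind = character(0),
                       ion1 = numeric(0), ion2 = numeric(0),
                       observed_delta = numeric(0), ref_mass = numeric(0),
                       ppm_error = numeric(0), fragment_intensity = numeric(0))
  hits <- hits[order(abs(hits$ppm_error), hits$modification), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Internal constructor for a screened metabolite record.
modified_metabolite <- function(feature, spectrum, hits) {
  stopifnot(nrow(hits) > 0L)
  structure(list(feature = feature, spectrum = spectrum, hits = hits),
            class = "modified_metabolite")
}

#' @export
print.modified_metabolite <- function(x, ...) {
  cat(sprintf("<modified_metabolite %s> m/z %.4f rt %.1f s, %d hit(s): %s\n",
              x$feature$id, x$feature$mz, x$feature$rt, nrow(x$hits),
              paste(unique(x$hits$modification), collapse = ", ")))
  invisible(x)
}

#' Fuse redundant ions of one metabolite
#'
#' Features arising from the same metabolite (repeat MS/MS triggers, slight
#' m/z re-estimates) are merged: members within both the ppm and RT windows of
#' each other — by single-linkage transitive closure — collapse to the
#' highest-intensity member (ties: lower m/z). Hits are unioned by
#' modification name, keeping the lowest-|ppm| evidence per name.
#'
#' @param modified List of `modified_metabolite` records.
#' @param tol_ppm m/z window in ppm (on the mean of the pair).
#' @param rt_window_s RT window in seconds.
#' @return Fused list of `modified_metabolite`, length <= input; idempotent.
#' @export
fuse_ions <- function(modified, tol_ppm = 15, rt_window_s = 12) {
  n <- length(modified)
  if (n <= 1L) return(modified)
  mz <- vapply(modified, function(m) m$feature$mz, numeric(1))
  rt <- vapply(modified, function(m) m$feature$rt, numeric(1))
  inten <- vapply(modified, function(m) m$feature$intensity, numeric(1))
  # single-linkage over the "within both windows" relation
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(rt[i] - rt[j]) <= rt_window_s &&
        abs(mz[i] - mz[j]) / ((mz[i] + mz[j]) / 2) * 1e6 <= tol_ppm) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in sort(unique(roots))) {
    members <- which(roots == r)
    rep <- members[order(-inten[members], mz[members])][1]
    hits <- do.call(rbind, lapply(modified[members], `[[`, "hits"))
    hits <- hits[order(abs(hits$ppm_error)), , drop = FALSE]
    hits <- hits[!duplicated(hits$modification), , drop = FALSE]
    hits <- hits[order(abs(hits$ppm_error), hits$modification), , drop = FALSE]
    rownames(hits) <- NULL
    m <- modified[[rep]]
    m$hits <- hits
    m$fused_from <- vapply(modified[members], function(x) x$feature$id, character(1))
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Screen the modified metabolome
#'
#' Full screening pipeline: match features to MS/MS, detect modification
#' neutral losses, keep features with at least one hit, fuse redundant ions,
#' and summarize per-modification-type statistics.
#'
#' @param features data.frame of MS1 features.
#' @param spectra List of [msms_spectrum].
#' @param registry A `modification_registry`.
#' @param tol_ppm,rt_window_s,min_fragment_intensity Screening parameters
#'   (defaults: 15 ppm, 12 s, absolute intensity 100).
#' @param delta_kinds Passed to [detect_modifications()].
#' @return List with `metabolites` (fused `modified_metabolite` list) and
#'   `summary`: counts per modification type, number of distinct types
#'   observed, fraction of metabolites carrying >= 2 distinct types, and
#'   funnel counts (`n_features`, `n_matched`, `n_with_hits`, `n_fused`).
#' @export
screen_modified_metabolome <- function(features, spectra, registry,
                                       tol_ppm = 15, rt_window_s = 12,
                                       min_fragment_intensity = 100,
                                       delta_kinds = "precursor-fragment") {
  matched <- match_features_to_msms(features, spectra, tol_ppm, rt_window_s)
  sp_by_id <- stats::setNames(spectra, vapply(spectra, `[[`, character(1), "id"))
  modified <- list()
  for (k in seq_len(nrow(matched$pairs))) {
    fid <- matched$pairs$feature_id[k]
    sp <- sp_by_id[[matched$pairs$spectrum_id[k]]]
    if (nrow(sp$peaks) == 0L) next
    hits <- detect_modifications(sp, registry, tol_ppm, min_fragment_intensity,
                                 delta_kinds)
    if (nrow(hits) == 0L) next
    feat <- features[features$id == fid, , drop = FALSE][1, ]
    modified[[length(modified) + 1L]] <- modified_metabolite(feat, sp, hits)
  }
  n_with_hits <- length(modified)
  fused <- fuse_ions(modified, tol_ppm, rt_window_s)
  types_per_met <- lapply(fused, function(m) unique(m$hits$modification))
  all_types <- unlist(types_per_met)
  per_type <- if (length(all_types)) as.list(table(all_types)) else list()
  n_multi <- sum(vapply(types_per_met, length, integer(1)) >= 2L)
  summary <- list(
    n_features = nrow(features),
    n_matched = nrow(matched$pairs),
    n_with_hits = n_with_hits,
    n_fused = length(fused),
    per_type_counts = per_type,
    n_types_observed = length(unique(all_types)),
    frac_multi_type = if (length(fused)) n_multi / length(fused) else 0,
    unmatched_features = matched$unmatched
  )
  list(metabolites = fused, summary = summary)
}

#' Tabulate screened metabolites (one row per metabolite-hit)
#'
#' @param metabolites List of `modified_metabolite`.
#' @return data.frame suitable for TSV export.
#' @export
modified_metabolome_table <- function(metabolites) {
  rows <- lapply(metabolites, function(m) {
    data.frame(feature_id = m$feature$id, mz = m$feature$mz, rt = m$feature$rt,
               intensity = m$feature$intensity, spectrum_id = m$spectrum$id,
               m$hits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(feature_id = character(0), mz = numeric(0), rt = numeric(0),
                      intensity = numeric(0), spectrum_id = character(0))
  rownames(out) <- NULL
  out
}
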