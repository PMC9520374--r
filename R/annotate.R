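# Seed assignment, network-propagation annotation, fragment substructure
# annotation and de-novo annotation of seedless clusters.

#' Match a spectrum against the probe library
#'
#' Dereplication step: probe records whose precursor lies within
#' `precursor_tol_ppm` of the query and whose spectral similarity reaches
#' `threshold` are returned in decreasing similarity order. Polarity must
#' agree.
#'
#' @param spectrum Query [msms_spectrum].
#' @param probes A `probe_library`.
#' @param sim_fn Similarity function; default [modified_cosine()].
#' @param threshold Minimum similarity (default 0.7, the network threshold).
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 15).
#' @return data.frame `probe_id`, `compound_name`, `chemical_class`,
#'   `similarity`, `matched_peaks`, `precursor_ppm`, sorted by similarity.
#' @export
library_match <- function(spectrum, probes, sim_fn = NULL, threshold = 0.7,
                          precursor_tol_ppm = 15) {
  if (is.null(sim_fn)) sim_fn <- modified_cosine
  empty <- data.frame(probe_id = character(0), compound_name = character(0),
                      chemical_class = character(0), similarity = numeric(0),
                      matched_peaks = integer(0), precursor_ppm = numeric(0),
                      stringsAsFactors = FALSE)
  if (inherits(probes, "probe_library") && probes$polarity != spectrum$polarity)
    stop("polarity of spectrum and probe library disagree")
  recs <- if (inherits(probes, "probe_library")) probes$records else probes
  rows <- list()
  for (rec in recs) {
    sp <- rec$spectrum
    ppm <- (spectrum$precursor_mz - sp$precursor_mz) / sp$precursor_mz * 1e6
    if (abs(ppm) > precursor_tol_ppm) next
    s <- sim_fn(spectrum, sp)
    if (s$similarity < threshold) next
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = sp$id,
      compound_name = if (is.null(rec$compound_name)) sp$id else rec$compound_name,
      chemical_class = if (is.null(rec$chemical_class)) NA_character_
                       else rec$chemical_class,
      similarity = s$similarity, matched_peaks = s$matched_peaks,
      precursor_ppm = ppm, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(-out$similarity, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One annotation-evidence record.
annotation_evidence <- function(node, status, seed = NA_character_,
                                chain = empty_chain(), depth = 0L,
                                fragment_assignments = NULL, notes = "") {
  structure(list(node = node, status = status, seed = seed, chain = chain,
                 depth = depth, fragment_assignments = fragment_assignments,
                 notes = notes),
            class = "annotation_evidence")
}

empty_chain <- function() {
  data.frame(modification = character(0), direction = character(0),
             mass = numeric(0), observed_delta = numeric(0),
             ppm_error = numeric(0), corroborated = logical(0),
             stringsAsFactors = FALSE)
}

#' @export
print.annotation_evidence <- function(x, ...) {
  cat(sprintf("<annotation %s> %s%s%s\n", x$node, x$status,
              if (!is.na(x$seed)) paste0(" (seed ", x$seed, ", depth ", x$depth, ")") else "",
              if (nrow(x$chain)) paste0(": ", format_chain(x$chain)) else ""))
  invisible(x)
}

format_chain <- function(chain) {
  if (!nrow(chain)) return("")
  paste0(ifelse(chain$direction == "gain", "+", "-"), chain$modification,
         collapse = " > ")
}

#' Network-propagation annotation from seed nodes
#'
#' Breadth-first propagation: starting from seed nodes (probes or library
#' hits), each edge's precursor mass difference is interpreted as a known
#' modification via [match_mass_delta()]; a match extends the seed's
#' modification chain by one gain/loss step (gain when the neighbor precursor
#' is heavier). A step is *corroborated* when [detect_modifications()] finds
#' the same modification as a neutral loss in the neighbor's own MS/MS —
#' recorded but not required. Nodes reachable from several seeds keep the
#' assignment with the shallower depth, then the higher incoming-edge
#' similarity, then the lexicographically smallest seed id; alternatives are
#' kept in `notes`.
#'
#' @param network A `molecular_network`.
#' @param seeds Character vector of seed node ids, optionally named with a
#'   seed label (compound name).
#' @param registry A `modification_registry`.
#' @param tol_ppm Tolerance for edge-delta matching (default 15).
#' @param max_depth Maximum propagation depth (default 3).
#' @param min_fragment_intensity Intensity floor used for corroboration.
#' @return List of `annotation_evidence`, one per network node (seeds:
#'   `library-hit`; reached nodes: `propagated`; the rest: `unannotated`).
#' @export
propagate <- function(network, seeds, registry, tol_ppm = 15, max_depth = 3,
                      min_fragment_intensity = 100) {
  ids <- network$nodes$id
  seeds <- if (is.null(names(seeds))) stats::setNames(seeds, seeds)
           else stats::setNames(ifelse(nzchar(names(seeds)), names(seeds), seeds),
                                seeds)
  if (!all(names(seeds) %in% ids)) stop("seeds must be network nodes")
  prec <- stats::setNames(network$nodes$precursor_mz, ids)
  ev <- stats::setNames(vector("list", length(ids)), ids)
  for (s in names(seeds))
    ev[[s]] <- annotation_evidence(s, "library-hit", seed = s, depth = 0L,
                                   notes = unname(seeds[s]))
  edges <- network$edges
  frontier <- sort(names(seeds))
  depth <- 1L
  while (length(frontier) && depth <= max_depth) {
    # collect candidate extensions into not-yet-annotated nodes
    cands <- list()
    for (u in frontier) {
      inc <- which(edges$node_a == u | edges$node_b == u)
      for (k in inc) {
        v <- if (edges$node_a[k] == u) edges$node_b[k] else edges$node_a[k]
        if (!is.null(ev[[v]])) next
        delta <- prec[[v]] - prec[[u]]
        if (abs(delta) <= 0) next
        m <- match_mass_delta(abs(delta), registry, tol_ppm = tol_ppm)
        if (!nrow(m)) next
        best <- m[1, ]
        cands[[length(cands) + 1L]] <- list(
          v = v, u = u, seed = ev[[u]]$seed, sim = edges$similarity[k],
          mod = best, direction = if (delta > 0) "gain" else "loss",
          delta = abs(delta))
      }
    }
    if (!length(cands)) break
    next_frontier <- character(0)
    by_v <- split(cands, vapply(cands, `[[`, character(1), "v"))
    for (v in sort(names(by_v))) {
      cs <- by_v[[v]]
      ord <- order(-vapply(cs, `[[`, numeric(1), "sim"),
                   vapply(cs, `[[`, character(1), "seed"),
                   vapply(cs, `[[`, character(1), "u"))
      cs <- cs[ord]
      chosen <- cs[[1]]
      # corroboration: same modification found as neutral loss in v's MS/MS
      corro <- FALSE
      sp_v <- network$spectra[[v]]
      if (!is.null(sp_v) && nrow(sp_v$peaks)) {
        h <- detect_modifications(sp_v, registry, tol_ppm,
                                  min_fragment_intensity)
        corro <- chosen$mod$name %in% h$modification
      }
      parent_chain <- ev[[chosen$u]]$chain
      step <- data.frame(modification = chosen$mod$name,
                         direction = chosen$direction,
                         mass = chosen$mod$ref_mass,
                         observed_delta = chosen$delta,
                         ppm_error = chosen$mod$ppm_error,
                         corroborated = corro, stringsAsFactors = FALSE)
      alt <- if (length(cs) > 1L)
        paste0("alternatives: ",
               paste(vapply(cs[-1], function(c)
                 sprintf("%s via %s (sim %.3f)", c$mod$name, c$u, c$sim),
                 character(1)), collapse = "; "))
        else ""
      ev[[v]] <- annotation_evidence(v, "propagated", seed = chosen$seed,
                                     chain = rbind(parent_chain, step),
                                     depth = depth, notes = alt)
      next_frontier <- c(next_frontier, v)
    }
    frontier <- sort(next_frontier)
    depth <- depth + 1L
  }
  for (id in ids) if (is.null(ev[[id]]))
    ev[[id]] <- annotation_evidence(id, "unannotated")
  unname(ev[ids])
}

#' Signed mass sum of a modification chain
#'
#' Gains count positive, losses negative; for a propagated node the sum
#' approximates `precursor(node) - precursor(seed)`.
#'
#' @param chain Chain data.frame from an `annotation_evidence`.
#' @return Signed mass in Da.
#' @export
chain_mass_sum <- function(chain) {
  if (!nrow(chain)) return(0)
  sum(ifelse(chain$direction == "gain", chain$mass, -chain$mass))
}

#' Annotate MS/MS fragments with substructure evidence
#'
#' Assigns fragment-level substructures: precursor-fragment and
#' fragment-fragment mass differences are matched against the modification
#' registry (optionally allowing +/-2H ring-opening adjustments), and
#' fragments themselves are matched against the characteristic-ion table.
#' Overlapping explanations are all reported.
#'
#' @param spectrum Non-empty [msms_spectrum].
#' @param registry A `modification_registry`.
#' @param characteristic_ions data.frame `name`, `mz`, `polarity` (default:
#'   packaged table, filtered to the spectrum polarity).
#' @param tol_ppm Tolerance in ppm (default 15).
#' @param allow_h2_adjustment Allow +/-2H-adjusted registry matches.
#' @param min_fragment_intensity Intensity floor for considered fragments.
#' @return data.frame of `FragmentAssignment` rows: `kind`
#'   (`"neutral-loss"`/`"characteristic-ion"`), `ion1`, `ion2` (`NA` for direct
#'   ion matches), `assigned`, `observed_delta`, `ref_mass`, `ppm_error`,
#'   `adjustment`.
#' @export
annotate_fragments <- function(spectrum, registry,
                               characteristic_ions = NULL, tol_ppm = 15,
                               allow_h2_adjustment = TRUE,
                               min_fragment_intensity = 0) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  if (nrow(spectrum$peaks) == 0L) stop("spectrum has no peaks")
  if (is.null(characteristic_ions))
    characteristic_ions <- load_characteristic_ions()
  characteristic_ions <- characteristic_ions[
    characteristic_ions$polarity == spectrum$polarity, , drop = FALSE]
  pk <- spectrum$peaks[spectrum$peaks$intensity >= min_fragment_intensity, ,
                       drop = FALSE]
  rows <- list()
  add_delta <- function(ion1, ion2) {
    delta <- ion1 - ion2
    if (delta <= 0) return()
    m <- match_mass_delta(delta, registry, tol_ppm = tol_ppm,
                          allow_h2_adjustment = allow_h2_adjustment)
    if (!nrow(m)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = "neutral-loss", ion1 = ion1, ion2 = ion2, assigned = m$name,
      observed_delta = delta, ref_mass = m$ref_mass, ppm_error = m$ppm_error,
      adjustment = m$adjustment, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pk)))
    add_delta(spectrum$precursor_mz, pk$mz[i])
  if (nrow(pk) >= 2L)
    for (i in seq_len(nrow(pk) - 1L)) for (j in (i + 1L):nrow(pk))
      add_delta(pk$mz[j], pk$mz[i])
  if (nrow(characteristic_ions) && nrow(pk)) {
    for (i in seq_len(nrow(pk))) {
      ppm <- (pk$mz[i] - characteristic_ions$mz) / characteristic_ions$mz * 1e6
      ok <- which(abs(ppm) <= tol_ppm)
      for (k in ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "characteristic-ion", ion1 = pk$mz[i], ion2 = NA_real_,
          assigned = characteristic_ions$name[k], observed_delta = NA_real_,
          ref_mass = characteristic_ions$mz[k], ppm_error = ppm[k],
          adjustment = "0", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(kind = character(0), ion1 = numeric(0), ion2 = numeric(0),
                      assigned = character(0), observed_delta = numeric(0),
                      ref_mass = numeric(0), ppm_error = numeric(0),
                      adjustment = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Search for a multiset of <= max_parts assigned substructure masses summing to
# the precursor within tol_ppm. Parts: unique (assigned, adjustment) pairs.
composition_search <- function(precursor_mz, assignments, tol_ppm,
                               max_parts = 3) {
  if (!nrow(assignments)) return(list())
  parts <- unique(assignments[, c("kind", "assigned", "ref_mass", "adjustment")])
  parts <- parts[order(parts$assigned, parts$adjustment), , drop = FALSE]
  labels <- paste0(parts$assigned,
                   ifelse(parts$adjustment == "0", "",
                          paste0(" ", parts$adjustment)))
  n <- nrow(parts)
  tol <- tol_ppm * 1e-6 * precursor_mz
  found <- list()
  # combinations with repetition, sizes 1..max_parts (n is small)
  search <- function(start, chosen, total) {
    if (length(chosen) > 0 && abs(total - precursor_mz) <= tol) {
      found[[length(found) + 1L]] <<- labels[chosen]
    }
    if (length(chosen) >= max_parts) return()
    for (k in start:n) {
      if (total + parts$ref_mass[k] > precursor_mz + tol) next
      search(k, c(chosen, k), total + parts$ref_mass[k])
    }
  }
  if (n > 0) search(1L, integer(0), 0)
  # prefer smaller compositions; deduplicate
  found <- found[order(lengths(found))]
  unique(lapply(found, sort))
}

#' De-novo annotation of a seedless pathway cluster
#'
#' For clusters that qualify only through pathway-specific modifications and
#' contain no annotated seed, each member node receives fragment-level
#' substructure assignments ([annotate_fragments()]) and a composition
#' summary: multisets of at most `max_parts` assigned substructure masses
#' (registry losses with optional +/-2H adjustment, plus characteristic ions)
#' that account for the precursor within tolerance.
#'
#' @param cluster A `pathway_cluster` (from [filter_pathway_clusters()]).
#' @param network The `molecular_network` holding the member spectra.
#' @param registry A `modification_registry`.
#' @param characteristic_ions Characteristic-ion table; `NULL` for the packaged
#'   default.
#' @param tol_ppm Tolerance in ppm.
#' @param max_parts Maximum number of substructure parts tried (default 3).
#' @return List of `annotation_evidence` with status `"de-novo"`; each carries
#'   `fragment_assignments` and a `composition` element (list of character
#'   vectors; empty when no combination fits).
#' @export
de_novo_annotate <- function(cluster, network, registry,
                             characteristic_ions = NULL, tol_ppm = 15,
                             max_parts = 3) {
  out <- list()
  kind <- stats::setNames(network$nodes$kind, network$nodes$id)
  for (id in cluster$members) {
    if (identical(unname(kind[id]), "probe")) next
    sp <- network$spectra[[id]]
    fa <- if (!is.null(sp) && nrow(sp$peaks))
      annotate_fragments(sp, registry, characteristic_ions, tol_ppm)
      else annotate_fragments_empty()
    comp <- if (nrow(fa) && !is.null(sp))
      composition_search(sp$precursor_mz, fa, tol_ppm, max_parts) else list()
    e <- annotation_evidence(id, "de-novo", fragment_assignments = fa,
                             notes = if (length(comp))
                               paste("composition:",
                                     paste(vapply(comp, paste, character(1),
                                                  collapse = " + "),
                                           collapse = " | ")) else "")
    e$composition <- comp
    out[[length(out) + 1L]] <- e
  }
  out
}

annotate_fragments_empty <- function() {
  data.frame(kind = character(0), ion1 = numeric(0), ion2 = numeric(0),
             assigned = character(0), observed_delta = numeric(0),
             ref_mass = numeric(0), ppm_error = numeric(0),
             adjustment = character(0), stringsAsFactors = FALSE)
}

#' Export annotation evidence
#'
#' Writes one TSV row per node (status, seed, formatted chain, depth, number
#' of fragment assignments, notes) and, when `graphml` is given, an annotated
#' GraphML copy of the network with per-node status attributes.
#'
#' @param evidence List of `annotation_evidence`.
#' @param network The `molecular_network`.
#' @param path Output TSV path.
#' @param graphml Optional annotated GraphML output path.
#' @return The TSV path, invisibly.
#' @export
export_annotations <- function(evidence, network, path, graphml = NULL) {
  df <- annotation_table(evidence)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml))
    write_network_graphml(network, graphml,
                          node_attrs = df[, c("id", "status", "seed", "chain")])
  invisible(path)
}

#' @rdname export_annotations
#' @export
annotation_table <- function(evidence) {
  do.call(rbind, lapply(evidence, function(e) data.frame(
    id = e$node, status = e$status,
    seed = if (is.na(e$seed)) "" else e$seed,
    chain = format_chain(e$chain),
    chain_mass = chain_mass_sum(e$chain),
    depth = e$depth,
    n_fragment_assignments = if (is.null(e$fragment_assignments)) 0L
                             else nrow(e$fragment_assignments),
    notes = e$notes, stringsAsFactors = FALSE)))
}
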