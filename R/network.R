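# Spectral similarity and molecular-network construction.

# Square-root (GNPS convention) or plain intensity weights, unit-normalized.
peak_weights <- function(spectrum, weighting = c("sqrt", "intensity")) {
  weighting <- match.arg(weighting)
  w <- spectrum$peaks$intensity
  if (weighting == "sqrt") w <- sqrt(w)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) return(rep(0, length(w)))
  w / nrm
}

# Candidate peak pairs between two spectra: direct (|dmz| <= tol) or shifted by
# the precursor difference (|dmz - shift| <= tol). Returns i, j, weight.
candidate_pairs <- function(a, b, wa, wb, fragment_tol_da, shift) {
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  mza <- a$peaks$mz; mzb <- b$peaks$mz
  res_i <- integer(0); res_j <- integer(0)
  for (i in seq_len(na)) {
    d <- mza[i] - mzb
    ok <- abs(d) <= fragment_tol_da | abs(d - shift) <= fragment_tol_da
    j <- which(ok)
    res_i <- c(res_i, rep.int(i, length(j)))
    res_j <- c(res_j, j)
  }
  data.frame(i = res_i, j = res_j, weight = wa[res_i] * wb[res_j])
}

# Exact maximum-weight one-to-one assignment on the candidate-pair graph,
# via weighted bipartite matching. Returns list(score, pairs data.frame).
optimal_assignment <- function(cand, na, nb) {
  if (nrow(cand) == 0L) return(list(score = 0, pairs = cand))
  keep <- cand$weight > 0
  cand_pos <- cand[keep, , drop = FALSE]
  if (nrow(cand_pos) == 0L) return(list(score = 0, pairs = cand[0, ]))
  g <- igraph::make_bipartite_graph(
    c(rep(FALSE, na), rep(TRUE, nb)),
    as.vector(t(cbind(cand_pos$i, na + cand_pos$j))),
    directed = FALSE)
  m <- igraph::max_bipartite_match(g, weights = cand_pos$weight)
  mate <- m$matching[seq_len(na)]           # for each a-peak, matched b vertex or NA
  i <- which(!is.na(mate))
  j <- as.integer(mate[i]) - na
  # retain only pairs that are actual candidates (defensive; matching only uses edges)
  pr <- data.frame(i = i, j = j)
  pr <- merge(pr, cand_pos, by = c("i", "j"))
  list(score = sum(pr$weight), pairs = pr)
}

# Greedy-by-score assignment (fast approximation, optional).
greedy_assignment <- function(cand) {
  if (nrow(cand) == 0L) return(list(score = 0, pairs = cand))
  cand <- cand[order(-cand$weight, cand$i, cand$j), , drop = FALSE]
  used_i <- logical(max(cand$i)); used_j <- logical(max(cand$j))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_i[cand$i[k]] && !used_j[cand$j[k]] && cand$weight[k] > 0) {
      keep[k] <- TRUE; used_i[cand$i[k]] <- TRUE; used_j[cand$j[k]] <- TRUE
    }
  }
  pr <- cand[keep, , drop = FALSE]
  list(score = sum(pr$weight), pairs = pr)
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' Cosine similarity in which fragment peaks may pair either directly
#' (`|dmz| <= fragment_tol_da`) or offset by the precursor mass difference, so
#' that a metabolite and its modified analogue still score highly. Peak
#' intensities are square-root transformed and unit-normalized (GNPS
#' convention; `weighting = "intensity"` selects the plain cosine). Each peak
#' is used at most once; the default assignment is the exact maximum-weight
#' one-to-one matching over candidate pairs.
#'
#' @param a,b [msms_spectrum] objects (non-empty).
#' @param fragment_tol_da Fragment tolerance in Da (default 0.02).
#' @param weighting `"sqrt"` (default) or `"intensity"`.
#' @param method `"optimal"` (exact matching, default) or `"greedy"`.
#' @return List with `similarity` (in \[0, 1\]) and `matched_peaks` (number of
#'   pairs in the chosen assignment).
#' @export
modified_cosine <- function(a, b, fragment_tol_da = 0.02,
                            weighting = c("sqrt", "intensity"),
                            method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L) stop("empty spectrum")
  wa <- peak_weights(a, weighting); wb <- peak_weights(b, weighting)
  shift <- a$precursor_mz - b$precursor_mz
  cand <- candidate_pairs(a, b, wa, wb, fragment_tol_da, shift)
  res <- if (method == "optimal") optimal_assignment(cand, nrow(a$peaks), nrow(b$peaks))
         else greedy_assignment(cand)
  list(similarity = min(1, max(0, res$score)),
       matched_peaks = nrow(res$pairs))
}

# Merge peaks lying within tol of each other (single linkage on the sorted mz
# axis); intensities summed, m/z intensity-weighted mean.
merge_peaks_within <- function(peaks, tol) {
  if (nrow(peaks) <= 1L) return(peaks)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(peaks$mz) > tol))
  data.frame(
    mz = as.numeric(tapply(peaks$mz * peaks$intensity, grp, sum) /
                    tapply(peaks$intensity, grp, sum)),
    intensity = as.numeric(tapply(peaks$intensity, grp, sum)))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Spectral entropy similarity
#'
#' Similarity based on the Shannon entropy of the intensity-normalized spectra
#' and of their 1:1 merged spectrum:
#' `1 - (2 * S_AB - S_A - S_B) / ln(4)`, clamped to \[0, 1\]. Peaks within
#' `fragment_tol_da` are merged before normalization, and the merged spectrum
#' combines both normalized spectra with equal weight.
#'
#' Identical spectra score 1; two single-peak spectra at different m/z score 0.
#'
#' @param a,b [msms_spectrum] objects (non-empty).
#' @param fragment_tol_da Fragment tolerance in Da.
#' @return Similarity in \[0, 1\]; symmetric in its arguments.
#' @export
entropy_similarity <- function(a, b, fragment_tol_da = 0.02) {
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  if (nrow(a$peaks) == 0L || nrow(b$peaks) == 0L) stop("empty spectrum")
  norm1 <- function(p) { p$intensity <- p$intensity / sum(p$intensity); p }
  pa <- norm1(merge_peaks_within(a$peaks, fragment_tol_da))
  pb <- norm1(merge_peaks_within(b$peaks, fragment_tol_da))
  sA <- shannon_entropy(pa$intensity)
  sB <- shannon_entropy(pb$intensity)
  mixed <- rbind(transform(pa, intensity = intensity / 2),
                 transform(pb, intensity = intensity / 2))
  mixed <- merge_peaks_within(mixed, fragment_tol_da)
  sAB <- shannon_entropy(mixed$intensity)
  sim <- 1 - (2 * sAB - sA - sB) / log(4)
  min(1, max(0, sim))
}

#' Build a molecular network
#'
#' Constructs a GNPS-style molecular network over experimental and probe
#' spectra: (1) near-duplicate nodes (precursors within
#' `precursor_merge_tol_da` and similarity >= `threshold`) are collapsed onto
#' the higher-intensity / lexicographically-earlier node; (2) edges connect
#' pairs with similarity >= `threshold` and at least `min_matched` matched
#' fragments; (3) an edge survives only if it ranks within the top
#' `max_neighbors` edges of *both* endpoints; (4) connected components larger
#' than `max_component` are split by iteratively removing their
#' lowest-similarity edges.
#'
#' @param experimental Named-by-id list of [msms_spectrum] (experimental nodes),
#'   or a plain list (ids taken from the spectra).
#' @param probes Probe spectra: a `probe_library` or list of [msms_spectrum].
#' @param sim_fn Similarity function `(a, b) -> list(similarity, matched_peaks)`;
#'   default [modified_cosine()] at `fragment_tol_da`.
#' @param threshold Similarity threshold (default 0.7).
#' @param min_matched Minimum matched fragment count per edge (default 6).
#' @param precursor_merge_tol_da Node-deduplication precursor tolerance
#'   (default 0.01 Da).
#' @param fragment_tol_da Fragment tolerance passed to the default `sim_fn`.
#' @param max_neighbors Per-node neighbor cap (default 50).
#' @param max_component Component size cap (default 500).
#' @param hits Optional named list: node id -> modification-hit data.frame
#'   from [detect_modifications()] (carried for cluster filtering).
#' @return A `molecular_network`: list with `nodes` (data.frame `id`, `kind`,
#'   `precursor_mz`, `total_intensity`), `edges` (data.frame `node_a`,
#'   `node_b`, `similarity`, `matched_peaks`, `precursor_delta`), `components`
#'   (named membership vector), `spectra`, `hits`, `merged` (absorbed id ->
#'   representative), `params`.
#' @export
build_network <- function(experimental, probes = list(), sim_fn = NULL,
                          threshold = 0.7, min_matched = 6,
                          precursor_merge_tol_da = 0.01,
                          fragment_tol_da = 0.02,
                          max_neighbors = 50, max_component = 500,
                          hits = list()) {
  stopifnot(threshold >= 0, min_matched >= 0, max_neighbors >= 1,
            max_component >= 1)
  if (is.null(sim_fn))
    sim_fn <- function(a, b) modified_cosine(a, b, fragment_tol_da = fragment_tol_da)
  exp_sp <- probe_spectra(experimental)  # names by id
  prb_sp <- probe_spectra(probes)
  if (any(names(prb_sp) %in% names(exp_sp)))
    stop("node ids must be unique across probe and experimental spectra")
  spectra <- c(exp_sp, prb_sp)
  if (anyDuplicated(names(spectra))) stop("duplicate node ids")
  kind <- c(rep("experimental", length(exp_sp)), rep("probe", length(prb_sp)))
  names(kind) <- names(spectra)
  ids <- sort(names(spectra))
  tot_int <- vapply(spectra, function(s) sum(s$peaks$intensity), numeric(1))
  prec <- vapply(spectra, `[[`, numeric(1), "precursor_mz")

  # (1) deduplicate near-identical nodes
  merged <- character(0)
  alive <- ids
  if (length(alive) > 1L) {
    ord <- alive[order(prec[alive])]
    absorbed <- stats::setNames(character(0), character(0))
    for (i in seq_len(length(ord) - 1L)) {
      a <- ord[i]
      if (a %in% names(absorbed)) next
      for (j in (i + 1L):length(ord)) {
        b <- ord[j]
        if (prec[b] - prec[a] > precursor_merge_tol_da) break
        if (b %in% names(absorbed)) next
        s <- sim_fn(spectra[[a]], spectra[[b]])
        if (s$similarity >= threshold) {
          # keep higher total intensity; tie -> lexicographically earlier id
          keep <- if (tot_int[a] > tot_int[b]) a
                  else if (tot_int[b] > tot_int[a]) b
                  else min(a, b)
          drop <- if (keep == a) b else a
          absorbed[drop] <- keep
          if (drop == a) break
        }
      }
    }
    merged <- absorbed
    alive <- setdiff(alive, names(absorbed))
  }

  # (2) all pairwise edges above threshold with enough matched peaks
  edges <- list()
  alive <- sort(alive)
  n <- length(alive)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- alive[i]; b <- alive[j]
      s <- sim_fn(spectra[[a]], spectra[[b]])
      if (s$similarity >= threshold && s$matched_peaks >= min_matched) {
        edges[[length(edges) + 1L]] <- data.frame(
          node_a = a, node_b = b, similarity = s$similarity,
          matched_peaks = s$matched_peaks,
          precursor_delta = prec[a] - prec[b], stringsAsFactors = FALSE)
      }
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        similarity = numeric(0), matched_peaks = integer(0),
                        precursor_delta = numeric(0), stringsAsFactors = FALSE)

  # (3) mutual top-K neighbor filter
  if (nrow(edges) > 0L) {
    rank_of <- function(node) {
      inc <- which(edges$node_a == node | edges$node_b == node)
      other <- ifelse(edges$node_a[inc] == node, edges$node_b[inc],
                      edges$node_a[inc])
      inc[order(-edges$similarity[inc], -edges$matched_peaks[inc], other)]
    }
    keep <- rep(TRUE, nrow(edges))
    for (node in alive) {
      ranked <- rank_of(node)
      if (length(ranked) > max_neighbors)
        keep[ranked[(max_neighbors + 1L):length(ranked)]] <- FALSE
    }
    edges <- edges[keep, , drop = FALSE]
  }

  # (4) split oversized components by removing lowest-similarity edges
  comp <- compute_components(alive, edges)
  repeat {
    sizes <- table(comp)
    oversized <- names(sizes)[sizes > max_component]
    if (!length(oversized) || nrow(edges) == 0L) break
    bad_nodes <- names(comp)[comp %in% oversized]
    in_bad <- edges$node_a %in% bad_nodes
    cand <- which(in_bad)
    if (!length(cand)) break
    ord <- cand[order(edges$similarity[cand], edges$matched_peaks[cand],
                      edges$node_a[cand], edges$node_b[cand])]
    edges <- edges[-ord[1], , drop = FALSE]
    comp <- compute_components(alive, edges)
  }
  rownames(edges) <- NULL

  structure(list(
    nodes = data.frame(id = alive, kind = unname(kind[alive]),
                       precursor_mz = unname(prec[alive]),
                       total_intensity = unname(tot_int[alive]),
                       stringsAsFactors = FALSE),
    edges = edges,
    components = comp,
    spectra = spectra[alive],
    hits = hits,
    merged = merged,
    params = list(threshold = threshold, min_matched = min_matched,
                  precursor_merge_tol_da = precursor_merge_tol_da,
                  fragment_tol_da = fragment_tol_da,
                  max_neighbors = max_neighbors, max_component = max_component)
  ), class = "molecular_network")
}

# Connected-component membership for a node set + edge list, labelled by the
# lexicographically smallest member id (deterministic).
compute_components <- function(ids, edges) {
  if (!length(ids)) return(stats::setNames(character(0), character(0)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(edges))
    g <- igraph::add_edges(g, as.vector(t(cbind(edges$node_a, edges$node_b))))
  memb <- igraph::components(g)$membership
  lab <- tapply(names(memb), memb, min)
  stats::setNames(unname(lab[as.character(memb)]), names(memb))
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("<molecular_network> %d nodes (%d probe / %d experimental), %d edges, %d components\n",
              nrow(x$nodes), sum(x$nodes$kind == "probe"),
              sum(x$nodes$kind == "experimental"), nrow(x$edges),
              length(unique(x$components))))
  invisible(x)
}

#' Node degrees of a molecular network
#' @param network A `molecular_network`.
#' @return Named integer vector.
#' @export
network_degrees <- function(network) {
  deg <- stats::setNames(rep(0L, nrow(network$nodes)), network$nodes$id)
  if (nrow(network$edges)) {
    t1 <- table(network$edges$node_a); t2 <- table(network$edges$node_b)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Filter pathway clusters from a molecular network
#'
#' A connected component qualifies as a pathway cluster when it either
#' contains at least one probe node together with at least one screened
#' modified metabolite, or contains at least one node carrying a
#' pathway-specific modification hit. Single-node components can only qualify
#' through the specific-modification rule.
#'
#' @param network A `molecular_network` built over probe + experimental nodes.
#' @param modified_ids Ids of nodes screened as modified metabolites.
#' @param registry A `modification_registry` (used to classify hits when the
#'   stored hit tables lack a `category` column).
#' @return List of `pathway_cluster` objects: `component` (label), `members`,
#'   `qualification` (`"probe+modified"` or `"specific-modification-only"`),
#'   `probes`, `specific_modifications`.
#' @export
filter_pathway_clusters <- function(network, modified_ids, registry) {
  comp <- network$components
  hits <- network$hits
  is_probe <- stats::setNames(network$nodes$kind == "probe", network$nodes$id)
  spec_by_cat <- stats::setNames(registry$category, registry$name)
  out <- list()
  for (lab in sort(unique(comp))) {
    members <- sort(names(comp)[comp == lab])
    probes <- members[is_probe[members]]
    modified <- intersect(members, modified_ids)
    spec_mods <- character(0)
    for (id in members) {
      h <- hits[[id]]
      if (is.null(h) || nrow(h) == 0L) next
      cat_col <- if ("category" %in% names(h)) h$category
                 else unname(spec_by_cat[h$modification])
      spec_mods <- c(spec_mods, h$modification[cat_col == "specific"])
    }
    spec_mods <- sort(unique(spec_mods))
    probe_rule <- length(probes) >= 1L && length(modified) >= 1L &&
      length(members) >= 2L
    spec_rule <- length(spec_mods) >= 1L
    if (!probe_rule && !spec_rule) next
    out[[length(out) + 1L]] <- structure(list(
      component = lab, members = members,
      qualification = if (probe_rule) "probe+modified"
                      else "specific-modification-only",
      probes = probes, specific_modifications = spec_mods),
      class = "pathway_cluster")
  }
  out
}

#' @export
print.pathway_cluster <- function(x, ...) {
  cat(sprintf("<pathway_cluster %s> %d member(s), %s; probes: %s\n",
              x$component, length(x$members), x$qualification,
              if (length(x$probes)) paste(x$probes, collapse = ", ") else "none"))
  invisible(x)
}

#' Export a molecular network
#'
#' Writes a Cytoscape-compatible GraphML file (node attributes: kind,
#' precursor m/z, annotation status when supplied) and optionally an edge TSV.
#'
#' @param network A `molecular_network`.
#' @param path Output GraphML path.
#' @param edge_tsv Optional edge-table TSV path.
#' @param node_attrs Optional data.frame with column `id` plus extra node
#'   attribute columns to attach.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, edge_tsv = NULL,
                                  node_attrs = NULL) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(network$nodes), name = network$nodes$id)
  igraph::V(g)$kind <- network$nodes$kind
  igraph::V(g)$precursor_mz <- network$nodes$precursor_mz
  igraph::V(g)$component <- unname(network$components[network$nodes$id])
  if (!is.null(node_attrs)) {
    idx <- match(network$nodes$id, node_attrs$id)
    for (col in setdiff(names(node_attrs), "id")) {
      v <- node_attrs[[col]][idx]
      if (is.character(v)) v[is.na(v)] <- ""
      g <- igraph::set_vertex_attr(g, col, value = v)
    }
  }
  if (nrow(network$edges)) {
    g <- igraph::add_edges(
      g, as.vector(t(cbind(network$edges$node_a, network$edges$node_b))))
    igraph::E(g)$similarity <- network$edges$similarity
    igraph::E(g)$matched_peaks <- network$edges$matched_peaks
    igraph::E(g)$precursor_delta <- network$edges$precursor_delta
  }
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(edge_tsv))
    utils::write.table(network$edges, edge_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
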