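# Shared fixtures and independent oracles.

# Quick toy spectrum.
toy_spectrum <- function(id, precursor, mz, intensity = rep(1000, length(mz)),
                         rt = NA_real_, polarity = "positive") {
  msms_spectrum(id, precursor, data.frame(mz = mz, intensity = intensity),
                rt = rt, polarity = polarity)
}

default_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- load_modification_registry()
    reg
  }
})

# Independent brute-force oracle for the modified cosine: exhaustive
# enumeration over all one-to-one pairings of candidate peak pairs (direct or
# precursor-shifted), maximizing the sum of products of unit-normalized
# square-root intensities. Kept free of the package's assignment code.
brute_modified_cosine <- function(a, b, fragment_tol_da = 0.02) {
  wa <- sqrt(a$peaks$intensity); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(b$peaks$intensity); wb <- wb / sqrt(sum(wb^2))
  shift <- a$precursor_mz - b$precursor_mz
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  cand <- vector("list", na)
  for (i in seq_len(na)) {
    d <- a$peaks$mz[i] - b$peaks$mz
    cand[[i]] <- which(abs(d) <= fragment_tol_da |
                         abs(d - shift) <= fragment_tol_da)
  }
  best <- 0
  rec <- function(i, used, acc) {
    if (i > na) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1L, used, acc)                     # leave peak i unmatched
    for (j in cand[[i]]) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1L, used, acc + wa[i] * wb[j])
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nb), 0)
  min(1, best)
}

# Random spectrum with n peaks; peaks may intentionally collide with `near`
# (m/z values copied within the fragment tolerance) to exercise ambiguous
# assignments.
random_spectrum <- function(id, n, precursor = runif(1, 200, 800),
                            near = NULL, tol = 0.02) {
  mz <- runif(n, 50, precursor - 10)
  if (!is.null(near) && length(near)) {
    k <- min(length(near), sample.int(n, 1))
    mz[seq_len(k)] <- near[seq_len(k)] + runif(k, -tol / 2, tol / 2)
  }
  toy_spectrum(id, precursor, sort(mz), intensity = runif(n, 100, 10000))
}

# Zero-noise synthetic world used across suites (sizes from the recovery
# criterion: 20 probes, 50 single-step derivatives, fixed seed).
synthetic_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      reg <- default_registry()
      probes <- generate_probes(20, seed = 7)
      ds <- derive_modified(probes, reg, n_derived = 50, seed = 7)
      cache <<- list(registry = reg, probes = probes, dataset = ds)
    }
    cache
  }
})
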