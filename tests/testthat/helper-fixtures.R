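# Shared fixtures (cached per session: the surface-area computation on the
# toy structures is the slow step) and independent oracles used to check
# the package's own implementations.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

toy_fv <- function(seed = 1, apr_in_cdr = TRUE, apr_length = 6) {
  cached(paste("fv", seed, apr_in_cdr, apr_length),
         make_toy_fv(seed = seed, apr_in_cdr = apr_in_cdr,
                     apr_length = apr_length))
}

toy_struct <- function(seed = 1, burial = "exposed") {
  cached(paste("st", seed, burial),
         make_toy_structure(toy_fv(seed), burial = burial))
}

toy_fit <- function(seed = 1, burial = NULL) {
  key <- paste("fit", seed, burial %||% "none")
  cached(key, {
    fx <- toy_fv(seed)
    st <- if (is.null(burial)) NULL else toy_struct(seed, burial)$structure
    solubis(heavy = fx$heavy, light = fx$light, structure = st,
            id = paste0("toy", seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_temp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}

# ---- independent oracles ----

# exhaustive maximal-run APR caller: checks every interval
apr_oracle <- function(scores, min_len = 5, threshold = 5) {
  n <- length(scores)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_len) next
      if (!all(scores[i:j] >= threshold)) next
      left_ok <- i == 1 || scores[i - 1] < threshold
      right_ok <- j == n || scores[j + 1] < threshold
      if (left_ok && right_ok)
        out <- rbind(out, data.frame(start = i, end = j))
    }
  }
  if (is.null(out)) data.frame(start = integer(), end = integer()) else out
}

# pair-counting AUC by explicit double loop, ties worth one half
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# dense random-direction surface-area sampler, independent of the
# golden-spiral implementation
sasa_bruteforce <- function(atoms, probe = 1.4, n_points = 3000,
                            seed = 99) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  r <- unname(radii[atoms$element])
  r[is.na(r)] <- 1.80
  r <- r + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * n_points), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  vapply(seq_len(nrow(atoms)), function(i) {
    pts <- sweep(dirs * r[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(nrow(atoms))[-i]) {
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & d2 >= r[j]^2
    }
    mean(free) * 4 * pi * r[i]^2
  }, numeric(1))
}
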