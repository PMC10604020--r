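# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (no log-space trick, no vectorization).

# Mass-balance speciation oracle: concentrations relative to the fully
# protonated species via stepwise products of Ka / [H+].
oracleFractions <- function(pkas, ph) {
  h <- 10^(-ph)
  rel <- 1
  for (j in seq_along(pkas)) {
    rel <- c(rel, rel[length(rel)] * 10^(-pkas[j]) / h)
  }
  rel / sum(rel)
}

# Brute-force scaffold enumeration: all site subsets x group tuples,
# substituted by string replacement and deduplicated on canonical SMILES.
oracleEnumeration <- function(core, sites, fragments, maxK) {
  out <- character(0)
  for (k in seq_len(maxK)) {
    subs <- utils::combn(seq_along(sites), k, simplify = FALSE)
    tuples <- expand.grid(rep(list(seq_along(fragments)), k))
    for (ss in subs) {
      for (r in seq_len(nrow(tuples))) {
        smi <- core
        chosen <- as.integer(tuples[r, ])
        for (q in seq_along(sites)) {
          idx <- match(q, ss)
          rep_ <- if (!is.na(idx)) paste0("(", fragments[chosen[idx]], ")")
                  else ""
          smi <- sub(sprintf("{%s}", sites[q]), rep_, smi, fixed = TRUE)
        }
        out <- c(out, smi)
      }
    }
  }
  unique(canonicalizeSmiles(out))
}

# Small complete property table with hand-controllable values.
tinyProps <- function(n = 5, seed = 7) {
  set.seed(seed)
  data.frame(
    id = paste0("c", seq_len(n)),
    mw = seq(200, 400, length.out = n), logp = seq(0, 4, length.out = n),
    hbd = rep(2L, n), hba = rep(5L, n), tpsa = seq(40, 120, length.out = n),
    rotb = rep(4L, n), mr = seq(60, 120, length.out = n),
    heavy_atoms = rep(25L, n), carbons = rep(18L, n),
    heteroatoms = rep(6L, n), rings = rep(3L, n),
    sa = seq(30, 80, length.out = n),
    ld50 = seq(300, 900, length.out = n),
    mutagenicity = seq(0.2, 0.6, length.out = n),
    dev_tox = seq(0.2, 0.6, length.out = n),
    bf = seq(0.5, 2.5, length.out = n),
    stringsAsFactors = FALSE)
}

tinyRefs <- function(n = 8, seed = 11) {
  set.seed(seed)
  d <- tinyProps(n, seed)
  d$id <- paste0("ref", seq_len(n))
  for (cl in setdiff(names(d), "id")) {
    d[[cl]] <- d[[cl]] * (1 + stats::rnorm(n, 0, 0.05))
  }
  # integer descriptors need genuine spread for non-degenerate reference sds
  d$hbd <- 1L + (seq_len(n) %% 3L)
  d$hba <- 4L + (seq_len(n) %% 3L)
  d$rotb <- 3L + (seq_len(n) %% 4L)
  d$heavy_atoms <- 23L + (seq_len(n) %% 5L)
  d
}

# A property row sitting exactly on the reference centroid.
centroidRow <- function(refStats, id = "centroid") {
  row <- data.frame(id = id, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(refStats))) {
    row[[refStats$property[k]]] <- refStats$mean[k]
  }
  for (cl in c("carbons", "heteroatoms", "rings")) row[[cl]] <- 3
  row
}
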