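# Independent brute-force oracles: plain double loops over residues and
# atoms, sharing no code with the vectorized production paths.

oracle_min_dist <- function(a, b, sidechain_only = FALSE) {
  keep <- function(at) {
    at <- at[at$element != "H", ]
    if (sidechain_only) at <- at[!at$name %in% c("N", "CA", "C", "O", "OXT"), ]
    at
  }
  a <- keep(a); b <- keep(b)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    dd <- sqrt((a$x[i] - b$x)^2 + (a$y[i] - b$y)^2 + (a$z[i] - b$z)^2)
    best <- min(best, min(dd))
  }
  best
}

# residues within the plain distance rule of the ligand
oracle_contact_residues <- function(s, ligand_key, cutoff = 5.5) {
  rs <- residues(s)
  at <- s$atoms[s$atoms$element != "H", ]
  blocks <- split(at, at$res_key)
  lig <- blocks[[ligand_key]]
  keys <- character()
  for (k in rs$res_key[rs$record_class == "polymer"]) {
    if (!is.null(blocks[[k]]) && oracle_min_dist(blocks[[k]], lig) < cutoff) {
      keys <- c(keys, k)
    }
  }
  keys
}

# unordered residue pairs under the vdW-sum side-chain rule
oracle_contact_map <- function(s, vdw = vdw_table(), tol = 0.6, min_sep = 4) {
  rs <- residues(s)
  rs <- rs[rs$record_class == "polymer", ]
  sc <- s$atoms[s$atoms$record_class == "polymer" &
                  !s$atoms$name %in% c("N", "CA", "C", "O", "OXT") &
                  s$atoms$element != "H", ]
  radius <- unclass(vdw)
  sc_plain <- list(x = sc$x, y = sc$y, z = sc$z, element = sc$element,
                   key = sc$res_key)
  blocks <- lapply(split(seq_along(sc_plain$key), sc_plain$key), function(ix) {
    list(x = sc_plain$x[ix], y = sc_plain$y[ix], z = sc_plain$z[ix],
         element = sc_plain$element[ix], n = length(ix))
  })
  keys <- rs$res_key; chains <- rs$chain; seqnums <- rs$seqnum
  pairs <- character()
  for (i in seq_len(length(keys) - 1)) {
    ai <- blocks[[keys[i]]]
    if (is.null(ai)) next
    for (j in seq(i + 1, length(keys))) {
      if (chains[i] == chains[j] &&
          abs(seqnums[i] - seqnums[j]) < min_sep) next
      aj <- blocks[[keys[j]]]
      if (is.null(aj)) next
      hit <- FALSE
      for (u in seq_len(ai$n)) {
        dd <- sqrt((ai$x[u] - aj$x)^2 + (ai$y[u] - aj$y)^2 +
                     (ai$z[u] - aj$z)^2)
        if (any(dd < radius[[ai$element[u]]] +
                  unname(radius[aj$element]) + tol)) {
          hit <- TRUE
          break
        }
      }
      if (hit) pairs <- c(pairs, paste(keys[i], keys[j], sep = "~"))
    }
  }
  sort(pairs)
}

map_pair_keys <- function(cm) {
  sort(paste(cm$res_key_i, cm$res_key_j, sep = "~"))
}
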