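# Independent naive oracles, kept deliberately separate from the package
# implementations: explicit per-window string slicing and scalar
# arithmetic only.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste0(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# replichore of one position by walking the ori->ter arc
oracle_replichore <- function(pos, ori, ter, L) {
  p <- ori
  while (p != ter) {
    if (p == pos) return("right")
    p <- if (p == L) 1L else p + 1L
  }
  "left"
}

# dictionary of k-window counts by explicit slicing with wrap
oracle_count_contexts <- function(seq, circular, k, ori = NULL,
                                  ter = NULL, region = "genome",
                                  strand = "reference") {
  L <- nchar(seq)
  key_off <- floor((k - 1) / 2)
  dict <- new.env()
  n_skipped <- 0L
  starts <- if (circular) 1:L else 1:(L - k + 1)
  for (st in starts) {
    idx <- ((st:(st + k - 1) - 1) %% L) + 1
    win <- paste0(substring(seq, idx, idx), collapse = "")
    keyc <- ((st + key_off - 1) %% L) + 1
    if (!circular) keyc <- st + key_off
    if (region != "genome") {
      want <- if (region == "right_replichore") "right" else "left"
      if (oracle_replichore(keyc, ori, ter, L) != want) next
    }
    if (grepl("N", win, fixed = TRUE)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (strand == "complement") win <- oracle_revcomp(win)
    dict[[win]] <- (dict[[win]] %||% 0L) + 1L
  }
  list(counts = unlist(as.list(dict)), n_skipped = n_skipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# oriented triplet of one variant by slicing + conditional revcomp
oracle_context <- function(seq, circular, pos, ref, alt, ori, ter,
                           convention = "lagging_template_revcomp") {
  L <- nchar(seq)
  at <- function(p) {
    if (circular) p <- ((p - 1) %% L) + 1
    if (p < 1 || p > L) return(NA_character_)
    substring(seq, p, p)
  }
  up <- at(pos - 1); down <- at(pos + 1)
  if (is.na(up) || is.na(down)) return(NULL)
  rep_side <- oracle_replichore(pos, ori, ter, L)
  trip <- paste0(up, ref, down)
  if (convention == "lagging_template_revcomp" && rep_side == "right") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    list(triplet = oracle_revcomp(trip), ref = unname(comp[ref]),
         alt = unname(comp[alt]), replichore = rep_side)
  } else {
    list(triplet = trip, ref = ref, alt = alt, replichore = rep_side)
  }
}

# per-class mutation counts and rates by scalar accumulation
oracle_rates <- function(oriented, counts_vec, G, N) {
  out <- list()
  for (i in seq_len(nrow(oriented))) {
    key <- paste(oriented$oriented_up[i], oriented$oriented_ref[i],
                 oriented$oriented_alt[i], oriented$oriented_down[i])
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  rate_of <- function(up, ref, alt, down) {
    m <- out[[paste(up, ref, alt, down)]] %||% 0L
    den <- counts_vec[[paste0(up, ref, down)]]
    if (den == 0) return(NA_real_)
    m / (den * G * N)
  }
  list(M = out, rate_of = rate_of)
}

# bin of one variant by scalar offset arithmetic
oracle_bin <- function(pos, ori, L, n_bins) {
  offset <- (pos - ori) %% L
  floor(offset * n_bins / L) + 1
}

# circular distance between two positions
circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  min(d, L - d)
}

# quick random genome string
random_genome <- function(L, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste0(sample(c("A", "C", "G", "T"), L, TRUE, p), collapse = "")
}

# standard small planted-rate map used across tests (rates per site per
# generation; mismatch-repair-deficient magnitudes keep planted counts
# informative on kilobase fixtures)
test_u_true <- function() {
  list(ACG = c(T = 2e-6), TCT = c(A = 1e-6, G = 5e-7),
       GAT = c(C = 1.5e-6), CCG = c(A = 8e-7))
}
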