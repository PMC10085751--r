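#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# 1-based modular wrap of positions onto a circle of length L
wrap_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

# reverse a single string
str_rev <- function(s) {
  vapply(s, function(x) intToUtf8(rev(utf8ToInt(x))), character(1),
         USE.NAMES = FALSE)
}

# all k-mers over A/C/G/T in lexicographic order
kmer_keyspace <- function(k) {
  stopifnot(k >= 1)
  grid <- do.call(expand.grid,
                  c(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

# canonical 192-row keyspace over (up, ref, alt, down), lexicographic,
# alt restricted to the three bases differing from ref
context_keyspace <- function() {
  grid <- expand.grid(down = DNA_BASES, alt = DNA_BASES, ref = DNA_BASES,
                      up = DNA_BASES, stringsAsFactors = FALSE)
  grid <- grid[, c("up", "ref", "alt", "down")]
  grid <- grid[grid$ref != grid$alt, , drop = FALSE]
  grid <- grid[order(grid$up, grid$ref, grid$alt, grid$down), ,
               drop = FALSE]
  rownames(grid) <- NULL
  grid
}

# deterministic per-stage seed derivation: one named substream per stage so
# adding a stage never perturbs earlier draws
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# evaluate expr under a temporary RNG state seeded for one generator stage
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
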