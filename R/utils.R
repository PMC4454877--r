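# Internal helpers: seeded RNG substreams and small IO wrappers.

# Derive a reproducible 32-bit substream seed from a master seed and a label.
# Named substreams keep stages independent: re-drawing one stage (e.g. the
# null model) never perturbs another (e.g. ANOSIM permutations).
substream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, !is.na(master))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(((abs(master) %% m) * 48271 + h) %% m)
}

# Evaluate code under a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

write_tsv_file <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
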