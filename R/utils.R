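`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Deterministic child-seed derivation: keeps every derived seed a valid
## 32-bit integer so independent streams (per module / neuron / condition)
## can be re-drawn in any order.
derive_seed <- function(root, ...) {
  m <- 2147483647
  s <- as.double(root) %% m
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) + 1) %% m
  }
  as.integer(s)
}

## Format a numeric for CSV output at full round-trip precision.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

## Write a data.frame as CSV with numerics at 17 significant digits so that
## re-running a pipeline reproduces byte-identical files.
write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

is_count <- function(x) {
  length(x) == 1 && is.finite(x) && x == as.integer(x) && x >= 0
}

is_fraction <- function(x) {
  length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

stop_midnet <- function(...) stop(..., call. = FALSE)
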